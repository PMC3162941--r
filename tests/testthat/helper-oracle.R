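# Independent brute-force Mamdani oracle used to cross-check the package's
# closed-form piecewise-linear path. Interpolation is hand-rolled (not
# stats::approx), aggregation and centroid are dense-grid numeric.

oracle_interp <- function(pts, x) {
  xs <- pts[, 1L]; mus <- pts[, 2L]
  n <- length(xs)
  vapply(x, function(xx) {
    if (xx <= xs[1L]) return(mus[1L])
    if (xx >= xs[n]) return(mus[n])
    i <- findInterval(xx, xs)
    mus[i] + (mus[i + 1L] - mus[i]) * (xx - xs[i]) / (xs[i + 1L] - xs[i])
  }, numeric(1))
}

# Full pipeline on a dense output grid: min conjunction, clip, pointwise
# max, trapezoidal centroid, winner-take-all label with the same
# safety-first tie-break the engine documents.
oracle_infer <- function(engine, mbp, spo2, step = 0.001) {
  clamp <- function(v, dom) min(max(v, dom[1L]), dom[2L])
  mbp <- clamp(mbp, engine$variables$MBP$domain)
  spo2 <- clamp(spo2, engine$variables$SpO2$domain)
  deg <- list(
    MBP = vapply(engine$variables$MBP$sets,
                 function(s) oracle_interp(s$points, mbp), numeric(1)),
    SpO2 = vapply(engine$variables$SpO2$sets,
                  function(s) oracle_interp(s$points, spo2), numeric(1)))
  strengths <- vapply(engine$rules, function(r)
    min(vapply(r$antecedents,
               function(a) deg[[a$variable]][[a$term]], numeric(1))),
    numeric(1))
  dom <- engine$output$domain
  grid <- seq(dom[1L], dom[2L], by = step)
  y <- numeric(length(grid))
  for (k in seq_along(engine$rules)) {
    if (strengths[k] > 0) {
      mu <- oracle_interp(
        engine$output$sets[[engine$rules[[k]]$consequent]]$points, grid)
      y <- pmax(y, pmin(mu, strengths[k]))
    }
  }
  w <- c(0.5, rep(1, length(grid) - 2L), 0.5)
  score <- sum(w * grid * y) / sum(w * y)
  urg <- vapply(engine$rules, `[[`, character(1), "urgency")
  ids <- vapply(engine$rules, `[[`, integer(1), "id")
  ord <- order(-strengths, -match(urg, c("none", "low", "medium", "high")),
               ids)
  list(score = score,
       label = engine$rules[[ord[1L]]]$consequent,
       strengths = strengths)
}

# Trapezoidal centroid of an aggregated vertex matrix on an n-point grid
# (numeric-integration oracle for the closed-form centroid).
oracle_centroid_grid <- function(agg, n = 10000L, dom = c(0, 10)) {
  grid <- seq(dom[1L], dom[2L], length.out = n)
  y <- oracle_interp(agg, grid)
  w <- c(0.5, rep(1, n - 2L), 0.5)
  sum(w * grid * y) / sum(w * y)
}
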