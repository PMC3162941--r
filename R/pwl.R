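# Piecewise-linear utilities used by Mamdani aggregation and centroid
# defuzzification. Functions are represented as two-column matrices of
# (x, y) vertices spanning the output domain; between vertices the function
# is linear, so all geometry below is exact (no grid discretization).

# Evaluate a vertex matrix at x (constant extension outside its range).
pwl_eval <- function(pts, x) {
  stats::approx(pts[, 1L], pts[, 2L], xout = x, method = "linear",
                rule = 2L)$y
}

# Clip a fuzzy set at height h over the closed domain: pointwise
# min(mu(x), h). New vertices are inserted where mu crosses h so the result
# is again piecewise linear on its vertex set.
pwl_clip <- function(set, h, domain) {
  bp <- set$points
  xs <- c(domain, bp[bp[, 1L] >= domain[1L] & bp[, 1L] <= domain[2L], 1L])
  # crossing points of each linear segment with the clip height
  full_x <- c(domain[1L], bp[, 1L], domain[2L])
  full_y <- c(bp[1L, 2L], bp[, 2L], bp[nrow(bp), 2L])
  for (i in seq_len(length(full_x) - 1L)) {
    y0 <- full_y[i]; y1 <- full_y[i + 1L]
    if ((y0 - h) * (y1 - h) < 0) {
      xc <- full_x[i] + (h - y0) / (y1 - y0) * (full_x[i + 1L] - full_x[i])
      if (xc > domain[1L] && xc < domain[2L]) xs <- c(xs, xc)
    }
  }
  xs <- sort(unique(xs))
  cbind(x = xs, y = pmin(pwl_eval(bp, xs), h))
}

# Upper envelope (pointwise max) of a list of vertex matrices sharing a
# domain. Vertices of every input plus all pairwise segment crossings are
# included, so the envelope is linear between consecutive vertices.
pwl_max <- function(fns) {
  xs <- sort(unique(unlist(lapply(fns, function(f) f[, 1L]))))
  if (length(fns) > 1L) {
    extra <- numeric(0)
    for (k in seq_len(length(xs) - 1L)) {
      a <- xs[k]; b <- xs[k + 1L]
      ya <- vapply(fns, pwl_eval, numeric(1), x = a)
      yb <- vapply(fns, pwl_eval, numeric(1), x = b)
      n <- length(fns)
      for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
        d0 <- ya[i] - ya[j]; d1 <- yb[i] - yb[j]
        if (d0 * d1 < 0) extra <- c(extra, a + d0 / (d0 - d1) * (b - a))
      }
    }
    xs <- sort(unique(c(xs, extra)))
  }
  ymat <- vapply(fns, pwl_eval, numeric(length(xs)), x = xs)
  if (is.null(dim(ymat))) ymat <- matrix(ymat, nrow = length(xs))
  cbind(x = xs, y = apply(ymat, 1L, max))
}

# Exact centroid (area-weighted mean abscissa) of a piecewise-linear
# function given by its vertices. For a segment with endpoints (x0,y0),
# (x1,y1): area = (y0+y1)/2 dx and first moment
# integral of x*y = dx * (x0(2 y0 + y1) + x1(y0 + 2 y1)) / 6.
pwl_centroid <- function(pts) {
  x0 <- pts[-nrow(pts), 1L]; x1 <- pts[-1L, 1L]
  y0 <- pts[-nrow(pts), 2L]; y1 <- pts[-1L, 2L]
  dx <- x1 - x0
  area <- sum((y0 + y1) / 2 * dx)
  if (area <= .Machine$double.eps)
    stop("degenerate output: aggregated membership has zero area",
         call. = FALSE)
  moment <- sum(dx * (x0 * (2 * y0 + y1) + x1 * (y0 + 2 * y1)) / 6)
  moment / area
}
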