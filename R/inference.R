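#' Fire the rule base against fuzzified inputs
#'
#' Computes each rule's activation strength as the minimum of its antecedent
#' degrees (AND = min, the Mamdani conjunction). By input-domain coverage at
#' least one rule activates strictly for any in-domain input pair.
#'
#' @param engine A [fuzzy_engine()].
#' @param fuzzified Named list, one entry per input variable, each a named
#'   degree vector as returned by [fuzzify()].
#' @return A data.frame with columns `rule_id`, `strength`, `consequent`.
#' @export
fire_rules <- function(engine, fuzzified) {
  stopifnot(inherits(engine, "fuzzy_engine"), is.list(fuzzified))
  strengths <- vapply(engine$rules, function(r) {
    degs <- vapply(r$antecedents, function(a) {
      fv <- fuzzified[[a$variable]]
      if (is.null(fv))
        stop("fuzzified inputs missing variable '", a$variable, "'",
             call. = FALSE)
      fv[[a$term]]
    }, numeric(1))
    min(degs)
  }, numeric(1))
  data.frame(rule_id = vapply(engine$rules, `[[`, integer(1), "id"),
             strength = strengths,
             consequent = vapply(engine$rules, `[[`, character(1),
                                 "consequent"),
             stringsAsFactors = FALSE)
}

#' Aggregate activated output sets (Mamdani max-min)
#'
#' Each activated rule's consequent set is clipped (pointwise minimum) at
#' the rule's activation strength; the clipped sets are combined by
#' pointwise maximum into a single output membership function over the
#' score domain. The result is an exact piecewise-linear function (vertex
#' matrix), suitable for closed-form centroid computation.
#'
#' @param engine A [fuzzy_engine()].
#' @param activations Data.frame from [fire_rules()].
#' @return Two-column matrix of `(x, y)` vertices over the output domain.
#' @export
aggregate_output <- function(engine, activations) {
  stopifnot(inherits(engine, "fuzzy_engine"), is.data.frame(activations))
  act <- activations[activations$strength > 0, , drop = FALSE]
  if (nrow(act) == 0L)
    stop("degenerate output: no rule activated", call. = FALSE)
  dom <- engine$output$domain
  clipped <- lapply(seq_len(nrow(act)), function(i)
    pwl_clip(engine$output$sets[[act$consequent[i]]], act$strength[i], dom))
  pwl_max(clipped)
}

#' Centroid defuzzification
#'
#' Collapses the aggregated output membership function to one crisp score:
#' the area-weighted mean abscissa, computed in closed form from the
#' piecewise-linear vertices. The score always lies inside the support of
#' the aggregated function, hence in the `[0, 10]` output domain.
#'
#' @param aggregated Vertex matrix from [aggregate_output()].
#' @return Crisp score (single numeric).
#' @export
defuzzify_centroid <- function(aggregated) {
  stopifnot(is.matrix(aggregated), ncol(aggregated) == 2L)
  pwl_centroid(aggregated)
}

#' Classify activations into a clinical situation
#'
#' The winning rule is the one with maximal activation strength; its
#' consequent is the situation label and its message/urgency accompany the
#' alert. Ties are broken safety-first: higher urgency wins, then the lower
#' rule id.
#'
#' @param engine A [fuzzy_engine()].
#' @param activations Data.frame from [fire_rules()].
#' @return List with `label`, `urgency`, `message`, `rule_id`.
#' @export
classify_situation <- function(engine, activations) {
  stopifnot(inherits(engine, "fuzzy_engine"), is.data.frame(activations))
  if (all(activations$strength <= 0))
    stop("degenerate output: no rule activated", call. = FALSE)
  ids <- vapply(engine$rules, `[[`, integer(1), "id")
  urg <- vapply(engine$rules, `[[`, character(1), "urgency")
  pos <- match(activations$rule_id, ids)
  if (anyNA(pos)) stop("activation for unknown rule id", call. = FALSE)
  ord <- order(-activations$strength,
               -match(urg[pos], urgency_levels),
               activations$rule_id)
  win <- engine$rules[[pos[ord[1L]]]]
  list(label = win$consequent, urgency = win$urgency,
       message = win$message, rule_id = win$id)
}

#' Run the full fuzzy pre-diagnosis pipeline
#'
#' Fuzzification, six-rule Mamdani min-max inference, centroid
#' defuzzification onto the `[0, 10]` pre-diagnosis scale, and
#' classification into one of the five clinical situations. Deterministic:
#' identical inputs give identical output.
#'
#' @param engine A [fuzzy_engine()].
#' @param mbp Mean blood pressure, mmHg.
#' @param spo2 Oxygen saturation, percent.
#' @return An object of class `pre_diagnosis`: inputs, rule activations,
#'   crisp `score`, situation `label`, `urgency` and `message`.
#' @examples
#' eng <- default_engine()
#' infer(eng, mbp = 33, spo2 = 94)
#' @export
infer <- function(engine, mbp, spo2) {
  stopifnot(inherits(engine, "fuzzy_engine"))
  fz <- list(MBP = fuzzify(engine$variables$MBP, mbp),
             SpO2 = fuzzify(engine$variables$SpO2, spo2))
  act <- fire_rules(engine, fz)
  agg <- aggregate_output(engine, act)
  score <- defuzzify_centroid(agg)
  cls <- classify_situation(engine, act)
  structure(list(inputs = c(MBP = mbp, SpO2 = spo2),
                 fuzzified = fz, activations = act, score = score,
                 label = cls$label, urgency = cls$urgency,
                 message = cls$message, rule_id = cls$rule_id),
            class = "pre_diagnosis")
}

#' @export
print.pre_diagnosis <- function(x, ...) {
  cat(sprintf("<pre_diagnosis> MBP=%g mmHg, SpO2=%g%% -> %s (score %.3f, urgency %s)\n",
              x$inputs[["MBP"]], x$inputs[["SpO2"]], x$label, x$score,
              x$urgency))
  cat("  ", x$message, "\n", sep = "")
  invisible(x)
}
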