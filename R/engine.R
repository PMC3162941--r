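#' @keywords internal
urgency_levels <- c("none", "low", "medium", "high")

#' Fuzzy inference rule
#'
#' One IF-AND-THEN rule: a conjunction of (variable, term) antecedents, an
#' output term as consequent, and the alert metadata attached to that
#' clinical situation (display message and urgency level).
#'
#' @param id Integer rule identifier (unique within a rule base).
#' @param antecedents List of `list(variable =, term =)` pairs, combined
#'   with AND (minimum).
#' @param consequent Output term name (one of the clinical situations).
#' @param message Display string shown when this rule wins.
#' @param urgency One of `"none"`, `"low"`, `"medium"`, `"high"`.
#' @return An object of class `fuzzy_rule`.
#' @export
fuzzy_rule <- function(id, antecedents, consequent, message,
                       urgency = "none") {
  stopifnot(length(id) == 1L, is.numeric(id),
            is.list(antecedents), length(antecedents) >= 1L,
            is.character(consequent), length(consequent) == 1L,
            is.character(message), length(message) == 1L)
  urgency <- match.arg(urgency, urgency_levels)
  for (a in antecedents)
    if (is.null(a$variable) || is.null(a$term))
      stop("each antecedent needs 'variable' and 'term'", call. = FALSE)
  structure(list(id = as.integer(id), antecedents = antecedents,
                 consequent = consequent, message = message,
                 urgency = urgency),
            class = "fuzzy_rule")
}

#' @export
print.fuzzy_rule <- function(x, ...) {
  ante <- paste(vapply(x$antecedents,
                       function(a) paste(a$term, a$variable), character(1)),
                collapse = " AND ")
  cat(sprintf("<rule %d> IF %s THEN %s [%s]\n",
              x$id, ante, x$consequent, x$urgency))
  invisible(x)
}

#' Assemble a fuzzy monitoring engine
#'
#' Binds input linguistic variables, the output (pre-diagnosis) variable and
#' the rule base into one validated engine. Every term referenced by a rule
#' must exist; dangling references are rejected at construction time.
#'
#' @param variables Named list of input [linguistic_variable()]s.
#' @param output The output [linguistic_variable()] on the `[0, 10]` scale.
#' @param rules List of [fuzzy_rule()]s.
#' @param monitoring List of stream-processing options: `debounce_seconds`
#'   (repeat-alert suppression window per label, default 0) and
#'   `stale_gap_seconds` (missing-data gap before a sensor-fault notice,
#'   default 30).
#' @return An object of class `fuzzy_engine`.
#' @seealso [default_engine()], [load_config()], [infer()]
#' @export
fuzzy_engine <- function(variables, output, rules,
                         monitoring = list()) {
  stopifnot(is.list(variables), length(variables) >= 1L,
            all(vapply(variables, inherits, logical(1),
                       "linguistic_variable")),
            inherits(output, "linguistic_variable"),
            is.list(rules), length(rules) >= 1L,
            all(vapply(rules, inherits, logical(1), "fuzzy_rule")))
  names(variables) <- vapply(variables, `[[`, character(1), "name")
  for (r in rules) {
    for (a in r$antecedents) {
      v <- variables[[a$variable]]
      if (is.null(v))
        stop("rule ", r$id, ": unknown variable '", a$variable, "'",
             call. = FALSE)
      if (is.null(v$sets[[a$term]]))
        stop("rule ", r$id, ": variable '", a$variable,
             "' has no term '", a$term, "'", call. = FALSE)
    }
    if (is.null(output$sets[[r$consequent]]))
      stop("rule ", r$id, ": output has no term '", r$consequent, "'",
           call. = FALSE)
  }
  ids <- vapply(rules, `[[`, integer(1), "id")
  if (anyDuplicated(ids)) stop("duplicate rule ids", call. = FALSE)
  mon <- utils::modifyList(list(debounce_seconds = 0,
                                stale_gap_seconds = 30),
                           monitoring)
  structure(list(variables = variables, output = output,
                 rules = rules[order(ids)], monitoring = mon),
            class = "fuzzy_engine")
}

#' @export
print.fuzzy_engine <- function(x, ...) {
  cat("<fuzzy_engine> ", length(x$variables), " input variable(s), ",
      length(x$rules), " rules, output '", x$output$name, "' on [",
      x$output$domain[1L], ", ", x$output$domain[2L], "]\n", sep = "")
  invisible(x)
}

#' The shipped default ICU monitoring engine
#'
#' Builds the engine from the default configuration installed with the
#' package: mean blood pressure (low/normal/high over 0-200 mmHg) and
#' oxygen saturation (low/normal over 0-100 %) membership breakpoints, the
#' six-rule Mamdani base covering every MBP-term x SpO2-term combination,
#' and the five output situations supported on the pre-diagnosis bands
#' (<2.5, 2.5-4.5, 4-6, 5.5-8, >8).
#'
#' @return A [fuzzy_engine()].
#' @examples
#' eng <- default_engine()
#' infer(eng, mbp = 98, spo2 = 94)
#' @export
default_engine <- function() {
  load_config(system.file("extdata", "default_config.yaml",
                          package = "vitalfuzz", mustWork = TRUE))
}

config_to_engine <- function(cfg) {
  build_var <- function(v) {
    sets <- lapply(v$sets, function(s)
      fuzzy_set(s$name, do.call(rbind, lapply(s$points, as.numeric))))
    linguistic_variable(v$name, v$units, as.numeric(v$domain), sets)
  }
  vars <- lapply(cfg$variables, build_var)
  out <- build_var(cfg$output)
  rules <- lapply(cfg$rules, function(r)
    fuzzy_rule(r$id, r$antecedents, r$consequent, r$message,
               if (is.null(r$urgency)) "none" else r$urgency))
  fuzzy_engine(vars, out, rules,
               if (is.null(cfg$monitoring)) list() else cfg$monitoring)
}

engine_to_config <- function(engine) {
  var_to_list <- function(v) list(
    name = v$name, units = v$units, domain = as.list(v$domain),
    sets = unname(lapply(v$sets, function(s) list(
      name = s$name,
      points = unname(apply(s$points, 1L, as.list, simplify = FALSE))))))
  list(
    variables = unname(lapply(engine$variables, var_to_list)),
    output = var_to_list(engine$output),
    rules = unname(lapply(engine$rules, function(r) list(
      id = r$id,
      antecedents = lapply(r$antecedents, function(a)
        list(variable = a$variable, term = a$term)),
      consequent = r$consequent, message = r$message,
      urgency = r$urgency))),
    monitoring = engine$monitoring)
}

#' Load an engine configuration
#'
#' Reads a YAML configuration document listing the input variables (domains
#' and membership breakpoints), the output variable with its situation
#' bands, the rule base with messages and urgency levels, and optional
#' monitoring settings. The document is fully validated: parse failures,
#' missing fields and rules referencing undefined terms are rejected with
#' an informative error.
#'
#' @param path Path to a YAML configuration file.
#' @return A validated [fuzzy_engine()].
#' @export
load_config <- function(path) {
  if (!file.exists(path))
    stop("config file not found: ", path, call. = FALSE)
  cfg <- tryCatch(yaml::read_yaml(path),
                  error = function(e)
                    stop("failed to parse config '", path, "': ",
                         conditionMessage(e), call. = FALSE))
  for (field in c("variables", "output", "rules"))
    if (is.null(cfg[[field]]))
      stop("config '", path, "': missing required section '", field, "'",
           call. = FALSE)
  config_to_engine(cfg)
}

#' Save an engine configuration
#'
#' Serializes an engine back to the YAML schema read by [load_config()].
#' `load_config(save_config(engine, path))` reproduces the engine exactly.
#'
#' @param engine A [fuzzy_engine()].
#' @param path Destination file path.
#' @return `path`, invisibly.
#' @export
save_config <- function(engine, path) {
  stopifnot(inherits(engine, "fuzzy_engine"))
  yaml::write_yaml(engine_to_config(engine), path)
  invisible(path)
}
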