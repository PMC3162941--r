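# Seeded synthetic vital-sign streams emulating per-second multi-channel
# ICU monitor records, so the whole pipeline is exercisable without any
# patient data.

# Characteristic input regions per clinical situation, placed at the cores
# (peaks/plateaus) of the membership functions that define each state.
# Extra channels carry adult resting norms and are inert passthrough.
state_means <- function(state) {
  switch(state,
         stable      = c(MBP = 105, SpO2 = 97),
         low_MBP     = c(MBP = 60,  SpO2 = 97),
         hypoxemia   = c(MBP = 105, SpO2 = 85),
         instability = c(MBP = 55,  SpO2 = 85),
         high_MBP    = c(MBP = 150, SpO2 = 97),
         stop("unknown state '", state, "'", call. = FALSE))
}

situation_labels <- function() {
  c("instability", "low_MBP", "hypoxemia", "stable", "high_MBP")
}

#' Scenario segment
#'
#' One homogeneous stretch of a synthetic monitoring scenario: a duration
#' in seconds, a target clinical state (or explicit channel means), a
#' per-channel Gaussian noise level and an artifact rate.
#'
#' @param duration Length in seconds (>= 1); records are emitted at 1 Hz.
#' @param state One of `"instability"`, `"low_MBP"`, `"hypoxemia"`,
#'   `"stable"`, `"high_MBP"`, or `NULL` when `means` is given.
#' @param means Optional named vector overriding channel means, e.g.
#'   `c(MBP = 70, SpO2 = 93)`.
#' @param noise Gaussian standard deviation applied to MBP (mmHg) and, at
#'   a quarter of the value, to SpO2 (%); default 0.
#' @param artifact_rate Per-tick probability in `[0, 1]` of an artifact
#'   (sensor dropout or transient spike); default 0.
#' @return An object of class `scenario_segment`.
#' @export
scenario_segment <- function(duration, state = NULL, means = NULL,
                             noise = 0, artifact_rate = 0) {
  stopifnot(length(duration) == 1L, duration >= 1,
            noise >= 0, artifact_rate >= 0, artifact_rate <= 1)
  if (is.null(means)) {
    if (is.null(state)) stop("give either 'state' or 'means'",
                             call. = FALSE)
    means <- state_means(state)
  }
  stopifnot(all(c("MBP", "SpO2") %in% names(means)))
  structure(list(duration = as.integer(duration), state = state,
                 means = means, noise = noise,
                 artifact_rate = artifact_rate),
            class = "scenario_segment")
}

#' Generate a synthetic per-second vital-sign stream
#'
#' Concatenates scenario segments into a 1 Hz multi-channel record stream.
#' Each tick draws MBP and SpO2 from the segment's target means plus
#' Gaussian noise (values clamped to physiologic domains), derives
#' consistent systolic/diastolic pressures (SBP = MBP + 25,
#' DBP = MBP - 12.5, so the MAP identity (SBP + 2 DBP)/3 recovers MBP) and
#' emits adult-normal HR, RR and temperature as passthrough channels.
#' Artifacts either blank the pressure and saturation channels (dropout)
#' or inject an out-of-range spike. Identical seeds give identical
#' streams.
#'
#' @param segments List of [scenario_segment()]s (a single segment may be
#'   passed bare).
#' @param patient_id Patient identifier string.
#' @param seed Integer seed; reproducibility is mandatory.
#' @param start Start timestamp (POSIXct or ISO string).
#' @return Wide data.frame of records compatible with [process_stream()].
#' @examples
#' seg <- scenario_segment(10, "stable")
#' generate_stream(list(seg), "p1", seed = 1)[1:3, ]
#' @export
generate_stream <- function(segments, patient_id, seed,
                            start = "2026-01-01T00:00:00") {
  if (inherits(segments, "scenario_segment")) segments <- list(segments)
  if (!is.list(segments) || length(segments) == 0L ||
      !all(vapply(segments, inherits, logical(1), "scenario_segment")))
    stop("'segments' must be a non-empty list of scenario_segment",
         call. = FALSE)
  stopifnot(length(seed) == 1L, is.numeric(seed))
  t0 <- parse_timestamp(start)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  rows <- list(); tick <- 0L
  for (seg in segments) {
    for (k in seq_len(seg$duration)) {
      mbp <- min(max(stats::rnorm(1, seg$means[["MBP"]], seg$noise), 0),
                 200)
      spo2 <- min(max(stats::rnorm(1, seg$means[["SpO2"]],
                                   seg$noise / 4), 0), 100)
      rec <- data.frame(
        patient_id = patient_id,
        timestamp = t0 + tick,
        ABP_mean = mbp, ABP_sys = mbp + 25, ABP_dia = mbp - 12.5,
        SpO2 = spo2, HR = 80, RR = 16, Temp = 36.5,
        stringsAsFactors = FALSE)
      if (seg$artifact_rate > 0 &&
          stats::runif(1) < seg$artifact_rate) {
        if (stats::runif(1) < 0.5) {            # dropout
          rec$ABP_mean <- NA; rec$ABP_sys <- NA
          rec$ABP_dia <- NA; rec$SpO2 <- NA
        } else {                                # spike
          rec$ABP_mean <- 300; rec$SpO2 <- 120
        }
      }
      rows[[length(rows) + 1L]] <- rec
      tick <- tick + 1L
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Generate a fuzzy-labelled (MBP, SpO2) dataset
#'
#' Draws input pairs class by class from each situation's characteristic
#' region (Gaussian around the membership-function cores, clamped to the
#' variable domains) and labels every pair by running the fuzzy engine, so
#' the stored label is by construction the engine's own inference.
#'
#' @param n Number of rows (>= 1).
#' @param class_mix Named proportions over the five situations, summing
#'   to 1; default uniform.
#' @param seed Integer seed.
#' @param engine Engine used for labelling; default [default_engine()].
#' @param sd_mbp,sd_spo2 Sampling spread around each class core (mmHg, %).
#' @return Data.frame with columns `MBP`, `SpO2`, `class` (the sampled
#'   region) and `label` (the engine's inference).
#' @export
generate_labelled_dataset <- function(n, class_mix = NULL, seed = 1,
                                      engine = default_engine(),
                                      sd_mbp = 8, sd_spo2 = 1.5) {
  stopifnot(n >= 1)
  labs <- situation_labels()
  if (is.null(class_mix)) class_mix <- stats::setNames(rep(0.2, 5), labs)
  if (is.null(names(class_mix)) ||
      !all(names(class_mix) %in% labs) ||
      any(class_mix < 0) || abs(sum(class_mix) - 1) > 1e-8 ||
      all(class_mix == 0))
    stop("'class_mix' must be named proportions over the five situations summing to 1",
         call. = FALSE)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  cls <- sample(names(class_mix), n, replace = TRUE, prob = class_mix)
  mu <- t(vapply(cls, state_means, numeric(2)))
  mbp <- pmin(pmax(stats::rnorm(n, mu[, 1L], sd_mbp), 0), 200)
  spo2 <- pmin(pmax(stats::rnorm(n, mu[, 2L], sd_spo2), 0), 100)
  label <- vapply(seq_len(n),
                  function(i) infer(engine, mbp[i], spo2[i])$label,
                  character(1))
  data.frame(MBP = mbp, SpO2 = spo2, class = cls, label = label,
             stringsAsFactors = FALSE)
}

#' Stratified train/test split
#'
#' Splits a labelled dataset into disjoint train and test parts,
#' stratifying on the label column so every class keeps (approximately)
#' the requested training proportion.
#'
#' @param dataset Data.frame with a `label` column.
#' @param train_prop Proportion assigned to training; default 0.8.
#' @param seed Integer seed.
#' @return List with `train` and `test` data.frames.
#' @export
stratified_split <- function(dataset, train_prop = 0.8, seed = 1) {
  stopifnot(is.data.frame(dataset), "label" %in% names(dataset),
            train_prop > 0, train_prop < 1)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  idx <- unlist(lapply(split(seq_len(nrow(dataset)), dataset$label),
                       function(ii) sample(ii, round(length(ii) *
                                                       train_prop))))
  list(train = dataset[sort(idx), , drop = FALSE],
       test = dataset[setdiff(seq_len(nrow(dataset)), idx), ,
                      drop = FALSE])
}
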