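fz_for <- function(eng, mbp, spo2) {
  list(MBP = fuzzify(eng$variables$MBP, mbp),
       SpO2 = fuzzify(eng$variables$SpO2, spo2))
}

test_that("rule activations are the min of antecedent degrees", {
  eng <- test_engine()
  # low MBP with borderline-normal saturation: only the low-MBP rule fires
  act <- fire_rules(eng, fz_for(eng, 33, 94))
  expect_equal(act$strength[act$rule_id == 2], 4.8 / 7)
  expect_equal(sum(act$strength > 0), 1L)
  # high-normal MBP with low saturation: only the hypoxemia rule fires
  act <- fire_rules(eng, fz_for(eng, 126, 87))
  expect_equal(act$strength[act$rule_id == 3], 0.16)
  expect_equal(sum(act$strength > 0), 1L)
  # both inputs at their membership peaks: the stable rule at full strength
  act <- fire_rules(eng, fz_for(eng, 105, 96.2))
  expect_equal(act$strength[act$rule_id == 4], 1.0)
  expect_equal(sum(act$strength > 0), 1L)
})

test_that("fire_rules demands every referenced variable", {
  eng <- test_engine()
  expect_error(fire_rules(eng, list(MBP = c(low = 1, normal = 0,
                                            high = 0))),
               "missing variable")
})

test_that("aggregation is the pointwise max of clipped consequent sets", {
  eng <- test_engine()
  act1 <- data.frame(rule_id = 4L, strength = 0.52, consequent = "stable")
  agg1 <- aggregate_output(eng, act1)
  grid <- seq(0, 10, by = 0.001)
  ref <- pmin(oracle_interp(eng$output$sets$stable$points, grid), 0.52)
  expect_lt(max(abs(oracle_interp(agg1, grid) - ref)), 1e-12)

  # a zero activation contributes nothing
  act2 <- rbind(act1, data.frame(rule_id = 3L, strength = 0,
                                 consequent = "hypoxemia"))
  expect_equal(aggregate_output(eng, act2), agg1)

  # two positive activations: dense-grid max oracle
  act3 <- data.frame(rule_id = c(1L, 2L), strength = c(0.5, 0.4),
                     consequent = c("instability", "low_MBP"))
  agg3 <- aggregate_output(eng, act3)
  ref3 <- pmax(
    pmin(oracle_interp(eng$output$sets$instability$points, grid), 0.5),
    pmin(oracle_interp(eng$output$sets$low_MBP$points, grid), 0.4))
  expect_lt(max(abs(oracle_interp(agg3, grid) - ref3)), 1e-12)

  expect_error(aggregate_output(eng, data.frame(rule_id = 1L,
                                                strength = 0,
                                                consequent = "stable")),
               "degenerate")
})

test_that("clipped symmetric sets defuzzify to their axis of symmetry", {
  eng <- test_engine()
  for (h in c(0.1, 0.5, 1)) {
    act <- data.frame(rule_id = 3L, strength = h,
                      consequent = "hypoxemia")
    expect_equal(defuzzify_centroid(aggregate_output(eng, act)), 5)
    act <- data.frame(rule_id = 2L, strength = h, consequent = "low_MBP")
    expect_equal(defuzzify_centroid(aggregate_output(eng, act)), 3.5)
  }
})

test_that("closed-form centroid matches 10,000-point numeric integration", {
  eng <- test_engine()
  set.seed(303)
  for (i in 1:50) {
    mbp <- runif(1, 0, 200); spo2 <- runif(1, 0, 100)
    act <- fire_rules(eng, fz_for(eng, mbp, spo2))
    agg <- aggregate_output(eng, act)
    expect_equal(defuzzify_centroid(agg), oracle_centroid_grid(agg),
                 tolerance = 1e-6)
  }
})

test_that("classification follows the maximal rule with safety-first ties", {
  eng <- test_engine()
  cases <- list(list(33, 94, "low_MBP", "low"),
                list(126, 87, "hypoxemia", "high"),
                list(98, 94, "stable", "none"))
  for (cs in cases) {
    act <- fire_rules(eng, fz_for(eng, cs[[1]], cs[[2]]))
    cls <- classify_situation(eng, act)
    expect_equal(cls$label, cs[[3]])
    expect_equal(cls$urgency, cs[[4]])
  }
  # exact tie between the instability rule (high) and the low-MBP rule
  # (low): higher urgency wins
  tie <- data.frame(rule_id = c(1L, 2L), strength = c(0.5, 0.5),
                    consequent = c("instability", "low_MBP"))
  expect_equal(classify_situation(eng, tie)$label, "instability")
  expect_error(classify_situation(eng,
                                  data.frame(rule_id = 1L, strength = 0,
                                             consequent = "instability")),
               "degenerate")
})

test_that("infer composes the pipeline deterministically", {
  eng <- test_engine()
  a <- infer(eng, 77, 91.3)
  b <- infer(eng, 77, 91.3)
  expect_identical(a, b)
  expect_s3_class(a, "pre_diagnosis")
  expect_true(a$score >= 0 && a$score <= 10)
  expect_equal(a$message,
               eng$rules[[a$rule_id]]$message)
})

test_that("a single activated rule confines the score to its band", {
  eng <- test_engine()
  set.seed(404)
  found <- 0L
  for (i in 1:500) {
    mbp <- runif(1, 0, 200); spo2 <- runif(1, 0, 100)
    pd <- infer(eng, mbp, spo2)
    if (sum(pd$activations$strength > 0) == 1L) {
      band <- situation_bands[[pd$label]]
      expect_gte(pd$score, band[1L])
      expect_lte(pd$score, band[2L])
      found <- found + 1L
    }
  }
  expect_gt(found, 100L)  # single-rule inputs are common, not corner cases
})
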