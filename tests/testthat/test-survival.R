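test_that("composite score is the mean of oriented z-scores", {
  set.seed(15)
  act <- matrix(rnorm(4 * 20), 4,
                dimnames = list(paste0("SN", 1:4), sprintf("s%02d", 1:20)))
  comp <- composite_score(act, c("SN1", "SN3"))
  manual <- colMeans(rbind(
    (act["SN1", ] - mean(act["SN1", ])) / sd(act["SN1", ]),
    (act["SN3", ] - mean(act["SN3", ])) / sd(act["SN3", ])))
  expect_equal(unname(comp), unname(manual), tolerance = 1e-12)

  # one subnetwork: composite equals its z-score
  one <- composite_score(act, "SN2")
  expect_equal(unname(one),
               unname((act["SN2", ] - mean(act["SN2", ])) / sd(act["SN2", ])),
               tolerance = 1e-12)
  # identical rows: same as either one
  act2 <- act; act2["SN4", ] <- act2["SN1", ]
  expect_equal(composite_score(act2, c("SN1", "SN4")),
               composite_score(act2, "SN1"), tolerance = 1e-12)
  # orientation flips negatively associated subnetworks
  flipped <- composite_score(act, c("SN1", "SN3"),
                             orientation = c(SN1 = 2, SN3 = -1))
  z3 <- (act["SN3", ] - mean(act["SN3", ])) / sd(act["SN3", ])
  expect_equal(unname(flipped), unname(manual - z3), tolerance = 1e-12)
  # zero-variance rows are excluded with a warning
  act3 <- act; act3["SN2", ] <- 5
  expect_warning(c3 <- composite_score(act3, c("SN1", "SN2")), "zero-variance")
  expect_equal(c3, composite_score(act3, "SN1"), tolerance = 1e-12)
})

test_that("risk-group assignment follows the strict median rule", {
  g <- assign_risk_groups(c(a = 1, b = 2, c = 3, d = 4))
  expect_equal(unname(g), c("low_risk", "low_risk", "high_risk", "high_risk"),
               ignore_attr = TRUE)
  same <- assign_risk_groups(rep(2, 5))
  expect_true(all(same == "low_risk"))
  expect_true(attr(same, "degenerate"))
  set.seed(3)
  s <- rnorm(101)
  expect_equal(sum(assign_risk_groups(s) == "high_risk"), 50)
  expect_error(assign_risk_groups(1), class = "snm_invalid_input")
})

test_that("KM estimator matches hand-computed product-limit tables", {
  # all censored: survival stays at 1
  km0 <- km_estimate(c(3, 5, 8), c(0, 0, 0))
  expect_length(km0$event_times, 0)
  expect_equal(km_at(km0, 10), 1)

  # three events, no censoring
  km1 <- km_estimate(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km1$event_times, c(1, 2, 3))
  expect_equal(km1$survival_prob, c(2 / 3, 1 / 3, 0), tolerance = 1e-12)

  # hand-computed 6-record table with a tie and interleaved censoring:
  # records (2,1) (3,0) (3,1) (5,1) (5,1) (7,0)
  # t=2: 6 at risk, 1 event -> 5/6
  # t=3: 5 at risk (censored-at-3 still at risk at 3), 1 event -> 2/3
  # t=5: 3 at risk, 2 events -> 2/3 * 1/3 = 2/9
  km2 <- km_estimate(c(2, 3, 3, 5, 5, 7), c(1, 0, 1, 1, 1, 0))
  expect_equal(km2$event_times, c(2, 3, 5))
  expect_equal(km2$at_risk, c(6, 5, 3))
  expect_equal(km2$n_events, c(1, 1, 2))
  expect_equal(km2$survival_prob, c(5 / 6, 2 / 3, 2 / 9), tolerance = 1e-12)

  # without censoring S at the last event time is (still alive)/n
  set.seed(41)
  t <- round(rexp(20, 0.1), 3)
  km3 <- km_estimate(t, rep(1, 20))
  expect_equal(km_at(km3, max(t)), 0)
  expect_true(all(diff(km3$survival_prob) <= 1e-12))
  expect_true(all(km3$survival_prob >= 0 & km3$survival_prob <= 1))
  expect_error(km_estimate(-1, 1), class = "snm_invalid_input")
})

test_that("log-rank test matches the textbook formula oracle", {
  set.seed(27)
  time <- c(round(rexp(5, 0.1), 2), round(rexp(5, 0.4), 2))
  event <- rbinom(10, 1, 0.8)
  group <- rep(c("a", "b"), each = 5)
  if (sum(event) == 0) event[1] <- 1
  got <- logrank_test(time, event, group)
  want <- oracle_logrank(time, event, group)
  expect_equal(got$chi_square, want$chi_square, tolerance = 1e-8)
  expect_equal(got$p, want$p, tolerance = 1e-8)

  # identical groups: chi-square 0, p 1
  t2 <- c(1, 2, 3, 1, 2, 3); e2 <- c(1, 1, 0, 1, 1, 0)
  same <- logrank_test(t2, e2, rep(c("a", "b"), each = 3))
  expect_equal(same$chi_square, 0, tolerance = 1e-12)
  expect_equal(same$p, 1, tolerance = 1e-12)
  # symmetry under group swap
  swap <- logrank_test(time, event, rev(group))
  expect_equal(logrank_test(time, event, group)$chi_square,
               swap$chi_square, tolerance = 1e-8)
  # time rescaling leaves the statistic unchanged
  scaled <- logrank_test(time * 7.3, event, group)
  expect_equal(scaled$chi_square, got$chi_square, tolerance = 1e-10)
  # no events: flagged p = 1
  none <- logrank_test(c(1, 2, 3, 4), c(0, 0, 0, 0), rep(c("a", "b"), 2))
  expect_true(none$degenerate)
  expect_equal(none$p, 1)
})

test_that("stratified analysis reduces to the unstratified test and skips bad strata", {
  clin <- random_clinical(40, seed = 5)
  clin$er_status <- NULL
  scores <- setNames(rnorm(40), clin$sample_id)
  res <- stratified_analysis(clin, scores, strata = "all")
  expect_named(res, "all")
  direct <- logrank_test(clin$survival_time, clin$event,
                         unname(assign_risk_groups(scores[clin$sample_id])))
  expect_equal(res$all$chi_square, direct$chi_square, tolerance = 1e-10)
  expect_equal(res$all$n_high + res$all$n_low, 40)

  # ER strata are analyzed independently; a single-group stratum is skipped
  clin2 <- random_clinical(30, seed = 6)
  scores2 <- setNames(rnorm(30), clin2$sample_id)
  # force every ER-negative sample into one risk group
  hi <- names(sort(scores2, decreasing = TRUE))[1:15]
  clin2$er_status <- ifelse(clin2$sample_id %in% hi, "negative", "positive")
  clin2$er_status[match(hi[1], clin2$sample_id)] <- "positive"
  expect_warning(res2 <- stratified_analysis(clin2, scores2),
                 "single risk group")
  expect_true("er_positive" %in% names(res2))
  expect_false("er_negative" %in% names(res2))
})
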