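test_that("the generator is deterministic in its seed", {
  p <- base_params()
  t1 <- generate_trial(7, 2000, 0.24, p$prevalence, p$accuracy, 0.9)
  t2 <- generate_trial(7, 2000, 0.24, p$prevalence, p$accuracy, 0.9)
  expect_identical(t1$detected, t2$detected)
  expect_identical(t1$state, t2$state)
  t3 <- generate_trial(8, 2000, 0.24, p$prevalence, p$accuracy, 0.9)
  expect_false(identical(t1$tff3_pos, t3$tff3_pos))
})

test_that("zero uptake yields a usual-care-like empty funnel", {
  p <- base_params()
  tr <- generate_trial(1, 500, 0, p$prevalence, p$accuracy, 1)
  expect_equal(sum(tr$attended), 0)
  expect_equal(tr$scenario$n_swallowed, 0)
  expect_equal(sum(tr$detected), 0)
})

test_that("a perfect funnel detects exactly the prevalent disease", {
  p <- base_params()
  acc <- list(sensitivity = 1, specificity = 1)
  tr <- generate_trial(3, 3000, 1, p$prevalence, acc, 1)
  expect_equal(sum(tr$detected), sum(tr$state != "NoBE"))
  expect_equal(tr$scenario$n_swallowed, 3000)
  # no false positives: referrals equal true disease
  expect_equal(tr$scenario$n_referred, sum(tr$state != "NoBE"))
})

test_that("funnel aggregates match analytic expectations within 3 binomial SEs", {
  p <- base_params()
  n <- 6834
  up <- p$scenario$uptake
  att <- 198 / 221
  tr <- generate_trial(11, n, up, p$prevalence, p$accuracy, att)
  # tests administered
  expect_lt(abs(sum(tr$attended) - n * up), 3 * sqrt(n * up * (1 - up)))
  # detected BE-or-cancer (scale of the trial's 131)
  prev <- sum(p$prevalence)
  p_det <- up * prev * p$accuracy$sensitivity * att
  expect_lt(abs(sum(tr$detected) - n * p_det),
            3 * sqrt(n * p_det * (1 - p_det)))
  expect_true(all(tr$detected <= vapply(prevalent_states(), function(s) {
    sum(tr$state == s & tr$attended)
  }, numeric(1))))
})

test_that("prevalence inversion is exact for a perfect funnel", {
  p <- base_params()
  acc <- list(sensitivity = 1, specificity = 1)
  tr <- generate_trial(5, 4000, 1, p$prevalence, acc, 1)
  est <- recover_prevalence(tr, acc)
  expect_equal(est$estimate, mean(tr$state != "NoBE"))
})

test_that("prevalence recovery is unbiased across replicate trials", {
  p <- base_params()
  truth <- sum(p$prevalence)
  ests <- vapply(1:200, function(s) {
    tr <- generate_trial(1000 + s, 6834, p$scenario$uptake, p$prevalence,
                         p$accuracy, 198 / 221)
    recover_prevalence(tr, p$accuracy)$estimate
  }, numeric(1))
  expect_lt(abs(mean(ests) - truth), 2 * sd(ests) / sqrt(length(ests)))
})

test_that("halving sensitivity halves detections but not the estimate", {
  p <- base_params()
  acc_half <- list(sensitivity = 0.5, specificity = 1)
  ests <- vapply(1:80, function(s) {
    tr <- generate_trial(3000 + s, 6834, 0.5, p$prevalence, acc_half, 1)
    recover_prevalence(tr, acc_half)$estimate
  }, numeric(1))
  truth <- sum(p$prevalence)
  expect_lt(abs(mean(ests) - truth), 3 * sd(ests) / sqrt(length(ests)))
})

test_that("a synthetic trial runs end-to-end with all invariants intact", {
  p <- base_params()
  tr <- generate_trial(21, 6834, p$scenario$uptake, p$prevalence,
                       p$accuracy, 198 / 221)
  det <- list(intervention = tr$detected,
              usual = c(NDBE = 0, LGD = 0, HGD = 0, EarlyEAC = 0))
  # totals must cover the detected counts: use realised disease counts
  realised <- vapply(prevalent_states(), function(s) sum(tr$state == s),
                     numeric(1))
  prev_real <- realised / tr$n_invited
  a <- allocate_from_trial(tr$scenario, p$accuracy, prev_real, det,
                           tr$n_invited)
  p2 <- p
  p2$settings$cohort_size <- tr$n_invited
  sc_cost <- screening_cost(tr$scenario, p$costs)
  t_int <- run_cohort(a, "intervention", p2, sc_cost$total_intervention)
  t_usu <- run_cohort(a, "usual", p2, 0)
  for (trace in list(t_int, t_usu)) {
    tot <- rowSums(apply(trace$occupancy, c(1, 3), sum))
    expect_equal(tot, rep(tr$n_invited, length(tot)),
                 tolerance = 1e-9 * tr$n_invited, ignore_attr = TRUE)
  }
  ce <- incremental_analysis(t_int, t_usu)
  expect_true(ce$delta_qaly == 0 || is.finite(ce$icer))
})

test_that("the repeat-test pathway reproduces repeat-round volumes in expectation", {
  p <- base_params()
  tr <- generate_trial(9, 6834, p$scenario$uptake, p$prevalence,
                       p$accuracy, 198 / 221,
                       inadequate_fraction = 311 / 1654,
                       retest_attendance = 202 / 311)
  n_rep <- tr$scenario$n_repeat_tests
  expected <- 6834 * p$scenario$uptake * (311 / 1654) * (202 / 311)
  expect_lt(abs(n_rep - expected), 3 * sqrt(expected))
  expect_true(tr$scenario$include_repeat)
})

test_that("trial outputs are written in the dialect cohort entry reads", {
  p <- base_params()
  tr <- generate_trial(2, 800, 0.3, p$prevalence, p$accuracy, 1)
  tmp <- file.path(tempdir(), "trial_out")
  files <- write_trial(tr, tmp)
  expect_true(all(file.exists(files)))
  sc <- yaml::read_yaml(files[1])$scenario
  expect_equal(sc$n_swallowed, tr$scenario$n_swallowed)
  det <- read.csv(files[2])
  expect_equal(det$detected, unname(tr$detected))
  unlink(tmp, recursive = TRUE)
})
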