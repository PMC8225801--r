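test_that("transition matrices are row-stochastic at every model age", {
  p <- base_params()
  for (age in 69:99) {
    M <- build_transition_matrix(p, age)
    expect_equal(unname(rowSums(M)), rep(1, 7), tolerance = 1e-12)
    expect_true(all(M >= 0))
    expect_equal(unname(M["Dead", ]), c(0, 0, 0, 0, 0, 0, 1))
  }
  expect_error(build_transition_matrix(p, 200), "life table")
})

test_that("with no disease dynamics every alive state stays with 1-q and dies with q", {
  p <- flat_params(qx = 0.1)
  M <- build_transition_matrix(p, 75)
  for (s in alive_states()) {
    expect_equal(M[s, s], 0.9)
    expect_equal(M[s, "Dead"], 0.1)
  }
})

test_that("composite incidence equals the configured rate times background survival", {
  p <- base_params()
  age <- 72
  q <- p$life_table$qx[p$life_table$age == age]
  M <- build_transition_matrix(p, age)
  expect_equal(M["NoBE", "NDBE"], p$transitions$p_NoBE_NDBE * (1 - q))
  expect_equal(M["NDBE", "LGD"], p$transitions$p_NDBE_LGD * (1 - q))
})

test_that("half-cycle correction is the trapezoid of start and end occupancy", {
  expect_equal(half_cycle_correct(100, 100), 100)
  expect_equal(half_cycle_correct(100, 0), 50)
  expect_equal(half_cycle_correct(c(10, 20), c(0, 10)), c(5, 15))
  expect_error(half_cycle_correct(-1, 5), "non-negative")
})

test_that("corrected life-years lie between the start- and end-count Riemann sums", {
  p <- base_params()
  trace <- run_arms(p)$usual
  alive <- rowSums(apply(trace$occupancy, c(1, 3), sum)[, alive_states()])
  n <- length(alive) - 1
  upper <- sum(alive[1:n])        # start-of-cycle counts
  lower <- sum(alive[2:(n + 1)])  # end-of-cycle counts
  ly <- sum(trace$ly_undisc)
  expect_lte(ly, upper)
  expect_gte(ly, lower)
  expect_equal(ly, (upper + lower) / 2, tolerance = 1e-9)
})

test_that("cohort mass is conserved every cycle and Dead is absorbing", {
  p <- base_params()
  for (arm in c("intervention", "usual")) {
    trace <- run_arms(p)[[arm]]
    totals <- rowSums(apply(trace$occupancy, c(1, 3), sum))
    expect_equal(totals, rep(6834, length(totals)), tolerance = 6834 * 1e-9,
                 ignore_attr = TRUE)
    dead <- apply(trace$occupancy, c(1, 3), sum)[, "Dead"]
    expect_true(all(diff(dead) >= -1e-9))
  }
})

test_that("with zero mortality nobody ever dies", {
  p <- flat_params(qx = 0)
  p <- set_param(p, "transitions", "esoph_90day_mortality", 0)
  trace <- run_cohort(table1_allocation(p), "intervention", p)
  dead <- apply(trace$occupancy, c(1, 3), sum)[, "Dead"]
  expect_equal(unname(dead), rep(0, length(dead)))
  expect_equal(trace$totals$eac_deaths, 0)
})

test_that("QALYs equal life-years in the unit-utility, zero-discount, no-disutility limit", {
  p <- flat_params(qx = 0.08, utility = 1, discount = 0)
  for (ev in p$disutilities$event) p <- set_param(p, "disutilities", ev, 0)
  trace <- run_cohort(table1_allocation(p), "intervention", p)
  expect_equal(trace$totals$qaly, trace$totals$ly, tolerance = 1e-12)
})

test_that("constant-hazard survival reproduces the closed-form discounted life expectancy", {
  q <- 0.1
  p <- flat_params(qx = q, utility = 1, discount = 0)
  p <- set_param(p, "transitions", "esoph_90day_mortality", 0)
  trace <- run_cohort(table1_allocation(p), "usual", p)
  T_ <- p$settings$age_cap - p$settings$start_age
  expected <- sum(((1 - q)^(0:(T_ - 1)) + (1 - q)^(1:T_)) / 2)
  expect_equal(trace$totals$ly / 6834, expected, tolerance = 1e-12)
})

test_that("a two-cycle cohort matches hand-computed occupancy arithmetic", {
  q <- 0.4
  p <- flat_params(qx = q, utility = 1, discount = 0, age_cap = 71)
  p <- set_param(p, "transitions", "esoph_90day_mortality", 0)
  trace <- run_cohort(table1_allocation(p), "usual", p)
  # survival 1 -> 0.6 -> 0.36; trapezoids (1+0.6)/2 + (0.6+0.36)/2 = 1.28
  expect_equal(trace$totals$ly / 6834, 1.28, tolerance = 1e-12)
})

test_that("raising the discount rate weakly lowers discounted outcomes after cycle 0", {
  p <- base_params()
  hi <- p
  hi$settings$discount_rate <- 0.07
  a <- table1_allocation(p)
  t_lo <- run_cohort(a, "intervention", p)
  t_hi <- run_cohort(a, "intervention", hi)
  expect_lt(t_hi$totals$qaly, t_lo$totals$qaly)
  expect_lt(t_hi$totals$ly, t_lo$totals$ly)
  recurring_lo <- t_lo$totals$treatment_cost - t_lo$entry$entry_cost
  recurring_hi <- t_hi$totals$treatment_cost - t_hi$entry$entry_cost
  expect_lt(recurring_hi, recurring_lo)
  expect_equal(t_hi$entry$entry_cost, t_lo$entry$entry_cost)
})

test_that("perfect treatment sends all 131 detected patients to NoBE", {
  p <- base_params()
  for (s in c("NDBE", "LGD", "HGD", "EarlyEAC")) {
    p <- set_param(p, "transitions", paste0("success_", s), 1)
  }
  p <- set_param(p, "transitions", "esoph_90day_mortality", 0)
  a <- table1_allocation(p)
  entry <- treatment_entry(a, "intervention", p)
  expect_equal(entry$occupancy["natural_history", "NoBE"],
               6230.6 + 131, tolerance = 1e-9)
  expect_equal(entry$occupancy["natural_history", "NDBE"], 443.6)
  expect_equal(sum(entry$occupancy["treatment", ]), 0)
})

test_that("an empty treatment chain incurs no entry cost or disutility", {
  p <- base_params()
  det <- list(intervention = c(NDBE = 0, LGD = 0, HGD = 0, EarlyEAC = 0),
              usual = c(NDBE = 0, LGD = 0, HGD = 0, EarlyEAC = 0))
  a <- allocate_from_trial(p$scenario, p$accuracy, p$prevalence, det, 6834)
  entry <- treatment_entry(a, "usual", p)
  expect_equal(entry$entry_cost, 0)
  expect_equal(entry$entry_disutility, 0)
  expect_equal(entry$entry_deaths, 0)
})

test_that("endotherapy disutility charges decrement x duration per treated dysplasia patient", {
  p <- base_params()
  det <- list(intervention = c(NDBE = 0, LGD = 1, HGD = 0, EarlyEAC = 0),
              usual = c(NDBE = 0, LGD = 0, HGD = 0, EarlyEAC = 0))
  a <- allocate_from_trial(p$scenario, p$accuracy, p$prevalence, det, 6834)
  entry <- treatment_entry(a, "intervention", p)
  du <- p$disutilities
  expected <- sum(du$event_prob[du$event %in%
                                  c("emr_rfa", "stricture", "perforation")] *
                  du$decrement[du$event %in%
                                 c("emr_rfa", "stricture", "perforation")] *
                  du$duration_years[du$event %in%
                                      c("emr_rfa", "stricture",
                                        "perforation")])
  expect_equal(entry$entry_disutility, expected)
  # the EMR/RFA component itself is decrement x 4 weeks
  emr <- du[du$event == "emr_rfa", ]
  expect_equal(emr$duration_years, 4 / 52, tolerance = 1e-4)
})

test_that("with zero treatment success the arms share one natural history", {
  p <- base_params()
  for (s in c("NDBE", "LGD", "HGD", "EarlyEAC")) {
    p <- set_param(p, "transitions", paste0("success_", s), 0)
  }
  p <- set_param(p, "transitions", "esoph_90day_mortality", 0)
  arms <- run_arms(p)
  expect_equal(arms$intervention$occupancy, arms$usual$occupancy,
               tolerance = 1e-9)
  expect_equal(sum(arms$intervention$qaly_disc), sum(arms$usual$qaly_disc),
               tolerance = 1e-9)
  expect_equal(arms$intervention$totals$ly, arms$usual$totals$ly,
               tolerance = 1e-9)
})

test_that("treated late-stage cancer at entry is rejected", {
  p <- base_params()
  a <- unclass(table1_allocation(p))
  a["intervention", "treatment", "LateEAC"] <- 1
  a["intervention", "natural_history", "NoBE"] <-
    a["intervention", "natural_history", "NoBE"] - 1
  class(a) <- c("cyto_allocation", "array")
  expect_error(treatment_entry(a, "intervention", p), "LateEAC")
})
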