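test_that("published starting allocation reproduces the trial's detection table", {
  a <- table1_allocation(base_params())
  # 131 endoscopy-confirmed cases enter the intervention treatment chain
  expect_equal(sum(a["intervention", "treatment", ]), 131)
  expect_equal(a["intervention", "treatment", "NDBE"], 123)
  expect_equal(a["intervention", "treatment", "LGD"], 1)
  expect_equal(a["intervention", "treatment", "HGD"], 3)
  expect_equal(a["intervention", "treatment", "EarlyEAC"], 4)
  # natural-history remainders
  expect_equal(a["intervention", "natural_history", "NDBE"], 443.6)
  expect_equal(a["usual", "natural_history", "NDBE"], 555)
  expect_equal(a["usual", "natural_history", "NoBE"], 6230.6,
               tolerance = 1e-9)
  # both arms total the full cohort
  expect_equal(sum(a["usual", , ]), 6834)
  expect_equal(sum(a["intervention", , ]), 6834)
  # identical per-state disease burden across arms
  tot <- apply(a, c(1, 3), sum)
  expect_equal(tot["intervention", ], tot["usual", ])
  expect_equal(unname(tot["usual", "NDBE"]), 566.6)
  # no one starts in late cancer or dead
  expect_true(all(a[, , c("LateEAC", "Dead")] == 0))
})

test_that("implied BE prevalence from the allocation is about 9%", {
  p <- base_params()
  expect_equal(sum(p$prevalence), (566.6 + 4.6 + 13.8 + 18.4) / 6834,
               tolerance = 1e-9)
  expect_equal(sum(p$prevalence), 0.09, tolerance = 0.02)
})

test_that("screening costs reproduce the printed per-person figures", {
  p <- base_params()
  sc <- screening_cost(p$scenario, p$costs)
  expect_equal(sc$total_intervention, 524716, tolerance = 1e-6)
  expect_equal(round(sc$per_person_intervention), 77)
  expect_equal(sc$total_usual, 7808)
  expect_equal(round(sc$per_person_usual, 2), 1.14)
})

test_that("an all-zero scenario costs nothing", {
  p <- base_params()
  sc0 <- screening_scenario(n_invited = 0, n_swallowed = 0, n_referred = 0,
                            n_endoscopy_intervention = 0,
                            n_endoscopy_usual = 0, uptake = 0)
  out <- screening_cost(sc0, p$costs)
  expect_equal(out$total_intervention, 0)
  expect_equal(out$per_person_usual, 0)
})

test_that("allocation from a perfect test puts all prevalent disease in treatment", {
  p <- base_params()
  totals <- p$prevalence * 6834
  det <- list(intervention = totals, usual = p$detected$usual)
  a <- allocate_from_trial(p$scenario, p$accuracy, p$prevalence, det, 6834)
  expect_equal(unname(a["intervention", "natural_history",
                        prevalent_states()]),
               rep(0, 4), tolerance = 1e-9)
  expect_equal(sum(a["intervention", , ]), 6834)
})

test_that("detected counts exceeding prevalence are rejected", {
  p <- base_params()
  det <- p$detected
  det$intervention["HGD"] <- 1e5
  expect_error(
    allocate_from_trial(p$scenario, p$accuracy, p$prevalence, det, 6834),
    "exceeds prevalent")
})

test_that("uptake rescaling is the identity at the base uptake", {
  p <- base_params()
  a <- table1_allocation(p)
  out <- scale_uptake(a, p$scenario, p$scenario$uptake)
  expect_equal(unclass(out$allocation), unclass(a), tolerance = 1e-12)
  expect_equal(out$scenario$n_swallowed, p$scenario$n_swallowed)
})

test_that("doubling-plus uptake to 50% reproduces the published volumes", {
  p <- base_params()
  a <- table1_allocation(p)
  out <- scale_uptake(a, p$scenario, 0.50)
  expect_equal(out$scenario$n_swallowed, 3417, tolerance = 0.001)
  expect_equal(out$scenario$n_referred, 457, tolerance = 0.002)
  # detections scale with uptake; totals conserved
  expect_equal(sum(out$allocation["intervention", "treatment", ]),
               131 * 0.5 / p$scenario$uptake, tolerance = 1e-9)
  tot <- apply(out$allocation, c(1, 3), sum)
  expect_equal(tot["intervention", ], tot["usual", ])
  expect_error(scale_uptake(a, p$scenario, 0), "new_uptake")
})

test_that("screening cost is linear and increasing in uptake", {
  p <- base_params()
  a <- table1_allocation(p)
  ups <- c(0.1, 0.2, 0.3, 0.4, 0.5)
  costs <- vapply(ups, function(u) {
    screening_cost(scale_uptake(a, p$scenario, u)$scenario,
                   p$costs)$per_person_intervention
  }, numeric(1))
  expect_true(all(diff(costs) > 0))
  # linearity: second differences vanish
  expect_equal(diff(diff(costs)), rep(0, 3), tolerance = 1e-9)
})

test_that("readministered scenario adds the repeat volumes and detections", {
  p <- base_params()
  sc <- readminister_scenario(p$scenario)
  expect_true(sc$include_repeat)
  expect_equal(sc$n_swallowed + sc$n_repeat_tests, 1654 + 202)
  expect_equal(sc$n_endoscopy_intervention + sc$n_repeat_endoscopies,
               198 + 23)
  expect_equal(unname(sc$detected_delta[c("LGD", "HGD", "EarlyEAC")]),
               c(0.1, 1.0, 2.0))
  a <- apply_detection_delta(table1_allocation(p), sc$detected_delta)
  expect_equal(sum(a["intervention", "treatment", ]), 131 + 3.1)
  expect_equal(sum(a["intervention", , ]), 6834)
  # repeat tests raise the screening cost
  base_cost <- screening_cost(p$scenario, p$costs)
  rep_cost <- screening_cost(sc, p$costs)
  expect_gt(rep_cost$per_person_intervention,
            base_cost$per_person_intervention)
})
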