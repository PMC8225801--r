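# Cohort entry: turn the screening funnel (invitation -> swallow -> TFF3 ->
# confirmatory endoscopy) into per-arm, per-chain starting-state allocations
# and screening costs.

#' Construct a screening scenario
#'
#' A screening scenario records the volumes of the one-round Cytosponge-TFF3
#' screening funnel: invitations, successfully administered tests, positive
#' referrals, confirmatory endoscopies in each arm, and (optionally) the
#' repeat-test pathway for inadequate samples.
#'
#' @param n_invited Persons invited (intervention arm denominator).
#' @param n_swallowed Tests successfully administered.
#' @param n_referred TFF3-positive referrals to confirmatory endoscopy.
#' @param n_endoscopy_intervention Confirmatory endoscopies performed
#'   (intervention arm).
#' @param n_endoscopy_usual Symptom-driven endoscopies in the usual-care arm.
#' @param n_repeat_tests Repeat Cytosponge tests after an inadequate sample.
#' @param n_repeat_endoscopies Additional endoscopies from the repeat round.
#' @param uptake Fraction of invitees tested.
#' @param include_repeat Whether repeat-round volumes are costed.
#' @return A `cyto_scenario` object.
#' @export
screening_scenario <- function(n_invited, n_swallowed, n_referred,
                               n_endoscopy_intervention, n_endoscopy_usual,
                               n_repeat_tests = 0, n_repeat_endoscopies = 0,
                               uptake = n_swallowed / n_invited,
                               include_repeat = FALSE) {
  counts <- c(n_invited = n_invited, n_swallowed = n_swallowed,
              n_referred = n_referred,
              n_endoscopy_intervention = n_endoscopy_intervention,
              n_endoscopy_usual = n_endoscopy_usual,
              n_repeat_tests = n_repeat_tests,
              n_repeat_endoscopies = n_repeat_endoscopies)
  for (nm in names(counts)) check_nonneg(counts[[nm]], nm)
  if (n_swallowed > n_invited) {
    stop("n_swallowed exceeds n_invited", call. = FALSE)
  }
  if (n_endoscopy_intervention > n_swallowed + n_repeat_tests) {
    stop("intervention endoscopies exceed tests administered", call. = FALSE)
  }
  check_prob(uptake, "uptake")
  structure(c(as.list(counts),
              list(uptake = uptake, include_repeat = include_repeat,
                   detected_delta = NULL)),
            class = "cyto_scenario")
}

#' @export
print.cyto_scenario <- function(x, ...) {
  cat("<cyto_scenario>\n")
  cat(sprintf("  invited %s | tested %s (uptake %.1f%%) | referred %s | endoscopies %s (int) / %s (usual)\n",
              format(x$n_invited), format(x$n_swallowed), 100 * x$uptake,
              format(x$n_referred), format(x$n_endoscopy_intervention),
              format(x$n_endoscopy_usual)))
  if (isTRUE(x$include_repeat)) {
    cat(sprintf("  repeat round: %s tests, %s endoscopies\n",
                format(x$n_repeat_tests), format(x$n_repeat_endoscopies)))
  }
  invisible(x)
}

# internal: empty allocation array [arm, chain, state]
empty_allocation <- function() {
  array(0, dim = c(2, 2, 7),
        dimnames = list(arm = model_arms(), chain = model_chains(),
                        state = health_states()))
}

new_allocation <- function(arr) {
  structure(arr, class = c("cyto_allocation", "array"))
}

#' @export
print.cyto_allocation <- function(x, ...) {
  cat("<cyto_allocation> starting-state allocation (persons)\n")
  for (arm in model_arms()) {
    cat(sprintf("  %s arm (total %.1f):\n", arm, sum(x[arm, , ])))
    m <- x[arm, , , drop = TRUE]
    print(round(m[, colSums(m != 0) > 0 | colnames(m) %in% "NoBE",
                  drop = FALSE], 1))
  }
  invisible(x)
}

#' Tidy data frame view of an allocation
#'
#' @param x A `cyto_allocation`.
#' @param ... Unused.
#' @return Data frame with columns arm, chain, state, count.
#' @export
as.data.frame.cyto_allocation <- function(x, ...) {
  g <- expand.grid(arm = model_arms(), chain = model_chains(),
                   state = health_states(), stringsAsFactors = FALSE)
  g$count <- mapply(function(a, c, s) x[a, c, s], g$arm, g$chain, g$state)
  g
}

# internal: validate allocation invariants
validate_allocation <- function(alloc, cohort_size = NULL, tol = 1e-6) {
  if (any(alloc < 0)) stop("allocation contains negative counts",
                           call. = FALSE)
  if (any(alloc[, , c("LateEAC", "Dead")] != 0)) {
    stop("LateEAC and Dead must start at 0", call. = FALSE)
  }
  arm_sums <- apply(alloc, 1, sum)
  if (abs(arm_sums[["intervention"]] - arm_sums[["usual"]]) > tol) {
    stop("arms must contain the same total cohort size", call. = FALSE)
  }
  if (!is.null(cohort_size) && any(abs(arm_sums - cohort_size) > tol)) {
    stop(sprintf("arm totals (%.3f) do not equal cohort_size (%s)",
                 arm_sums[[1]], cohort_size), call. = FALSE)
  }
  totals <- apply(alloc, c(1, 3), sum)  # arm x state
  if (any(abs(totals["intervention", ] - totals["usual", ]) > tol)) {
    stop("per-state totals must be identical across arms", call. = FALSE)
  }
  invisible(TRUE)
}

#' Starting allocation from trial detections, prevalence and test accuracy
#'
#' Builds the two-arm, two-chain starting allocation: the treatment chain of
#' each arm receives the endoscopy-confirmed (true-positive) detected counts;
#' the natural-history chain receives the remainder of the prevalent disease
#' (including Cytosponge false negatives and everyone not tested), so that
#' per-state totals equal prevalence times cohort size in both arms. False
#' positives (from specificity among non-diseased attendees) incur screening
#' and endoscopy costs in the scenario but remain in NoBE with no treatment
#' cost.
#'
#' @param scenario A `cyto_scenario` (used for consistency checks).
#' @param accuracy Test-accuracy list (sensitivity, specificity, ...).
#' @param prevalence Named per-state prevalence vector over
#'   [prevalent_states()].
#' @param detected List with named vectors `intervention` and `usual` of
#'   detected (treated) counts per prevalent state.
#' @param cohort_size Persons per arm.
#' @return A `cyto_allocation`.
#' @export
allocate_from_trial <- function(scenario, accuracy, prevalence, detected,
                                cohort_size) {
  stopifnot(inherits(scenario, "cyto_scenario"))
  prev_states <- prevalent_states()
  totals <- prevalence[prev_states] * cohort_size
  alloc <- empty_allocation()
  for (arm in model_arms()) {
    det <- detected[[arm]][prev_states]
    if (any(det > totals + 1e-9)) {
      bad <- prev_states[which(det > totals + 1e-9)[1]]
      stop(sprintf(
        "detected count for %s in %s arm (%.2f) exceeds prevalent total (%.2f)",
        bad, arm, det[[bad]], totals[[bad]]), call. = FALSE)
    }
    alloc[arm, "treatment", prev_states] <- det
    alloc[arm, "natural_history", prev_states] <- totals - det
    alloc[arm, "natural_history", "NoBE"] <- cohort_size - sum(totals)
  }
  alloc <- new_allocation(alloc)
  validate_allocation(alloc, cohort_size)
  alloc
}

#' The published starting-state allocation
#'
#' Returns the base-case starting allocation of the 6834-person cohort in
#' each arm, reconstructed from the packaged prevalence vector and the trial
#' detection counts. In the intervention arm the treatment chain holds the
#' 131 patients with endoscopy-confirmed BE or early cancer (123 NDBE, 1
#' LGD, 3 HGD, 4 early EAC); the usual-care treatment chain holds the few
#' cases found by symptom-driven referral. Both arms carry identical
#' per-state disease totals.
#'
#' @param params Parameter set; defaults to [base_case()].
#' @return A `cyto_allocation`.
#' @export
#' @examples
#' a <- table1_allocation()
#' sum(a["intervention", "treatment", ])  # 131 detected
table1_allocation <- function(params = base_case()) {
  allocate_from_trial(params$scenario, params$accuracy, params$prevalence,
                      params$detected, params$settings$cohort_size)
}

#' Screening costs of a scenario
#'
#' Screening cost in the intervention arm is tests administered times the
#' Cytosponge unit cost (device, laboratory processing, TFF3 antibody,
#' pathology reporting, nurse time) plus confirmatory endoscopies at the
#' endoscopy-with-biopsy tariff; the repeat round is added when the scenario
#' includes it. Usual-care screening cost is its endoscopies alone.
#'
#' @param scenario A `cyto_scenario`.
#' @param costs Cost list with `cytosponge_test` and `endoscopy_biopsy`.
#' @return A `cyto_screening_cost` list: `total_intervention`, `total_usual`,
#'   `per_person_intervention`, `per_person_usual`.
#' @export
#' @examples
#' sc <- screening_cost(base_case()$scenario, base_case()$costs)
#' round(sc$per_person_intervention)  # 77
screening_cost <- function(scenario, costs) {
  stopifnot(inherits(scenario, "cyto_scenario"))
  if (scenario$n_invited == 0) {
    if (scenario$n_swallowed == 0 && scenario$n_endoscopy_usual == 0) {
      return(structure(list(total_intervention = 0, total_usual = 0,
                            per_person_intervention = 0, per_person_usual = 0),
                       class = "cyto_screening_cost"))
    }
    stop("n_invited is zero but screening volumes are non-zero",
         call. = FALSE)
  }
  tests <- scenario$n_swallowed
  endos <- scenario$n_endoscopy_intervention
  if (isTRUE(scenario$include_repeat)) {
    tests <- tests + scenario$n_repeat_tests
    endos <- endos + scenario$n_repeat_endoscopies
  }
  total_int <- tests * costs$cytosponge_test + endos * costs$endoscopy_biopsy
  total_usual <- scenario$n_endoscopy_usual * costs$endoscopy_biopsy
  structure(list(
    total_intervention = total_int,
    total_usual = total_usual,
    per_person_intervention = total_int / scenario$n_invited,
    per_person_usual = total_usual / scenario$n_invited),
    class = "cyto_screening_cost")
}

#' Rescale a scenario and allocation to a different uptake
#'
#' Test volumes, referrals, endoscopies and detected (treatment-chain)
#' counts in the intervention arm scale proportionally with uptake; the
#' natural-history chain absorbs the difference so per-state totals are
#' conserved. The usual-care arm is unchanged.
#'
#' @param allocation A `cyto_allocation`.
#' @param scenario The matching `cyto_scenario`.
#' @param new_uptake New uptake fraction in (0, 1].
#' @return List with elements `allocation` and `scenario`.
#' @export
scale_uptake <- function(allocation, scenario, new_uptake) {
  if (!is.numeric(new_uptake) || new_uptake <= 0 || new_uptake > 1) {
    stop("new_uptake must lie in (0, 1], got ", new_uptake, call. = FALSE)
  }
  f <- new_uptake / scenario$uptake
  sc <- scenario
  for (nm in c("n_swallowed", "n_referred", "n_endoscopy_intervention",
               "n_repeat_tests", "n_repeat_endoscopies")) {
    sc[[nm]] <- scenario[[nm]] * f
  }
  sc$uptake <- new_uptake

  alloc <- unclass(allocation)
  totals <- apply(alloc["intervention", , , drop = TRUE], 2, sum)
  treat <- alloc["intervention", "treatment", ] * f
  if (any(treat > totals + 1e-9)) {
    stop("scaled detections exceed prevalent totals; uptake too high for allocation",
         call. = FALSE)
  }
  alloc["intervention", "treatment", ] <- treat
  alloc["intervention", "natural_history", ] <- totals - treat
  alloc <- new_allocation(alloc)
  validate_allocation(alloc)
  list(allocation = alloc, scenario = sc)
}

#' Repeat-test (readministered Cytosponge) scenario
#'
#' Adds the repeat-round volumes to the base scenario (202 additional tests
#' and 23 additional endoscopies in the base case) and records the extra
#' detections the repeat round yields (0.1 LGD, 1.0 HGD, 2.0 early EAC),
#' which [apply_detection_delta()] moves from the natural-history chain into
#' the treatment chain.
#'
#' @param base Base-case `cyto_scenario`.
#' @param detected_delta Named vector of extra detected counts per state.
#' @return A `cyto_scenario` with `include_repeat = TRUE` and a
#'   `detected_delta` field.
#' @export
readminister_scenario <- function(base,
                                  detected_delta = c(NDBE = 0, LGD = 0.1,
                                                     HGD = 1.0,
                                                     EarlyEAC = 2.0)) {
  stopifnot(inherits(base, "cyto_scenario"))
  sc <- base
  sc$include_repeat <- TRUE
  sc$detected_delta <- detected_delta[prevalent_states()]
  sc$detected_delta[is.na(sc$detected_delta)] <- 0
  names(sc$detected_delta) <- prevalent_states()
  sc
}

#' Move extra detected patients into the treatment chain
#'
#' @param allocation A `cyto_allocation`.
#' @param delta Named vector of additional detected counts (intervention arm).
#' @return The adjusted `cyto_allocation`.
#' @export
apply_detection_delta <- function(allocation, delta) {
  if (is.null(delta)) return(allocation)
  alloc <- unclass(allocation)
  sts <- names(delta)[delta != 0]
  if (any(alloc["intervention", "natural_history", sts] < delta[sts] - 1e-9)) {
    stop("detection delta exceeds natural-history occupancy", call. = FALSE)
  }
  alloc["intervention", "treatment", sts] <-
    alloc["intervention", "treatment", sts] + delta[sts]
  alloc["intervention", "natural_history", sts] <-
    alloc["intervention", "natural_history", sts] - delta[sts]
  alloc <- new_allocation(alloc)
  validate_allocation(alloc)
  alloc
}
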