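# Synthetic screening-trial generator: per-person simulation of the
# invitation -> swallow -> TFF3 -> confirmatory-endoscopy funnel, producing
# scenario and detection inputs in the dialect the cohort-entry module reads.

#' Generate a synthetic screening trial
#'
#' Simulates the screening funnel person by person: attendance (and a
#' successful swallow) is Bernoulli with the uptake probability; the true
#' disease state is multinomial at the supplied per-state prevalence; the
#' TFF3 result is positive with probability `sensitivity` for any BE state
#' and `1 - specificity` otherwise; positives attend a (perfect)
#' confirmatory endoscopy with probability `endoscopy_attendance`.
#' Optionally, an inadequate-sample fraction of tests is re-administered,
#' re-attended with a retest probability, reproducing the repeat-round
#' volumes of the alternative scenario. Regenerating with the same seed
#' reproduces the dataset exactly.
#'
#' @param seed Integer seed.
#' @param n_invited Persons invited.
#' @param uptake Probability an invitee is successfully tested.
#' @param prevalence Named per-state prevalence over [prevalent_states()].
#' @param accuracy Accuracy list (sensitivity, specificity).
#' @param endoscopy_attendance Probability a TFF3-positive attends
#'   endoscopy.
#' @param inadequate_fraction Fraction of tests with an inadequate sample
#'   offered a repeat test (0 disables the repeat pathway).
#' @param retest_attendance Probability an offered repeat test is attended.
#' @return A `cyto_trial` with per-person vectors, the aggregated
#'   `cyto_scenario` and the detected counts.
#' @export
generate_trial <- function(seed, n_invited, uptake, prevalence, accuracy,
                           endoscopy_attendance = 1,
                           inadequate_fraction = 0,
                           retest_attendance = 0) {
  for (nm in c("uptake", "endoscopy_attendance", "inadequate_fraction",
               "retest_attendance")) {
    check_prob(get(nm), nm)
  }
  check_prob(accuracy$sensitivity, "sensitivity")
  check_prob(accuracy$specificity, "specificity")
  prevalence <- prevalence[prevalent_states()]
  if (any(is.na(prevalence)) || any(prevalence < 0) || sum(prevalence) > 1) {
    stop("invalid prevalence vector", call. = FALSE)
  }

  set.seed(as.integer(seed))
  n <- as.integer(n_invited)
  probs <- c(NoBE = 1 - sum(prevalence), prevalence)
  state <- sample(names(probs), n, replace = TRUE, prob = probs)
  attended <- runif(n) < uptake
  diseased <- state != "NoBE"
  p_pos <- ifelse(diseased, accuracy$sensitivity, 1 - accuracy$specificity)
  tff3_pos <- attended & (runif(n) < p_pos)
  endoscopy <- tff3_pos & (runif(n) < endoscopy_attendance)
  # endoscopy is gold standard: confirmed iff truly diseased
  confirmed <- endoscopy & diseased

  n_swallowed <- sum(attended)
  inadequate <- attended & (runif(n) < inadequate_fraction)
  retested <- inadequate & (runif(n) < retest_attendance)
  # repeat round: retested positives referred again (same accuracy)
  retest_pos <- retested & !tff3_pos & (runif(n) < p_pos)
  n_repeat_endoscopies <- sum(retest_pos)

  detected <- vapply(prevalent_states(), function(s) {
    sum(confirmed & state == s)
  }, numeric(1))

  scenario <- screening_scenario(
    n_invited = n, n_swallowed = n_swallowed,
    n_referred = sum(tff3_pos),
    n_endoscopy_intervention = sum(endoscopy),
    n_endoscopy_usual = 0,
    n_repeat_tests = sum(retested),
    n_repeat_endoscopies = n_repeat_endoscopies,
    uptake = max(n_swallowed / n, 1e-12),
    include_repeat = inadequate_fraction > 0)

  structure(list(
    seed = as.integer(seed), n_invited = n, state = state,
    attended = attended, tff3_pos = tff3_pos, endoscopy = endoscopy,
    confirmed = confirmed, detected = detected, scenario = scenario,
    uptake = uptake, endoscopy_attendance = endoscopy_attendance),
    class = "cyto_trial")
}

#' @export
print.cyto_trial <- function(x, ...) {
  cat(sprintf("<cyto_trial> seed %d: %d invited, %d tested, %d referred, %d endoscopies\n",
              x$seed, x$n_invited, sum(x$attended), sum(x$tff3_pos),
              sum(x$endoscopy)))
  cat("  detected:", paste(names(x$detected), x$detected, sep = "=",
                           collapse = ", "), "\n")
  invisible(x)
}

#' Estimate BE prevalence by inverting the screening funnel
#'
#' Detected (endoscopy-confirmed) cases undercount true prevalence by the
#' funnel's losses: only a fraction of invitees are tested, the test misses
#' `1 - sensitivity` of diseased attendees, and a fraction of positives skip
#' endoscopy. Dividing the detected count by attendees x sensitivity x
#' endoscopy attendance recovers the prevalence among attendees, with a
#' binomial standard error.
#'
#' @param trial A `cyto_trial`.
#' @param accuracy Accuracy list used in the inversion (sensitivity).
#' @param endoscopy_attendance Endoscopy attendance used in the inversion;
#'   defaults to the trial's generating value.
#' @return List: `estimate`, `se`, `detected`, `attendees`.
#' @export
recover_prevalence <- function(trial, accuracy,
                               endoscopy_attendance = trial$endoscopy_attendance) {
  stopifnot(inherits(trial, "cyto_trial"))
  n_att <- sum(trial$attended)
  if (n_att < 1) stop("trial has no attendees", call. = FALSE)
  if (accuracy$sensitivity <= 0) stop("sensitivity must be positive",
                                      call. = FALSE)
  capture <- accuracy$sensitivity * endoscopy_attendance
  if (capture <= 0) stop("zero detection probability", call. = FALSE)
  d <- sum(trial$detected)
  est <- d / (n_att * capture)
  # delta-method SE from binomial variance of the detected count
  p_det <- d / n_att
  se <- sqrt(max(p_det * (1 - p_det), 0) / n_att) / capture
  list(estimate = est, se = se, detected = d, attendees = n_att)
}

#' Write the synthetic trial outputs read by the cohort-entry module
#'
#' Emits the scenario as YAML and the detected counts as CSV.
#'
#' @param trial A `cyto_trial`.
#' @param dir Output directory.
#' @return Invisibly, the two file paths.
#' @export
write_trial <- function(trial, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  sc <- trial$scenario
  yaml_path <- file.path(dir, "scenario.yaml")
  yaml::write_yaml(list(scenario = sc[c(
    "n_invited", "n_swallowed", "n_referred", "n_endoscopy_intervention",
    "n_endoscopy_usual", "n_repeat_tests", "n_repeat_endoscopies",
    "uptake", "include_repeat")]), yaml_path)
  csv_path <- file.path(dir, "detected.csv")
  write.csv(data.frame(state = names(trial$detected),
                       detected = as.numeric(trial$detected)),
            csv_path, row.names = FALSE, quote = FALSE)
  invisible(c(yaml_path, csv_path))
}
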