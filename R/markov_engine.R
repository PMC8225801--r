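# Yearly-cycle cohort Markov engine over the seven-state Barrett esophagus
# space, run separately for each arm with half-cycle correction and
# discounting over a lifetime (age-capped) horizon.

# internal: background all-cause death probability at an integer age
lookup_qx <- function(params, age) {
  i <- match(age, params$life_table$age)
  if (is.na(i)) stop("life table has no entry for age ", age, call. = FALSE)
  params$life_table$qx[i]
}

#' Build the age-specific annual transition matrix
#'
#' Composites the annual disease-transition probabilities with age-specific
#' all-cause mortality from the life table. Background death applies first;
#' survivors of background mortality face excess cancer mortality in the EAC
#' states and then the disease moves. Every row sums to one; Dead is
#' absorbing.
#'
#' @param params A `cyto_params` object.
#' @param age Integer age at the start of the cycle (within life-table range).
#' @return A 7x7 row-stochastic matrix over [health_states()].
#' @export
build_transition_matrix <- function(params, age) {
  q <- lookup_qx(params, age)
  sts <- health_states()
  M <- matrix(0, 7, 7, dimnames = list(from = sts, to = sts))
  M["Dead", "Dead"] <- 1
  tr <- params$transitions
  edges <- disease_edges()
  targets <- edge_targets()
  excess <- c(NoBE = 0, NDBE = 0, LGD = 0, HGD = 0,
              EarlyEAC = tr$p_mort_EarlyEAC, LateEAC = tr$p_mort_LateEAC)
  for (s in alive_states()) {
    death <- 1 - (1 - q) * (1 - excess[[s]])
    ps <- edges[[s]]
    move <- 0
    for (e in ps) {
      p <- tr[[e]]
      M[s, targets[[e]]] <- M[s, targets[[e]]] + p * (1 - death)
      move <- move + p
    }
    if (move > 1 + 1e-12) {
      stop("outgoing disease probabilities from ", s, " exceed 1",
           call. = FALSE)
    }
    M[s, "Dead"] <- death
    M[s, s] <- M[s, s] + (1 - death) * (1 - move)
  }
  if (any(M < -1e-15)) stop("negative composite transition probability",
                            call. = FALSE)
  M
}

#' Half-cycle correction
#'
#' Trapezoidal person-time: transitions are treated as occurring mid-cycle
#' on average, so the effective occupancy over a cycle is the mean of the
#' start-of-cycle and end-of-cycle occupancy.
#'
#' @param occupancy_start,occupancy_end Occupancy (persons) at the start and
#'   end of a cycle; vectors are corrected element-wise.
#' @return Effective person-years over the cycle.
#' @export
#' @examples
#' half_cycle_correct(100, 0)  # 50
half_cycle_correct <- function(occupancy_start, occupancy_end) {
  if (any(occupancy_start < 0) || any(occupancy_end < 0)) {
    stop("occupancies must be non-negative", call. = FALSE)
  }
  (occupancy_start + occupancy_end) / 2
}

# internal: one-off QALY loss per patient for a set of disutility events
event_disutility <- function(params, events) {
  du <- params$disutilities
  rows <- du[du$event %in% events, , drop = FALSE]
  sum(rows$event_prob * rows$decrement * rows$duration_years)
}

#' Apply entry treatment to a starting allocation
#'
#' Everyone in the treatment chain receives the state-appropriate therapy at
#' model entry: endoscopic management for NDBE, endotherapy (EMR/RFA) for
#' dysplasia, and a resection/chemotherapy or endotherapy pathway for early
#' EAC (with 90-day post-esophagectomy mortality). Successes move to NoBE in
#' the natural-history chain, failures remain in-state in the natural-history
#' chain. One-off treatment costs and procedural disutilities (decrement
#' times duration) are charged at entry, undiscounted.
#'
#' @param allocation A `cyto_allocation`.
#' @param arm `"intervention"` or `"usual"`.
#' @param params A `cyto_params` object.
#' @return List: `occupancy` (chain x state matrix after entry),
#'   `entry_cost` (GBP), `entry_disutility` (QALYs lost),
#'   `entry_deaths` (90-day surgical deaths), `treated` (per-state counts).
#' @export
treatment_entry <- function(allocation, arm, params) {
  slice <- allocation[arm, , , drop = TRUE]
  treat <- slice["treatment", ]
  nat <- slice["natural_history", ]
  if (treat[["LateEAC"]] != 0) {
    stop("LateEAC is not a permitted entry state for treatment",
         call. = FALSE)
  }
  tr <- params$transitions
  co <- params$costs
  cost <- 0
  disu <- 0
  deaths <- 0

  # NDBE: confirmatory work-up / endoscopic management episode
  n <- treat[["NDBE"]]
  cost <- cost + n * co$endoscopy_biopsy
  succ <- n * tr$success_NDBE
  nat[["NoBE"]] <- nat[["NoBE"]] + succ
  nat[["NDBE"]] <- nat[["NDBE"]] + (n - succ)

  # dysplasia: endotherapy (EMR for visible lesions + RFA course)
  endo_du <- event_disutility(params, c("emr_rfa", "stricture", "perforation"))
  for (s in c("LGD", "HGD")) {
    n <- treat[[s]]
    unit_cost <- if (s == "LGD") co$endotherapy_rfa else
      co$endotherapy_emr + co$endotherapy_rfa
    cost <- cost + n * unit_cost
    disu <- disu + n * endo_du
    sr <- if (s == "LGD") tr$success_LGD else tr$success_HGD
    succ <- n * sr
    nat[["NoBE"]] <- nat[["NoBE"]] + succ
    nat[[s]] <- nat[[s]] + (n - succ)
  }

  # early EAC: esophagectomy + chemotherapy pathway or endotherapy
  n <- treat[["EarlyEAC"]]
  f <- tr$eac_surgery_fraction
  surgical <- n * f
  endoscopic <- n * (1 - f)
  cost <- cost + surgical * (co$esophagectomy + co$chemotherapy) +
    endoscopic * (co$endotherapy_emr + co$endotherapy_rfa)
  disu <- disu + surgical * event_disutility(params, c("esophagectomy",
                                                       "chemotherapy")) +
    endoscopic * endo_du
  op_deaths <- surgical * tr$esoph_90day_mortality
  deaths <- deaths + op_deaths
  survivors <- n - op_deaths
  succ <- survivors * tr$success_EarlyEAC
  nat[["NoBE"]] <- nat[["NoBE"]] + succ
  nat[["EarlyEAC"]] <- nat[["EarlyEAC"]] + (survivors - succ)
  nat[["Dead"]] <- nat[["Dead"]] + op_deaths

  occ <- rbind(treatment = 0 * treat, natural_history = nat)
  list(occupancy = occ, entry_cost = cost, entry_disutility = disu,
       entry_deaths = deaths, treated = treat)
}

# states whose first-ever entries are counted as incidence, with the
# less-severe origin states whose inflow counts
incidence_sources <- function() {
  list(NDBE = "NoBE", LGD = "NDBE", HGD = "LGD",
       EarlyEAC = c("NDBE", "HGD"), LateEAC = "EarlyEAC")
}

#' Run the cohort Markov model for one arm
#'
#' Iterates yearly cycles from the starting age to the age cap. Each cycle
#' the cohort moves under the age-specific transition matrix; quality-
#' adjusted life-years, life-years and recurring costs accrue on half-cycle-
#' corrected occupancy and are discounted by `1/(1+r)^t` with `t` whole
#' cycles since entry. Screening and treatment-entry costs are charged at
#' cycle 0 undiscounted. Acid-suppressant (PPI/H2RA) drug costs accrue for
#' alive person-time; palliative care is charged once per death from late
#' EAC.
#'
#' @param allocation A `cyto_allocation`.
#' @param arm `"intervention"` or `"usual"`.
#' @param params A `cyto_params` object.
#' @param screening_total Cohort-level screening cost charged at cycle 0.
#' @param matrices Optional precomputed list of transition matrices (one per
#'   cycle) to avoid rebuilding when running many scenarios.
#' @return A `cyto_trace` object; see [trace_summary()].
#' @export
run_cohort <- function(allocation, arm, params, screening_total = 0,
                       matrices = NULL) {
  s <- params$settings
  n_cycles <- s$age_cap - s$start_age
  sts <- health_states()
  start_counts <- apply(allocation[arm, , , drop = TRUE], 2, sum)

  entry <- treatment_entry(allocation, arm, params)
  occ <- array(0, dim = c(n_cycles + 1, 2, 7),
               dimnames = list(cycle = 0:n_cycles, chain = model_chains(),
                               state = sts))
  occ[1, , ] <- entry$occupancy

  if (is.null(matrices)) {
    matrices <- lapply(seq_len(n_cycles), function(t) {
      build_transition_matrix(params, s$start_age + t - 1)
    })
  }

  disc <- (1 + s$discount_rate)^-(seq_len(n_cycles))
  u <- params$utilities[alive_states()]
  tr <- params$transitions
  co <- params$costs

  ly_ud <- qaly_ud <- cost_ud <- numeric(n_cycles)
  eac_deaths <- late_deaths <- numeric(n_cycles)
  inc_sources <- incidence_sources()
  incident <- setNames(numeric(length(inc_sources)), names(inc_sources))

  cur <- entry$occupancy["natural_history", ]
  for (t in seq_len(n_cycles)) {
    age <- s$start_age + t - 1
    M <- matrices[[t]]
    q <- lookup_qx(params, age)
    nxt <- as.numeric(cur %*% M)
    names(nxt) <- sts
    if (any(nxt < -1e-9)) stop("negative occupancy at cycle ", t,
                               call. = FALSE)
    nxt[nxt < 0] <- 0

    eac_deaths[t] <- cur[["EarlyEAC"]] * (1 - q) * tr$p_mort_EarlyEAC +
      cur[["LateEAC"]] * (1 - q) * tr$p_mort_LateEAC
    late_deaths[t] <- cur[["LateEAC"]] * (1 - q) * tr$p_mort_LateEAC

    for (tgt in names(inc_sources)) {
      from <- inc_sources[[tgt]]
      incident[[tgt]] <- incident[[tgt]] + sum(cur[from] * M[from, tgt])
    }

    hcc <- half_cycle_correct(cur[alive_states()], nxt[alive_states()])
    ly_ud[t] <- sum(hcc)
    qaly_ud[t] <- sum(u * hcc)
    ppi_py <- if (isTRUE(s$ppi_all_alive)) sum(hcc) else
      sum(hcc[c("NoBE", "NDBE", "LGD", "HGD")])
    cost_ud[t] <- ppi_py * co$ppi_annual + late_deaths[t] * co$palliative_care

    occ[t + 1, "natural_history", ] <- nxt
    cur <- nxt
  }

  entry_cost <- entry$entry_cost
  treatment_cost <- entry_cost + sum(cost_ud * disc)
  totals <- list(
    screening_cost = screening_total,
    treatment_cost = treatment_cost,
    total_cost = screening_total + treatment_cost,
    qaly = sum(qaly_ud * disc) - entry$entry_disutility,
    ly = sum(ly_ud * disc),
    qaly_undisc = sum(qaly_ud) - entry$entry_disutility,
    ly_undisc = sum(ly_ud),
    eac_deaths = sum(eac_deaths),
    censored_alive = sum(cur[alive_states()]) / s$cohort_size)

  structure(list(
    arm = arm, occupancy = occ, ages = s$start_age + 0:n_cycles,
    ly_disc = ly_ud * disc, qaly_disc = qaly_ud * disc,
    cost_disc = cost_ud * disc, ly_undisc = ly_ud, qaly_undisc = qaly_ud,
    cost_undisc = cost_ud, eac_deaths = eac_deaths,
    late_eac_deaths = late_deaths,
    incident = incident, start_counts = start_counts, entry = entry,
    cohort_size = s$cohort_size, totals = totals),
    class = "cyto_trace")
}

#' @export
print.cyto_trace <- function(x, ...) {
  t <- x$totals
  cat(sprintf("<cyto_trace> %s arm, cohort of %s\n", x$arm,
              format(x$cohort_size)))
  cat(sprintf("  discounted per person: cost £%.2f (screening £%.2f + treatment £%.2f)\n",
              t$total_cost / x$cohort_size, t$screening_cost / x$cohort_size,
              t$treatment_cost / x$cohort_size))
  cat(sprintf("  QALYs %.3f, life-years %.3f; EAC deaths %.1f\n",
              t$qaly / x$cohort_size, t$ly / x$cohort_size, t$eac_deaths))
  invisible(x)
}

#' Key model outputs for one arm
#'
#' Cohort-level counts in the style of the screening/disease summary table:
#' screening volumes, patients who start with or develop each disease stage
#' (first-ever entries plus the starting occupancy), and EAC deaths.
#'
#' @param trace A `cyto_trace`.
#' @param scenario The `cyto_scenario` that produced the trace (for
#'   screening volumes); optional.
#' @return Named list of counts.
#' @export
trace_summary <- function(trace, scenario = NULL) {
  ever <- trace$start_counts[names(trace$incident)] + trace$incident
  out <- list(
    invited = if (!is.null(scenario) && trace$arm == "intervention")
      scenario$n_invited else 0,
    tests = if (!is.null(scenario) && trace$arm == "intervention")
      scenario$n_swallowed else 0,
    endoscopies = if (is.null(scenario)) NA_real_ else
      if (trace$arm == "intervention") scenario$n_endoscopy_intervention
      else scenario$n_endoscopy_usual,
    ever_LGD = ever[["LGD"]], ever_HGD = ever[["HGD"]],
    ever_EarlyEAC = ever[["EarlyEAC"]],
    eac_deaths = trace$totals$eac_deaths)
  out
}

#' Run both arms of the base-case model
#'
#' Builds the starting allocation, screening costs and transition matrices,
#' then runs each arm through [run_cohort()].
#'
#' @param params A `cyto_params` object.
#' @param allocation Optional allocation override (default
#'   [table1_allocation()] of `params`).
#' @param scenario Optional scenario override (default from `params`).
#' @return List with `cyto_trace` elements `intervention` and `usual`, plus
#'   the `scenario` and `screening` cost object used.
#' @export
run_arms <- function(params, allocation = NULL, scenario = NULL) {
  if (is.null(scenario)) scenario <- params$scenario
  if (is.null(allocation)) {
    allocation <- table1_allocation(params)
    if (!is.null(scenario$detected_delta)) {
      allocation <- apply_detection_delta(allocation, scenario$detected_delta)
    }
  }
  sc <- screening_cost(scenario, params$costs)
  n_cycles <- params$settings$age_cap - params$settings$start_age
  mats <- lapply(seq_len(n_cycles), function(t) {
    build_transition_matrix(params, params$settings$start_age + t - 1)
  })
  list(
    intervention = run_cohort(allocation, "intervention", params,
                              sc$total_intervention, matrices = mats),
    usual = run_cohort(allocation, "usual", params, sc$total_usual,
                       matrices = mats),
    scenario = scenario, screening = sc)
}

#' Export a trace as a tidy per-cycle data frame
#'
#' @param trace A `cyto_trace`.
#' @return Data frame with one row per cycle, age, state occupancies and
#'   per-cycle discounted cost/QALY/life-year accruals.
#' @export
trace_to_df <- function(trace) {
  n <- length(trace$ages)
  occ <- apply(trace$occupancy, c(1, 3), sum)
  df <- data.frame(cycle = 0:(n - 1), age = trace$ages, occ,
                   check.names = FALSE)
  df$cost_disc <- c(NA, trace$cost_disc)
  df$qaly_disc <- c(NA, trace$qaly_disc)
  df$ly_disc <- c(NA, trace$ly_disc)
  df$eac_deaths <- c(NA, trace$eac_deaths)
  df
}
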