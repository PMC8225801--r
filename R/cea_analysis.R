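# Incremental cost-effectiveness analysis and budget impact.

#' Incremental cost-effectiveness analysis between arms
#'
#' Computes per-person mean costs (screening, treatment, total), QALYs and
#' life-years for each arm, the increments, the ICER on unrounded increments
#' and the net monetary benefit at a willingness-to-pay threshold. When the
#' intervention is cheaper and more effective the result is flagged as
#' dominant rather than reported as a negative ICER; when the QALY increment
#' is zero the ICER is `NA` with status `"undefined"`.
#'
#' @param trace_int,trace_usual `cyto_trace` objects for the intervention
#'   and usual-care arms, run under identical settings.
#' @param threshold Willingness-to-pay threshold (GBP/QALY).
#' @return A `cyto_ce` object.
#' @export
incremental_analysis <- function(trace_int, trace_usual, threshold = 20000) {
  stopifnot(inherits(trace_int, "cyto_trace"),
            inherits(trace_usual, "cyto_trace"))
  if (trace_int$cohort_size != trace_usual$cohort_size) {
    stop("traces were run with different cohort sizes", call. = FALSE)
  }
  n <- trace_int$cohort_size
  per_person <- function(trace) {
    t <- trace$totals
    list(screening_cost = t$screening_cost / n,
         treatment_cost = t$treatment_cost / n,
         total_cost = t$total_cost / n,
         qaly = t$qaly / n, ly = t$ly / n)
  }
  int <- per_person(trace_int)
  usu <- per_person(trace_usual)
  dC <- int$total_cost - usu$total_cost
  dE <- int$qaly - usu$qaly
  dLY <- int$ly - usu$ly

  if (dE == 0) {
    icer <- NA_real_
    status <- "undefined"
  } else {
    icer <- dC / dE
    status <- if (dC <= 0 && dE > 0) "dominant"
      else if (dC > 0 && dE < 0) "dominated"
      else "tradeoff"
  }
  nmb <- dE * threshold - dC

  structure(list(
    intervention = int, usual = usu,
    delta_cost = dC, delta_qaly = dE, delta_ly = dLY,
    icer = icer, icer_status = status, nmb = nmb, threshold = threshold,
    eac_deaths = c(intervention = trace_int$totals$eac_deaths,
                   usual = trace_usual$totals$eac_deaths),
    cohort_size = n),
    class = "cyto_ce")
}

#' @export
print.cyto_ce <- function(x, ...) {
  cat("<cyto_ce> incremental cost-effectiveness (per person)\n")
  fmt <- function(a) sprintf("cost £%.0f (screen £%.2f + treat £%.0f), %.3f QALYs, %.3f LYs",
                             a$total_cost, a$screening_cost,
                             a$treatment_cost, a$qaly, a$ly)
  cat("  intervention:", fmt(x$intervention), "\n")
  cat("  usual care:  ", fmt(x$usual), "\n")
  cat(sprintf("  increments: £%.2f, %.4f QALYs, %.4f LYs\n",
              x$delta_cost, x$delta_qaly, x$delta_ly))
  if (x$icer_status == "dominant") {
    cat("  intervention dominates (cheaper and more effective)\n")
  } else if (is.na(x$icer)) {
    cat("  ICER undefined (zero QALY increment)\n")
  } else {
    cat(sprintf("  ICER £%.0f/QALY; NMB £%.0f at £%s/QALY\n", x$icer,
                x$nmb, format(x$threshold, big.mark = ",")))
  }
  invisible(x)
}

#' Run the full base-case cost-effectiveness analysis
#'
#' Convenience wrapper: builds the allocation, runs both arms and returns
#' the incremental analysis together with the traces.
#'
#' @param params A `cyto_params` object (default the packaged base case).
#' @param allocation,scenario Optional overrides passed to [run_arms()].
#' @return List with elements `ce` (`cyto_ce`), `traces` (list of
#'   `cyto_trace`), `scenario` and `screening`.
#' @export
#' @examples
#' \donttest{
#' res <- run_cea(base_case())
#' res$ce$icer
#' }
run_cea <- function(params = base_case(), allocation = NULL,
                    scenario = NULL) {
  arms <- run_arms(params, allocation = allocation, scenario = scenario)
  ce <- incremental_analysis(arms$intervention, arms$usual,
                             params$settings$wtp_threshold)
  list(ce = ce, traces = arms[c("intervention", "usual")],
       scenario = arms$scenario, screening = arms$screening)
}

#' Budget impact of one screening round
#'
#' Scales the unrounded per-person incremental cost to the eligible
#' population and spreads the total evenly over the stated horizon.
#'
#' @param ce A `cyto_ce` result.
#' @param eligible Eligible persons (GERD patients offered screening).
#' @param horizon Years over which the cost is spread.
#' @return A `cyto_budget` list: `eligible_patients`, `total_budget`,
#'   `horizon_years`, `annual_cost`, `per_person_cost`.
#' @export
budget_impact <- function(ce, eligible = 262941, horizon = 29) {
  stopifnot(inherits(ce, "cyto_ce"))
  if (eligible <= 0) stop("eligible must be > 0", call. = FALSE)
  if (horizon <= 0) stop("horizon must be > 0", call. = FALSE)
  total <- eligible * ce$delta_cost
  structure(list(
    eligible_patients = eligible,
    total_budget = total,
    horizon_years = horizon,
    annual_cost = total / horizon,
    per_person_cost = ce$delta_cost),
    class = "cyto_budget")
}

#' @export
print.cyto_budget <- function(x, ...) {
  cat("<cyto_budget>\n")
  cat(sprintf("  %s eligible patients x £%.2f incremental cost = £%s total\n",
              format(x$eligible_patients, big.mark = ","), x$per_person_cost,
              format(round(x$total_budget), big.mark = ",")))
  cat(sprintf("  £%s per year over %s years\n",
              format(round(x$annual_cost), big.mark = ","),
              x$horizon_years))
  invisible(x)
}

#' Cost/benefit breakdown table (per patient)
#'
#' @param ce A `cyto_ce` result.
#' @return Data frame mirroring the main results table: screening cost,
#'   treatment cost, total cost, QALYs, life-years per arm plus mean
#'   differences, and the ICER.
#' @export
ce_table <- function(ce) {
  rows <- c("screening_cost", "treatment_cost", "total_cost", "qaly", "ly")
  lab <- c("Screening cost", "Treatment cost", "Total cost",
           "QALYs gained", "Life years gained")
  data.frame(
    quantity = c(lab, "ICER"),
    intervention = c(vapply(rows, function(r) ce$intervention[[r]],
                            numeric(1)), NA),
    usual = c(vapply(rows, function(r) ce$usual[[r]], numeric(1)), NA),
    difference = c(vapply(rows, function(r) {
      ce$intervention[[r]] - ce$usual[[r]]
    }, numeric(1)), ce$icer),
    row.names = NULL)
}
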