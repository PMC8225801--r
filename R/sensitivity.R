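# Probabilistic (Monte Carlo) and deterministic (one-way) sensitivity
# analysis around the base-case cost-utility result.

#' PSA configuration
#'
#' @param n_draws Number of Monte Carlo draws (base 1000).
#' @param seed Integer seed; every random stream in the PSA derives from it.
#' @return A `cyto_psa_config` list.
#' @export
psa_config <- function(n_draws = 1000, seed = 1L) {
  if (n_draws < 1) stop("n_draws must be >= 1", call. = FALSE)
  structure(list(n_draws = as.integer(n_draws), seed = as.integer(seed)),
            class = "cyto_psa_config")
}

# internal: moment-matched random draw for one registry row.
# Probabilities and utilities use a beta distribution, costs a gamma;
# default dispersion is SD = 20% of the mean unless the registry row
# carries an explicit sd.
draw_param <- function(value, sd, distribution) {
  if (is.na(distribution) || !nzchar(distribution)) return(value)
  if (is.na(sd)) sd <- 0.2 * value
  if (sd == 0 || value == 0) return(value)
  if (distribution == "beta") {
    if (value >= 1) return(value)
    v <- min(sd^2, 0.999 * value * (1 - value))
    k <- value * (1 - value) / v - 1
    rbeta(1, value * k, (1 - value) * k)
  } else if (distribution == "gamma") {
    shape <- (value / sd)^2
    rgamma(1, shape = shape, rate = shape / value)
  } else {
    stop("unsupported PSA distribution '", distribution,
         "' (supported: beta, gamma)", call. = FALSE)
  }
}

# internal: one perturbed parameter set
sample_parameter_set <- function(params) {
  m <- params$meta
  idx <- which(!is.na(m$distribution) & nzchar(m$distribution))
  for (i in idx) {
    params <- set_param(params, m$table[i], m$parameter[i],
                        draw_param(m$value[i], m$sd[i], m$distribution[i]))
  }
  params
}

#' Probabilistic sensitivity analysis
#'
#' Each draw samples every registered parameter carrying a distribution
#' (beta for probabilities and utilities, gamma for costs; moment-matched,
#' default SD 20\% of the mean unless the registry specifies one), then
#' reruns both arms on the common draw and records per-arm and incremental
#' costs and QALYs. The starting allocation is held at the trial-observed
#' detection counts. Results are reproducible bit-for-bit given the seed.
#'
#' @param params Base `cyto_params`.
#' @param config A [psa_config()].
#' @param thresholds Willingness-to-pay grid for the acceptability curve.
#' @return A `cyto_psa` object with the per-draw table, summary statistics,
#'   point ICER (ratio of mean increments) and CEAC.
#' @export
run_psa <- function(params, config = psa_config(),
                    thresholds = seq(0, 50000, by = 1000)) {
  stopifnot(inherits(config, "cyto_psa_config"))
  allocation <- table1_allocation(params)
  set.seed(config$seed)
  n <- config$n_draws
  draws <- data.frame(draw = seq_len(n), cost_int = NA_real_,
                      qaly_int = NA_real_, cost_usual = NA_real_,
                      qaly_usual = NA_real_, delta_cost = NA_real_,
                      delta_qaly = NA_real_, icer = NA_real_)
  for (i in seq_len(n)) {
    p_i <- sample_parameter_set(params)
    arms <- run_arms(p_i, allocation = allocation)
    ce <- incremental_analysis(arms$intervention, arms$usual,
                               params$settings$wtp_threshold)
    draws$cost_int[i] <- ce$intervention$total_cost
    draws$qaly_int[i] <- ce$intervention$qaly
    draws$cost_usual[i] <- ce$usual$total_cost
    draws$qaly_usual[i] <- ce$usual$qaly
    draws$delta_cost[i] <- ce$delta_cost
    draws$delta_qaly[i] <- ce$delta_qaly
    draws$icer[i] <- if (ce$delta_qaly != 0) ce$delta_cost / ce$delta_qaly
      else NA_real_
  }
  summary <- list(
    mean_cost_int = mean(draws$cost_int), sd_cost_int = sd(draws$cost_int),
    mean_qaly_int = mean(draws$qaly_int), sd_qaly_int = sd(draws$qaly_int),
    mean_cost_usual = mean(draws$cost_usual),
    sd_cost_usual = sd(draws$cost_usual),
    mean_qaly_usual = mean(draws$qaly_usual),
    sd_qaly_usual = sd(draws$qaly_usual),
    mean_delta_cost = mean(draws$delta_cost),
    sd_delta_cost = sd(draws$delta_cost),
    mean_delta_qaly = mean(draws$delta_qaly),
    sd_delta_qaly = sd(draws$delta_qaly))
  icer_point <- summary$mean_delta_cost / summary$mean_delta_qaly
  psa <- structure(list(draws = draws, summary = summary,
                        icer_point = icer_point, config = config,
                        threshold = params$settings$wtp_threshold),
                   class = "cyto_psa")
  psa$ceac <- ceac(psa, thresholds)
  psa
}

#' @importFrom stats sd
#' @export
print.cyto_psa <- function(x, ...) {
  s <- x$summary
  ci <- icer_interval(x, 0.95)
  cat(sprintf("<cyto_psa> %d draws (seed %d)\n", nrow(x$draws),
              x$config$seed))
  cat(sprintf("  incremental cost £%.0f (SD %.0f), incremental QALYs %.4f (SD %.4f)\n",
              s$mean_delta_cost, s$sd_delta_cost, s$mean_delta_qaly,
              s$sd_delta_qaly))
  cat(sprintf("  ICER £%.0f (95%% interval £%.0f to £%.0f)\n", x$icer_point,
              ci[1], ci[2]))
  p <- ceac(x, x$threshold)$probability
  cat(sprintf("  P(cost-effective at £%s/QALY) = %.3f\n",
              format(x$threshold, big.mark = ","), p))
  invisible(x)
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay threshold, the probability of being
#' cost-effective is the share of PSA draws with positive net monetary
#' benefit (dE x threshold - dC > 0), which is well defined in every
#' quadrant of the cost-effectiveness plane.
#'
#' @param psa A `cyto_psa` object.
#' @param thresholds Numeric vector of thresholds (GBP/QALY).
#' @return Data frame with columns `threshold` and `probability`.
#' @export
ceac <- function(psa, thresholds) {
  stopifnot(inherits(psa, "cyto_psa"))
  if (!length(thresholds)) stop("threshold grid is empty", call. = FALSE)
  prob <- vapply(thresholds, function(lambda) {
    mean(psa$draws$delta_qaly * lambda - psa$draws$delta_cost > 0)
  }, numeric(1))
  data.frame(threshold = thresholds, probability = prob)
}

#' Percentile interval for the per-draw ICER
#'
#' Percentile interval of the per-draw incremental cost-effectiveness
#' ratios. Draws with negative increments are retained, so the lower bound
#' can be negative (cost saving).
#'
#' @param psa A `cyto_psa` object.
#' @param level Coverage level in (0, 1); 0.95 gives the 2.5/97.5
#'   percentiles.
#' @return Numeric vector `c(low, high)`.
#' @export
icer_interval <- function(psa, level = 0.95) {
  stopifnot(inherits(psa, "cyto_psa"))
  if (level <= 0 || level >= 1) stop("level must lie in (0,1)",
                                     call. = FALSE)
  icers <- psa$draws$icer[!is.na(psa$draws$icer)]
  if (length(icers) < 2) stop("need at least 2 draws for an interval",
                              call. = FALSE)
  a <- (1 - level) / 2
  unname(quantile(icers, c(a, 1 - a)))
}

# ---- deterministic (one-way) sensitivity analysis ---------------------------

# internal: ICER after one structural modification
structural_icer <- function(params, what, value) {
  allocation <- table1_allocation(params)
  scenario <- params$scenario
  if (what == "uptake") {
    up <- scale_uptake(allocation, scenario, value)
    allocation <- up$allocation
    scenario <- up$scenario
  } else if (what == "start_age") {
    params$settings$start_age <- value
  } else if (what == "prevalence_BE") {
    f <- value / sum(params$prevalence)
    params$prevalence <- params$prevalence * f
    params$detected <- lapply(params$detected, function(d) d * f)
    allocation <- table1_allocation(params)
  } else if (what == "sensitivity") {
    f <- value / params$accuracy$sensitivity
    params$accuracy$sensitivity <- value
    params$detected$intervention <- params$detected$intervention * f
    allocation <- table1_allocation(params)
  } else {
    stop("unknown structural DSA parameter: ", what, call. = FALSE)
  }
  res <- run_cea(params, allocation = allocation, scenario = scenario)
  res$ce$icer
}

# structural DSA entries with their explicit ranges
dsa_structural_specs <- function() {
  data.frame(
    parameter = c("uptake", "start_age", "prevalence_BE", "sensitivity"),
    table = "structural",
    low = c(0.10, 50, 0.04, 0.764),
    high = c(0.50, 74, 0.12, 0.830),
    stringsAsFactors = FALSE)
}

#' One-way deterministic sensitivity analysis (tornado)
#'
#' Varies each parameter one at a time between its low and high bound
#' (explicit registry bounds where given, otherwise +/-20\% of the base
#' value clamped to the parameter's support), reruns the full base-case
#' pipeline and records the ICER at each bound. Structural parameters
#' (uptake, starting age, BE prevalence, Cytosponge sensitivity) rebuild
#' the cohort entry rather than only the Markov inputs. Entries are ranked
#' by the width of the induced ICER range.
#'
#' @param params Base `cyto_params`.
#' @param include_structural Include the structural funnel parameters.
#' @return A `cyto_dsa` data frame (parameter, table, low, high, icer_low,
#'   icer_high, range_width) sorted by descending width, with the base ICER
#'   as attribute `icer_base`.
#' @export
run_dsa <- function(params, include_structural = TRUE) {
  base_icer <- run_cea(params)$ce$icer

  eval_at <- function(table, parameter, value) {
    run_cea(set_param(params, table, parameter, value))$ce$icer
  }

  m <- params$meta
  sup_hi <- ifelse(m$table %in% c("transitions", "utilities", "disutilities"),
                   1, Inf)
  low <- ifelse(is.na(m$low), pmax(0, 0.8 * m$value), m$low)
  high <- ifelse(is.na(m$high), pmin(sup_hi, 1.2 * m$value), m$high)
  if (any(low > high)) stop("DSA bound with low > high", call. = FALSE)
  if (any(high > sup_hi + 1e-12)) {
    bad <- m$parameter[which(high > sup_hi + 1e-12)[1]]
    stop("DSA bound outside parameter support for '", bad, "'",
         call. = FALSE)
  }

  entries <- lapply(seq_len(nrow(m)), function(i) {
    data.frame(parameter = m$parameter[i], table = m$table[i],
               low = low[i], high = high[i],
               icer_low = eval_at(m$table[i], m$parameter[i], low[i]),
               icer_high = eval_at(m$table[i], m$parameter[i], high[i]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, entries)

  if (include_structural) {
    st <- dsa_structural_specs()
    st$icer_low <- NA_real_
    st$icer_high <- NA_real_
    for (i in seq_len(nrow(st))) {
      st$icer_low[i] <- structural_icer(params, st$parameter[i], st$low[i])
      st$icer_high[i] <- structural_icer(params, st$parameter[i], st$high[i])
    }
    out <- rbind(out, st)
  }

  out$range_width <- abs(out$icer_high - out$icer_low)
  out <- out[order(-out$range_width), ]
  rownames(out) <- NULL
  structure(out, class = c("cyto_dsa", "data.frame"), icer_base = base_icer)
}

#' @export
print.cyto_dsa <- function(x, n = 10, ...) {
  cat(sprintf("<cyto_dsa> one-way sensitivity of the ICER (base £%.0f)\n",
              attr(x, "icer_base")))
  df <- as.data.frame(x)[seq_len(min(n, nrow(x))), ]
  df$icer_low <- round(df$icer_low)
  df$icer_high <- round(df$icer_high)
  df$range_width <- round(df$range_width)
  print(df)
  invisible(x)
}
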