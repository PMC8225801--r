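#' @importFrom stats quantile rbeta rbinom rgamma runif setNames
#' @importFrom utils read.csv write.csv packageVersion
NULL

PROVENANCE_LEVELS <- c("paper-main-text", "paper-appendix", "assumption",
                       "derived-calibration")

# ---- constructors -----------------------------------------------------------

new_parameter_set <- function(settings, accuracy, scenario, prevalence,
                              detected, costs, utilities, disutilities,
                              transitions, life_table, meta) {
  structure(
    list(settings = settings, accuracy = accuracy, scenario = scenario,
         prevalence = prevalence, detected = detected, costs = costs,
         utilities = utilities, disutilities = disutilities,
         transitions = transitions, life_table = life_table, meta = meta),
    class = "cyto_params")
}

#' @export
print.cyto_params <- function(x, ...) {
  s <- x$settings
  cat("<cyto_params> Barrett esophagus screening model parameter set\n")
  cat(sprintf("  cohort: %s persons entering at age %s (horizon to age %s)\n",
              format(s$cohort_size), s$start_age, s$age_cap))
  cat(sprintf("  discount rate: %.1f%%/yr, WTP threshold: £%s/QALY\n",
              100 * s$discount_rate, format(s$wtp_threshold, big.mark = ",")))
  cat(sprintf("  Cytosponge-TFF3 sensitivity %.1f%%, specificity %.1f%%\n",
              100 * x$accuracy$sensitivity, 100 * x$accuracy$specificity))
  cat(sprintf("  BE prevalence (all stages): %.2f%%\n", 100 * sum(x$prevalence)))
  cat(sprintf("  %d registered parameters (%d with PSA distributions)\n",
              nrow(x$meta), sum(!is.na(x$meta$distribution) &
                                  nzchar(x$meta$distribution))))
  invisible(x)
}

# ---- loading ----------------------------------------------------------------

#' Load a model parameter set from configuration files
#'
#' Reads a YAML settings file plus the CSV parameter tables it references
#' (transitions, costs, utilities, disutilities, life table) and returns a
#' fully validated parameter set. Table paths in the YAML are resolved
#' relative to the YAML file's directory.
#'
#' @param path Path to the YAML settings file.
#' @param allow_defaults If `TRUE`, fields missing from the file fall back to
#'   the packaged base case; if `FALSE` (default) a missing field is an error.
#' @return A `cyto_params` object.
#' @seealso [base_case()], [write_parameters()]
#' @export
load_parameters <- function(path, allow_defaults = FALSE) {
  if (!file.exists(path)) {
    stop("parameter file not found: ", path, call. = FALSE)
  }
  cfg <- yaml::read_yaml(path)
  dir <- dirname(path)

  fallback <- if (allow_defaults) base_case() else NULL
  get_field <- function(block, name, where) {
    if (!is.null(block[[name]])) return(block[[name]])
    if (!is.null(fallback)) {
      return(fallback[[where]][[name]])
    }
    stop(sprintf("missing parameter '%s' in section '%s' of %s",
                 name, where, path), call. = FALSE)
  }

  st <- cfg$settings
  settings <- list(
    start_age     = get_field(st, "start_age", "settings"),
    cohort_size   = get_field(st, "cohort_size", "settings"),
    discount_rate = get_field(st, "discount_rate", "settings"),
    cycle_length  = get_field(st, "cycle_length", "settings"),
    age_cap       = get_field(st, "age_cap", "settings"),
    wtp_threshold = get_field(st, "wtp_threshold", "settings"),
    ppi_all_alive = isTRUE(get_field(st, "ppi_all_alive", "settings"))
  )

  ac <- cfg$accuracy
  accuracy <- list(
    sensitivity           = get_field(ac, "sensitivity", "accuracy"),
    specificity           = get_field(ac, "specificity", "accuracy"),
    endoscopy_sensitivity = get_field(ac, "endoscopy_sensitivity", "accuracy"),
    endoscopy_specificity = get_field(ac, "endoscopy_specificity", "accuracy")
  )

  sc <- cfg$scenario
  scenario <- screening_scenario(
    n_invited               = get_field(sc, "n_invited", "scenario"),
    n_swallowed             = get_field(sc, "n_swallowed", "scenario"),
    n_referred              = get_field(sc, "n_referred", "scenario"),
    n_endoscopy_intervention = get_field(sc, "n_endoscopy_intervention", "scenario"),
    n_endoscopy_usual       = get_field(sc, "n_endoscopy_usual", "scenario"),
    n_repeat_tests          = get_field(sc, "n_repeat_tests", "scenario"),
    n_repeat_endoscopies    = get_field(sc, "n_repeat_endoscopies", "scenario"),
    uptake                  = get_field(sc, "uptake", "scenario"),
    include_repeat          = isTRUE(sc$include_repeat)
  )

  prev_raw <- cfg$prevalence
  if (is.null(prev_raw) && !is.null(fallback)) {
    prevalence <- fallback$prevalence
  } else {
    prevalence <- vapply(prevalent_states(), function(s) {
      v <- prev_raw[[s]]
      if (is.null(v)) stop("missing prevalence entry for state ", s,
                           call. = FALSE)
      as.numeric(v)
    }, numeric(1))
  }

  det_block <- function(name) {
    d <- cfg$detected[[name]]
    if (is.null(d) && !is.null(fallback)) return(fallback$detected[[name]])
    vapply(prevalent_states(), function(s) {
      v <- d[[s]]
      if (is.null(v)) stop(sprintf("missing detected count '%s' for arm %s",
                                   s, name), call. = FALSE)
      as.numeric(v)
    }, numeric(1))
  }
  detected <- list(intervention = det_block("intervention"),
                   usual = det_block("usual"))

  read_table <- function(key) {
    f <- cfg$tables[[key]]
    if (is.null(f)) stop("settings file lists no '", key, "' table",
                         call. = FALSE)
    fp <- file.path(dir, f)
    if (!file.exists(fp)) stop("parameter table not found: ", fp,
                               call. = FALSE)
    read.csv(fp, stringsAsFactors = FALSE)
  }

  tr_tab <- read_table("transitions")
  co_tab <- read_table("costs")
  ut_tab <- read_table("utilities")
  du_tab <- read_table("disutilities")
  lt_tab <- read_table("life_table")

  as_named <- function(tab) setNames(as.numeric(tab$value), tab$parameter)
  transitions <- as.list(as_named(tr_tab))
  costs       <- as.list(as_named(co_tab))
  utilities   <- as_named(ut_tab)

  disutilities <- data.frame(
    event          = du_tab$event,
    decrement      = as.numeric(du_tab$decrement),
    duration_years = as.numeric(du_tab$duration_years),
    event_prob     = as.numeric(du_tab$event_prob),
    stringsAsFactors = FALSE)

  life_table <- data.frame(age = as.integer(lt_tab$age),
                           qx = as.numeric(lt_tab$qx))

  meta_cols <- function(tab, table_name, parameter_col = "parameter",
                        value_col = "value") {
    n <- nrow(tab)
    grab <- function(col, default) {
      if (col %in% names(tab)) suppressWarnings(as.numeric(tab[[col]]))
      else rep(default, n)
    }
    data.frame(
      table = table_name,
      parameter = tab[[parameter_col]],
      value = as.numeric(tab[[value_col]]),
      low = grab("low", NA_real_),
      high = grab("high", NA_real_),
      sd = grab("sd", NA_real_),
      distribution = if ("distribution" %in% names(tab))
        as.character(tab$distribution) else rep(NA_character_, n),
      provenance = if ("provenance" %in% names(tab))
        as.character(tab$provenance) else rep("assumption", n),
      stringsAsFactors = FALSE)
  }
  meta <- rbind(
    meta_cols(tr_tab, "transitions"),
    meta_cols(co_tab, "costs"),
    meta_cols(ut_tab, "utilities"),
    meta_cols(du_tab, "disutilities", parameter_col = "event",
              value_col = "decrement"))

  params <- new_parameter_set(settings, accuracy, scenario, prevalence,
                              detected, costs, utilities, disutilities,
                              transitions, life_table, meta)
  validate_parameters(params)
  params
}

#' Packaged base-case parameter set
#'
#' Returns the base-case parameter set shipped with the package: a cohort of
#' 6834 GERD patients entering at age 69, discounted at 3.5\% per year over a
#' lifetime horizon, Cytosponge-TFF3 sensitivity 79.9\% and specificity
#' 92.4\%, total Barrett prevalence near 9\%, and the associated cost,
#' utility, transition and life-table inputs. The function is pure: repeated
#' calls return identical values.
#'
#' @return A validated `cyto_params` object.
#' @export
#' @examples
#' p <- base_case()
#' p$accuracy$sensitivity   # 0.799
#' p$settings$wtp_threshold # 20000
base_case <- function() {
  path <- system.file("extdata", "base_case", "settings.yaml",
                      package = "cytoscreen", mustWork = TRUE)
  load_parameters(path, allow_defaults = FALSE)
}

#' Write a parameter set back to configuration files
#'
#' Serialises a parameter set to the same YAML + CSV layout read by
#' [load_parameters()], such that re-loading reproduces a semantically
#' identical object (round-trip property).
#'
#' @param params A `cyto_params` object.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the path of the written settings file.
#' @export
write_parameters <- function(params, dir) {
  stopifnot(inherits(params, "cyto_params"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)

  meta_for <- function(table_name) {
    params$meta[params$meta$table == table_name, , drop = FALSE]
  }
  write_tab <- function(table_name, file, parameter_col = "parameter",
                        value_col = "value", extra = NULL) {
    m <- meta_for(table_name)
    out <- data.frame(m$parameter, m$value, m$low, m$high, m$sd,
                      m$distribution, m$provenance, stringsAsFactors = FALSE)
    names(out) <- c(parameter_col, value_col, "low", "high", "sd",
                    "distribution", "provenance")
    if (!is.null(extra)) out <- cbind(out[1], extra, out[-1])
    write.csv(out, file.path(dir, file), row.names = FALSE, quote = FALSE)
    file
  }
  write_tab("transitions", "transitions.csv")
  write_tab("costs", "costs.csv")
  write_tab("utilities", "utilities.csv")

  du <- meta_for("disutilities")
  idx <- match(du$parameter, params$disutilities$event)
  du_out <- data.frame(event = du$parameter, decrement = du$value,
                       duration_years = params$disutilities$duration_years[idx],
                       event_prob = params$disutilities$event_prob[idx],
                       low = du$low, high = du$high, sd = du$sd,
                       distribution = du$distribution,
                       provenance = du$provenance, stringsAsFactors = FALSE)
  write.csv(du_out, file.path(dir, "disutilities.csv"), row.names = FALSE,
            quote = FALSE)
  write.csv(params$life_table, file.path(dir, "life_table.csv"),
            row.names = FALSE, quote = FALSE)

  sc <- params$scenario
  cfg <- list(
    settings = params$settings,
    accuracy = params$accuracy,
    scenario = list(
      n_invited = sc$n_invited, n_swallowed = sc$n_swallowed,
      n_referred = sc$n_referred,
      n_endoscopy_intervention = sc$n_endoscopy_intervention,
      n_endoscopy_usual = sc$n_endoscopy_usual,
      n_repeat_tests = sc$n_repeat_tests,
      n_repeat_endoscopies = sc$n_repeat_endoscopies,
      uptake = sc$uptake, include_repeat = sc$include_repeat),
    prevalence = as.list(params$prevalence),
    detected = list(intervention = as.list(params$detected$intervention),
                    usual = as.list(params$detected$usual)),
    tables = list(transitions = "transitions.csv", costs = "costs.csv",
                  utilities = "utilities.csv",
                  disutilities = "disutilities.csv",
                  life_table = "life_table.csv"))
  out <- file.path(dir, "settings.yaml")
  yaml::write_yaml(cfg, out, precision = 15)
  invisible(out)
}

# ---- validation -------------------------------------------------------------

check_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1) {
    stop(sprintf("parameter '%s' must be a probability in [0,1], got %s",
                 name, format(x)), call. = FALSE)
  }
  invisible(TRUE)
}

check_nonneg <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0) {
    stop(sprintf("parameter '%s' must be non-negative, got %s",
                 name, format(x)), call. = FALSE)
  }
  invisible(TRUE)
}

#' Validate a parameter set
#'
#' Checks every structural invariant of the parameter set: probabilities and
#' utilities in \[0,1\], non-negative costs, per-state outgoing disease
#' probabilities summing to at most 1, a prevalence vector summing to at most
#' 1, a life table covering every model age, recognised provenance tags, and
#' consistent settings. Errors name the offending parameter and value.
#'
#' @param params A `cyto_params` object.
#' @return Invisibly `TRUE`; otherwise an error.
#' @export
validate_parameters <- function(params) {
  stopifnot(inherits(params, "cyto_params"))
  s <- params$settings

  if (s$discount_rate < 0) {
    stop("parameter 'discount_rate' must be >= 0, got ", s$discount_rate,
         call. = FALSE)
  }
  if (s$cycle_length != 1) {
    stop("parameter 'cycle_length' must equal 1 year, got ", s$cycle_length,
         call. = FALSE)
  }
  if (s$start_age >= s$age_cap) {
    stop(sprintf("'start_age' (%s) must be below 'age_cap' (%s)",
                 s$start_age, s$age_cap), call. = FALSE)
  }
  check_nonneg(s$cohort_size, "cohort_size")
  check_nonneg(s$wtp_threshold, "wtp_threshold")

  for (nm in names(params$accuracy)) check_prob(params$accuracy[[nm]], nm)

  for (nm in names(params$costs)) check_nonneg(params$costs[[nm]], nm)

  for (st in names(params$utilities)) {
    check_prob(params$utilities[[st]], paste0("utility[", st, "]"))
  }
  if (!setequal(names(params$utilities), alive_states())) {
    stop("utilities must be defined for exactly the alive states; got: ",
         paste(names(params$utilities), collapse = ", "), call. = FALSE)
  }

  du <- params$disutilities
  for (i in seq_len(nrow(du))) {
    check_prob(du$decrement[i], paste0("disutility[", du$event[i], "]"))
    check_prob(du$event_prob[i], paste0("event_prob[", du$event[i], "]"))
    if (du$duration_years[i] <= 0) {
      stop(sprintf("disutility duration for '%s' must be > 0, got %s",
                   du$event[i], du$duration_years[i]), call. = FALSE)
    }
  }

  for (nm in names(params$transitions)) check_prob(params$transitions[[nm]], nm)
  # per-state outgoing disease probabilities sum to <= 1 (residual = stay)
  out_edges <- disease_edges()
  for (st in names(out_edges)) {
    tot <- sum(vapply(out_edges[[st]], function(e) params$transitions[[e]],
                      numeric(1)))
    if (tot > 1 + 1e-12) {
      stop(sprintf("outgoing disease probabilities from state '%s' sum to %.4f > 1",
                   st, tot), call. = FALSE)
    }
  }

  prev <- params$prevalence
  if (any(prev < 0)) {
    bad <- names(prev)[prev < 0][1]
    stop(sprintf("prevalence[%s] must be >= 0, got %s", bad,
                 format(prev[[bad]])), call. = FALSE)
  }
  if (sum(prev) > 1) {
    stop(sprintf("prevalence vector sums to %.4f > 1 (residual must be NoBE)",
                 sum(prev)), call. = FALSE)
  }

  lt <- params$life_table
  ages_needed <- seq(s$start_age, s$age_cap - 1)
  if (!all(ages_needed %in% lt$age)) {
    miss <- setdiff(ages_needed, lt$age)
    stop("life table missing required ages: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (any(lt$qx < 0 | lt$qx > 1)) {
    stop("life-table qx values must lie in [0,1]", call. = FALSE)
  }

  bad_prov <- setdiff(unique(params$meta$provenance), PROVENANCE_LEVELS)
  if (length(bad_prov)) {
    stop("unknown provenance tag(s): ", paste(bad_prov, collapse = ", "),
         call. = FALSE)
  }
  invisible(TRUE)
}

# disease-transition edge registry: from-state -> transition parameter names
disease_edges <- function() {
  list(
    NoBE     = c("p_NoBE_NDBE"),
    NDBE     = c("p_NDBE_LGD", "p_NDBE_EarlyEAC"),
    LGD      = c("p_LGD_NDBE", "p_LGD_HGD"),
    HGD      = c("p_HGD_EarlyEAC"),
    EarlyEAC = c("p_EarlyEAC_LateEAC")
  )
}

# destination state for each disease edge
edge_targets <- function() {
  c(p_NoBE_NDBE = "NDBE", p_NDBE_LGD = "LGD", p_NDBE_EarlyEAC = "EarlyEAC",
    p_LGD_NDBE = "NDBE", p_LGD_HGD = "HGD", p_HGD_EarlyEAC = "EarlyEAC",
    p_EarlyEAC_LateEAC = "LateEAC")
}

# ---- parameter updates (used by DSA / PSA) ----------------------------------

#' Set a single registered parameter
#'
#' Updates one entry of the parameter registry and the corresponding typed
#' slot, returning the modified set. Used by the sensitivity-analysis
#' machinery; validation can be deferred for speed when sweeping.
#'
#' @param params A `cyto_params` object.
#' @param table One of `"transitions"`, `"costs"`, `"utilities"`,
#'   `"disutilities"`.
#' @param parameter Parameter (or disutility event) name.
#' @param value New numeric value.
#' @param validate Re-validate the full set after the update.
#' @return The modified `cyto_params` object.
#' @export
set_param <- function(params, table, parameter, value, validate = FALSE) {
  i <- which(params$meta$table == table & params$meta$parameter == parameter)
  if (length(i) != 1) {
    stop(sprintf("unknown parameter '%s' in table '%s'", parameter, table),
         call. = FALSE)
  }
  params$meta$value[i] <- value
  switch(table,
    transitions = { params$transitions[[parameter]] <- value },
    costs = { params$costs[[parameter]] <- value },
    utilities = { params$utilities[[parameter]] <- value },
    disutilities = {
      params$disutilities$decrement[params$disutilities$event == parameter] <- value
    },
    stop("unknown parameter table: ", table, call. = FALSE))
  if (validate) validate_parameters(params)
  params
}

# internal: fetch a registry row
get_meta_row <- function(params, table, parameter) {
  i <- which(params$meta$table == table & params$meta$parameter == parameter)
  if (length(i) != 1) {
    stop(sprintf("unknown parameter '%s' in table '%s'", parameter, table),
         call. = FALSE)
  }
  params$meta[i, , drop = FALSE]
}
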