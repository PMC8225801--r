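# Shared fixtures: small deterministic parameter sets built in code, and an
# independent per-person microsimulation used as an oracle for the cohort
# engine.

base_params <- local({
  cached <- NULL
  function() {
    if (is.null(cached)) cached <<- base_case()
    cached
  }
})

# a parameter set with all disease dynamics switched off and a flat life
# table, for closed-form checks
flat_params <- function(qx = 0.1, utility = 1, discount = 0,
                        age_cap = NULL) {
  p <- base_params()
  for (nm in names(p$transitions)) {
    if (startsWith(nm, "p_")) p <- set_param(p, "transitions", nm, 0)
  }
  p$life_table$qx <- rep(qx, nrow(p$life_table))
  for (s in alive_states()) p <- set_param(p, "utilities", s, utility)
  p$settings$discount_rate <- discount
  if (!is.null(age_cap)) p$settings$age_cap <- age_cap
  p
}

# independent microsimulation oracle: per-person categorical sampling under
# the same age-specific matrices, half-cycle-corrected and discounted the
# same way the cohort engine aggregates.
microsim_oracle <- function(params, start_probs, n, seed) {
  set.seed(seed)
  s <- params$settings
  n_cycles <- s$age_cap - s$start_age
  mats <- lapply(seq_len(n_cycles), function(t) {
    build_transition_matrix(params, s$start_age + t - 1)
  })
  uvec <- c(params$utilities[alive_states()], Dead = 0)
  uvec <- uvec[health_states()]
  disc <- (1 + s$discount_rate)^-(seq_len(n_cycles))
  state <- sample.int(7, n, replace = TRUE, prob = start_probs)
  ly <- qaly <- numeric(n)
  for (t in seq_len(n_cycles)) {
    M <- mats[[t]]
    nxt <- state
    for (si in 1:6) {
      idx <- which(state == si)
      if (length(idx)) {
        nxt[idx] <- sample.int(7, length(idx), replace = TRUE,
                               prob = M[si, ])
      }
    }
    alive_h <- ((state != 7) + (nxt != 7)) / 2
    ly <- ly + disc[t] * alive_h
    qaly <- qaly + disc[t] * (uvec[state] + uvec[nxt]) / 2
    state <- nxt
  }
  list(ly = mean(ly), qaly = mean(qaly),
       se_ly = sd(ly) / sqrt(n), se_qaly = sd(qaly) / sqrt(n))
}
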