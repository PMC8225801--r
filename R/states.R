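#' Health states of the Barrett esophagus disease model
#'
#' The model space has seven states: no Barrett esophagus (NoBE),
#' non-dysplastic Barrett esophagus (NDBE), low-grade dysplasia (LGD),
#' high-grade dysplasia (HGD), early (curable) esophageal adenocarcinoma
#' (EarlyEAC), late (stage-4-like) adenocarcinoma (LateEAC) and Dead.
#' Dead is absorbing; utilities are defined only for the alive states.
#'
#' @return Character vector of the seven state labels, in severity order.
#' @export
#' @examples
#' health_states()
health_states <- function() {
  c("NoBE", "NDBE", "LGD", "HGD", "EarlyEAC", "LateEAC", "Dead")
}

#' Alive (non-absorbing) health states
#'
#' @return Character vector of the six alive states.
#' @export
alive_states <- function() {
  setdiff(health_states(), "Dead")
}

#' Diseased states carried in the prevalence vector
#'
#' States a GERD patient can occupy at entry other than NoBE; LateEAC and
#' Dead never occur at entry (a symptomatic stage-4 cancer would not be in
#' a screening cohort).
#'
#' @return Character vector of the four prevalent disease states.
#' @export
prevalent_states <- function() {
  c("NDBE", "LGD", "HGD", "EarlyEAC")
}

# internal: model arms and chains
model_arms <- function() c("intervention", "usual")
model_chains <- function() c("treatment", "natural_history")
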