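#' Physiotherapy scenario mix
#'
#' Physiotherapy cycle cost is a consultation fee plus a claims-derived
#' mixture of four modality-combination scenarios (weights from national
#' claims data). Beta concentration pairs per scenario drive PSA sampling
#' of the weights (renormalized to the simplex after sampling).
#'
#' @param scenario_costs Numeric vector of the four per-cycle scenario
#'   costs, USD.
#' @param weights Numeric vector of four mixture weights summing to 1.
#' @param consultation Consultation fee per treated cycle, USD.
#' @param beta_params Optional 4x2 matrix (or list of pairs) of Beta
#'   (alpha, beta) concentrations per scenario.
#' @return An object of class \code{ppcea_pt_mix}.
#' @export
pt_scenario_mix <- function(scenario_costs, weights, consultation,
                            beta_params = NULL) {
  stopifnot(length(scenario_costs) == 4, length(weights) == 4,
            all(scenario_costs >= 0), all(weights >= 0), consultation >= 0)
  if (abs(sum(weights) - 1) > 1e-6)
    stop(sprintf("scenario weights sum to %.8f, not 1", sum(weights)))
  if (!is.null(beta_params)) {
    if (is.list(beta_params)) beta_params <- do.call(rbind, beta_params)
    beta_params <- as.matrix(beta_params)
    stopifnot(nrow(beta_params) == 4, ncol(beta_params) == 2,
              all(beta_params > 0))
  }
  structure(list(scenario_costs = as.numeric(scenario_costs),
                 weights = as.numeric(weights),
                 consultation = consultation,
                 beta_params = beta_params),
            class = "ppcea_pt_mix")
}

#' Physiotherapy cost per treated cycle
#'
#' Consultation fee plus the weighted average of the four scenario costs.
#'
#' @param mix A [pt_scenario_mix()].
#' @return Cost per treated cycle, USD.
#' @export
#' @examples
#' mix <- pt_scenario_mix(c(43.83, 47.23, 61.40, 64.80),
#'                        c(0.25, 0.61, 0.08, 0.06), 107.53)
#' pt_cycle_cost(mix)  # 156.0978
pt_cycle_cost <- function(mix) {
  stopifnot(inherits(mix, "ppcea_pt_mix"))
  if (abs(sum(mix$weights) - 1) > 1e-6)
    stop("scenario weights do not sum to 1")
  mix$consultation + sum(mix$weights * mix$scenario_costs)
}

#' Per-state, per-arm cycle payoffs
#'
#' Holds the per-treated-cycle medical, transport and time costs, the
#' per-cycle productivity loss by state (accrued in every state including
#' mild), and the state utilities. The per-cycle QALY weight is
#' \code{utility * cycle_length_years} unless an explicit
#' \code{per_cycle_qaly} is supplied (the PSA samples that quantity
#' directly from its Beta distributions).
#'
#' @param arm \code{"PPT"} or \code{"PT"}.
#' @param medical_cost Medical cost per treated cycle, USD.
#' @param transport_cost Transport cost per treated cycle, USD.
#' @param time_cost Patient time cost per treated cycle, USD.
#' @param productivity_loss Named numeric vector (mild, moderate, severe):
#'   productivity loss per cycle by state, USD.
#' @param utility Named numeric vector of state utilities in [0, 1].
#' @param cycle_length_years Cycle length used to convert utility to a
#'   per-cycle QALY weight.
#' @param per_cycle_qaly Optional named vector of per-cycle QALY weights
#'   overriding \code{utility * cycle_length_years}.
#' @return An object of class \code{ppcea_payoffs}.
#' @export
payoff_schedule <- function(arm, medical_cost, transport_cost, time_cost,
                            productivity_loss, utility,
                            cycle_length_years = 0.25,
                            per_cycle_qaly = NULL) {
  arm <- match_arm(arm)
  states <- health_states()
  productivity_loss <- productivity_loss[states]
  utility <- utility[states]
  if (any(is.na(productivity_loss)) || any(is.na(utility)))
    stop("`productivity_loss` and `utility` must be named with the three states")
  stopifnot(medical_cost >= 0, transport_cost >= 0, time_cost >= 0,
            all(productivity_loss >= 0),
            all(utility >= 0 & utility <= 1))
  if (is.null(per_cycle_qaly)) {
    per_cycle_qaly <- utility * cycle_length_years
  } else {
    per_cycle_qaly <- per_cycle_qaly[states]
    if (any(is.na(per_cycle_qaly)) || any(per_cycle_qaly < 0))
      stop("`per_cycle_qaly` must be a non-negative named vector over the three states")
  }
  structure(list(arm = arm,
                 medical_cost_per_treated_cycle = medical_cost,
                 transport_cost_per_treated_cycle = transport_cost,
                 time_cost_per_treated_cycle = time_cost,
                 productivity_loss_per_cycle_by_state = productivity_loss,
                 utility_by_state = utility,
                 per_cycle_qaly_by_state = per_cycle_qaly),
            class = "ppcea_payoffs")
}

perspectives <- function() c("healthcare", "restricted_societal", "full_societal")

match_perspective <- function(perspective)
  match.arg(perspective, perspectives())
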