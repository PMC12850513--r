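#' Markov model settings
#'
#' Global settings of the cohort model: cycle length (3 months), horizon
#' (12 cycles = 3 years), annual discount rate (4.5%), initial state
#' distribution (the source trial enrolled only moderate/severe patients,
#' split 12:88), the willingness-to-pay threshold (30.5 million KRW
#' converted at the fixed 2021 rate of 1,144.61 KRW/USD), and the
#' accounting conventions: how the 2-cycle mild row is handled, whether
#' half-cycle correction is applied, and whether cycle t is discounted at
#' the start (\code{(1+r)^(-t*dt)}, cycle 0 undiscounted) or end of the
#' cycle.
#'
#' @param cycle_length_years Cycle length as a fraction of a year.
#' @param horizon_cycles Number of cycles simulated.
#' @param annual_discount_rate Annual discount rate for costs and QALYs.
#' @param initial_distribution Named probability vector over the three
#'   states; must sum to 1 and place no mass on mild.
#' @param wtp_per_qaly Willingness-to-pay threshold, USD per QALY.
#' @param krw_per_usd Fixed KRW/USD exchange rate used for conversion.
#' @param mild_handling_mode See [per_cycle_matrix()].
#' @param cycle_correction \code{"none"} (accrue on the occupancy entering
#'   each cycle) or \code{"half_cycle"} (average of entering and leaving
#'   occupancy).
#' @param discount_timing \code{"cycle_start"} or \code{"cycle_end"}.
#' @return An object of class \code{ppcea_model_spec}.
#' @export
model_spec <- function(cycle_length_years = 0.25,
                       horizon_cycles = 12L,
                       annual_discount_rate = 0.045,
                       initial_distribution = c(mild = 0, moderate = 0.12, severe = 0.88),
                       wtp_per_qaly = 30500000 / 1144.61,
                       krw_per_usd = 1144.61,
                       mild_handling_mode = c("tunnel", "matrix_root", "direct"),
                       cycle_correction = c("none", "half_cycle"),
                       discount_timing = c("cycle_start", "cycle_end")) {
  mild_handling_mode <- match.arg(mild_handling_mode)
  cycle_correction <- match.arg(cycle_correction)
  discount_timing <- match.arg(discount_timing)
  stopifnot(cycle_length_years > 0, horizon_cycles >= 1,
            annual_discount_rate >= 0, wtp_per_qaly > 0, krw_per_usd > 0)
  pi0 <- initial_distribution[health_states()]
  if (any(is.na(pi0)))
    stop("`initial_distribution` must be named with the three states")
  if (abs(sum(pi0) - 1) > 1e-9)
    stop("`initial_distribution` must sum to 1")
  if (any(pi0 < 0)) stop("`initial_distribution` must be non-negative")
  if (pi0[["mild"]] != 0)
    stop("initial mild occupancy must be 0 (trial enrolled moderate/severe only)")
  structure(
    list(cycle_length_years = cycle_length_years,
         horizon_cycles = as.integer(horizon_cycles),
         annual_discount_rate = annual_discount_rate,
         initial_distribution = pi0,
         wtp_per_qaly = wtp_per_qaly,
         krw_per_usd = krw_per_usd,
         mild_handling_mode = mild_handling_mode,
         cycle_correction = cycle_correction,
         discount_timing = discount_timing),
    class = "ppcea_model_spec")
}

#' @export
print.ppcea_model_spec <- function(x, ...) {
  cat(sprintf(
    "Markov model spec: %d cycles of %.2f y, discount %.1f%%/y, WTP %.0f USD/QALY\n",
    x$horizon_cycles, x$cycle_length_years, 100 * x$annual_discount_rate,
    x$wtp_per_qaly))
  cat(sprintf("conventions: mild=%s, correction=%s, discounting=%s\n",
              x$mild_handling_mode, x$cycle_correction, x$discount_timing))
  invisible(x)
}

#' Per-cycle discount factor
#'
#' Under \code{cycle_start} timing cycle t is discounted by
#' \code{(1 + r)^(-t * dt)} (cycle 0 undiscounted); under \code{cycle_end}
#' by \code{(1 + r)^(-(t + 1) * dt)}.
#'
#' @param cycle_index Integer cycle index (0-based); vectorized.
#' @param spec A [model_spec()].
#' @return Discount factor(s) in (0, 1].
#' @export
#' @examples
#' sp <- model_spec()
#' discount_factor(0, sp)   # 1
#' discount_factor(4, sp)   # 1.045^-1
discount_factor <- function(cycle_index, spec) {
  stopifnot(inherits(spec, "ppcea_model_spec"))
  if (any(cycle_index < 0)) stop("`cycle_index` must be non-negative")
  t_eff <- if (spec$discount_timing == "cycle_start") cycle_index else cycle_index + 1
  (1 + spec$annual_discount_rate)^(-t_eff * spec$cycle_length_years)
}

#' Run the deterministic cohort simulation
#'
#' Starting from the initial distribution, the occupancy row vector is
#' repeatedly left-multiplied by the per-cycle transition matrix (expanded
#' per the spec's mild handling mode) for \code{horizon_cycles} cycles.
#' Purely deterministic; the trace is the basis of all cost/QALY accrual.
#'
#' @param spec A [model_spec()].
#' @param model A [transition_model()].
#' @return An object of class \code{ppcea_cohort_trace} with the expanded
#'   \code{occupancy} matrix (rows = cycles 0..T) and
#'   \code{collapsed_occupancy} over the three clinical states.
#' @export
run_cohort <- function(spec, model) {
  stopifnot(inherits(spec, "ppcea_model_spec"),
            inherits(model, "ppcea_transition_model"))
  ex <- per_cycle_matrix(model, spec$mild_handling_mode)
  M <- ex$matrix
  n <- length(ex$states)
  T <- spec$horizon_cycles

  p <- numeric(n)
  names(p) <- ex$states
  for (s in health_states()) {
    idx <- which(ex$collapse == s)
    # initial mass enters the first sub-state of a tunnel
    p[idx[1]] <- spec$initial_distribution[[s]]
  }

  occ <- matrix(0, T + 1, n, dimnames = list(0:T, ex$states))
  occ[1, ] <- p
  for (t in seq_len(T)) {
    p <- as.vector(p %*% M)
    occ[t + 1, ] <- p
  }

  coll <- sapply(health_states(), function(s)
    rowSums(occ[, ex$collapse == s, drop = FALSE]))
  dimnames(coll) <- list(0:T, health_states())

  structure(
    list(arm = model$arm, occupancy = occ, collapsed_occupancy = coll,
         states = ex$states, collapse = ex$collapse,
         mild_handling_mode = spec$mild_handling_mode),
    class = "ppcea_cohort_trace")
}

#' @export
print.ppcea_cohort_trace <- function(x, ...) {
  cat(sprintf("Cohort trace, arm %s (%d cycles, mild handling: %s)\n",
              x$arm, nrow(x$collapsed_occupancy) - 1L, x$mild_handling_mode))
  print(round(utils::head(x$collapsed_occupancy, 5), 4))
  if (nrow(x$collapsed_occupancy) > 5) cat("...\n")
  invisible(x)
}

#' Write a cohort trace to CSV
#'
#' One row per cycle: cycle index, collapsed occupancy of the three states,
#' and the discount factor applying to that cycle.
#'
#' @param trace A [run_cohort()] result.
#' @param spec The [model_spec()] used (for discount factors).
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_trace_csv <- function(trace, spec, path) {
  stopifnot(inherits(trace, "ppcea_cohort_trace"))
  cycles <- seq_len(nrow(trace$collapsed_occupancy)) - 1L
  df <- data.frame(cycle = cycles,
                   trace$collapsed_occupancy,
                   discount_factor = discount_factor(cycles, spec))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
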