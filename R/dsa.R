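#' Perturb one element of a probability row
#'
#' Shifts the target element by \code{delta}, clips it to [0, 1], and
#' rescales the remaining elements proportionally so the row sums to 1.
#' When the remaining elements are all zero the freed (or required) mass is
#' split equally among them.
#'
#' @param row Probability vector summing to 1.
#' @param element_index Index of the element to shift.
#' @param delta Shift to apply.
#' @return A valid probability vector.
#' @export
#' @examples
#' perturb_probability_row(c(0.612, 0.321, 0.067), 1, 0.079)
perturb_probability_row <- function(row, element_index, delta) {
  stopifnot(is.numeric(row), all(row >= 0), abs(sum(row) - 1) < 1e-6,
            element_index >= 1, element_index <= length(row))
  new_val <- min(max(row[element_index] + delta, 0), 1)
  rest <- setdiff(seq_along(row), element_index)
  out <- row
  out[element_index] <- new_val
  remainder <- 1 - new_val
  rest_sum <- sum(row[rest])
  if (rest_sum > 0) {
    out[rest] <- row[rest] * remainder / rest_sum
  } else {
    out[rest] <- remainder / length(rest)
  }
  if (all(out == 0)) stop("perturbation produced an all-zero row")
  out / sum(out)
}

#' One-way sensitivity parameter ranges from a configuration
#'
#' Builds the default deterministic-sensitivity parameter list: discount
#' rate (3.5--6%), horizon (1--5 years), initial severity split (+/- 0.03
#' on the moderate share), per-arm medical cycle costs (+/- 10%), transport
#' and time costs (+/- their standard errors), per-state productivity
#' losses (+/- SE), per-cycle QALY weights (+/- 0.003), each transition
#' row element (+/- its published range, clipped to [0, 1]; the pooled
#' mild row is a single set of parameters applied to both arms), and the
#' physiotherapy scenario weights (base to 100%).
#'
#' @param config A \code{ppcea_config}.
#' @return A data.frame with columns \code{name}, \code{base}, \code{low},
#'   \code{high}, \code{kind}.
#' @export
dsa_parameter_ranges <- function(config) {
  stopifnot(inherits(config, "ppcea_config"))
  d <- config$dsa
  spec <- config$model
  rng <- list()
  add <- function(name, base, low, high, kind)
    rng[[length(rng) + 1L]] <<- data.frame(
      name = name, base = base, low = low, high = high, kind = kind,
      stringsAsFactors = FALSE)

  add("discount_rate", spec$annual_discount_rate,
      d$discount_rate_range[1], d$discount_rate_range[2], "rate")
  add("horizon_years", spec$horizon_cycles * spec$cycle_length_years,
      d$horizon_years_range[1], d$horizon_years_range[2], "horizon")
  p_mod <- spec$initial_distribution[["moderate"]]
  add("initial_moderate", p_mod,
      max(p_mod - d$initial_moderate_delta, 0),
      min(p_mod + d$initial_moderate_delta, 1), "probability_row")
  for (a in arms()) {
    med <- config$payoffs[[a]]$medical_cost_per_treated_cycle
    add(paste0("medical_cost_", a), med,
        med * (1 - d$medical_cost_fraction),
        med * (1 + d$medical_cost_fraction), "cost")
    tr <- config$payoffs[[a]]$transport_cost_per_treated_cycle
    add(paste0("transport_", a), tr,
        max(tr - d$transport_delta[[a]], 0), tr + d$transport_delta[[a]], "cost")
    tc <- config$payoffs[[a]]$time_cost_per_treated_cycle
    add(paste0("time_", a), tc,
        max(tc - d$time_delta[[a]], 0), tc + d$time_delta[[a]], "cost")
  }
  for (s in health_states()) {
    pl <- config$productivity$per_cycle[[s]]
    add(paste0("productivity_", s), pl,
        max(pl - d$productivity_delta[[s]], 0),
        pl + d$productivity_delta[[s]], "cost")
    q <- config$payoffs$PPT$per_cycle_qaly_by_state[[s]]
    add(paste0("qaly_", s), q,
        max(q - d$qaly_delta, 0), q + d$qaly_delta, "utility")
  }
  # transition elements: pooled mild row once, moderate/severe per arm
  states <- health_states()
  for (j in seq_along(states)) {
    base <- config$transitions$PPT$rows["mild", j]
    delta <- d$transition_delta$PPT$mild[j]
    add(paste0("trans_pooled_mild_", states[j]), base,
        max(base - delta, 0), min(base + delta, 1), "probability_row")
  }
  for (a in arms()) {
    for (s in c("moderate", "severe")) {
      for (j in seq_along(states)) {
        base <- config$transitions[[a]]$rows[s, j]
        delta <- d$transition_delta[[a]][[s]][j]
        add(paste0("trans_", a, "_", s, "_", states[j]), base,
            max(base - delta, 0), min(base + delta, 1), "probability_row")
      }
    }
  }
  for (i in 1:4) {
    w <- config$pt_mix$weights[i]
    add(paste0("scenario_weight_", i), w, w, 1, "weight")
  }
  do.call(rbind, rng)
}

# Apply a named DSA parameter value to a configuration, returning a new
# configuration. Probability-row elements are applied via
# perturb_probability_row (delta = value - base).
apply_dsa_value <- function(config, name, value) {
  cfg <- config
  states <- health_states()
  set_row <- function(tm, row_name, j, value) {
    row <- tm$rows[row_name, ]
    tm$rows[row_name, ] <- perturb_probability_row(row, j, value - row[j])
    tm
  }
  if (name == "discount_rate") {
    cfg$model$annual_discount_rate <- value
  } else if (name == "horizon_years") {
    cfg$model$horizon_cycles <-
      as.integer(round(value / cfg$model$cycle_length_years))
  } else if (name == "initial_moderate") {
    cfg$model$initial_distribution <-
      c(mild = 0, moderate = value, severe = 1 - value)
  } else if (grepl("^medical_cost_", name)) {
    a <- sub("^medical_cost_", "", name)
    cfg$payoffs[[a]]$medical_cost_per_treated_cycle <- value
  } else if (grepl("^transport_", name)) {
    a <- sub("^transport_", "", name)
    cfg$payoffs[[a]]$transport_cost_per_treated_cycle <- value
  } else if (grepl("^time_", name)) {
    a <- sub("^time_", "", name)
    cfg$payoffs[[a]]$time_cost_per_treated_cycle <- value
  } else if (grepl("^productivity_", name)) {
    s <- sub("^productivity_", "", name)
    for (a in arms())
      cfg$payoffs[[a]]$productivity_loss_per_cycle_by_state[[s]] <- value
  } else if (grepl("^qaly_", name)) {
    s <- sub("^qaly_", "", name)
    for (a in arms())
      cfg$payoffs[[a]]$per_cycle_qaly_by_state[[s]] <- value
  } else if (grepl("^trans_pooled_mild_", name)) {
    s_to <- sub("^trans_pooled_mild_", "", name)
    j <- match(s_to, states)
    for (a in arms())
      cfg$transitions[[a]] <- set_row(cfg$transitions[[a]], "mild", j, value)
  } else if (grepl("^trans_", name)) {
    parts <- strsplit(name, "_")[[1]]  # trans, arm, from, to
    a <- parts[2]; s_from <- parts[3]; s_to <- parts[4]
    if (!a %in% arms() || !s_from %in% states || !s_to %in% states)
      stop(sprintf("unknown parameter '%s'", name))
    cfg$transitions[[a]] <- set_row(cfg$transitions[[a]], s_from,
                                    match(s_to, states), value)
  } else if (grepl("^scenario_weight_", name)) {
    i <- as.integer(sub("^scenario_weight_", "", name))
    w <- perturb_probability_row(cfg$pt_mix$weights, i,
                                 value - cfg$pt_mix$weights[i])
    cfg$pt_mix$weights <- w
    cfg$payoffs$PT$medical_cost_per_treated_cycle <- pt_cycle_cost(cfg$pt_mix)
  } else {
    stop(sprintf("unknown parameter '%s'; valid names: %s", name,
                 paste(dsa_parameter_ranges(config)$name, collapse = ", ")))
  }
  cfg
}

#' One-way deterministic sensitivity analysis
#'
#' Re-runs the full base case at the low and high end of each parameter
#' range (all other parameters at base), recording the ICER and the net
#' monetary benefit at the WTP threshold at each end. Results are ordered
#' by descending NMB spread (tornado order); ties keep input order. NMB is
#' the ranking metric because the ICER changes sign near zero incremental
#' QALYs.
#'
#' @param config A \code{ppcea_config}.
#' @param ranges A data.frame as produced by [dsa_parameter_ranges()]
#'   (the default).
#' @param perspective Costing perspective to evaluate.
#' @return A data.frame of class \code{ppcea_dsa_results}: parameter, low
#'   and high input values, ICER and NMB at each end, and the NMB spread.
#' @export
run_one_way <- function(config, ranges = dsa_parameter_ranges(config),
                        perspective = c("healthcare", "restricted_societal",
                                        "full_societal")) {
  stopifnot(inherits(config, "ppcea_config"))
  perspective <- match.arg(perspective)
  if (is.null(ranges) || nrow(ranges) == 0) {
    out <- data.frame(parameter = character(0), low = numeric(0),
                      high = numeric(0), icer_low = numeric(0),
                      icer_high = numeric(0), nmb_low = numeric(0),
                      nmb_high = numeric(0), spread = numeric(0),
                      stringsAsFactors = FALSE)
    class(out) <- c("ppcea_dsa_results", class(out))
    return(out)
  }

  eval_at <- function(name, value) {
    bc <- run_base_case(apply_dsa_value(config, name, value))
    r <- bc$results[[perspective]]
    c(icer = unname(r$icer), nmb = unname(r$nmb))
  }

  rows <- lapply(seq_len(nrow(ranges)), function(i) {
    nm <- ranges$name[i]
    lo <- eval_at(nm, ranges$low[i])
    hi <- eval_at(nm, ranges$high[i])
    data.frame(parameter = nm, low = ranges$low[i], high = ranges$high[i],
               icer_low = lo[["icer"]], icer_high = hi[["icer"]],
               nmb_low = lo[["nmb"]], nmb_high = hi[["nmb"]],
               spread = abs(hi[["nmb"]] - lo[["nmb"]]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$spread), , drop = FALSE]  # stable for ties
  rownames(out) <- NULL
  attr(out, "perspective") <- perspective
  class(out) <- c("ppcea_dsa_results", class(out))
  out
}

#' Write one-way sensitivity results to CSV (tornado order)
#'
#' @param dsa A [run_one_way()] result.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_dsa_csv <- function(dsa, path) {
  stopifnot(inherits(dsa, "ppcea_dsa_results"))
  utils::write.csv(as.data.frame(dsa), path, row.names = FALSE)
  invisible(path)
}
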