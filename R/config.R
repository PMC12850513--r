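#' Load and validate an analysis configuration
#'
#' The configuration is a JSON document holding every model constant: the
#' model settings (cycle length, horizon, discount rate, initial severity
#' split, WTP threshold in KRW, exchange rate, accounting conventions),
#' per-arm transition rows with Dirichlet concentrations, per-arm cost
#' components with their standard errors, the physiotherapy scenario mix
#' with per-scenario Beta concentrations, state utilities with Beta
#' concentrations on the per-cycle QALY scale, one-way sensitivity deltas,
#' PSA settings, and (optionally) a synthetic-trial block. Monetary inputs
#' are stored in USD as published; the WTP threshold is stored in KRW and
#' converted once at load using the fixed exchange rate. Validation
#' collects every violation before failing.
#'
#' @param path Path to a JSON configuration file.
#' @return An object of class \code{ppcea_config}.
#' @seealso [default_config()], [write_config()]
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path))
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  config_from_list(raw, source_path = path)
}

#' The packaged default configuration
#'
#' Encodes the published model inputs verbatim: costs, utilities and
#' assumptions, and the transition probabilities with their Dirichlet
#' concentrations, plus the accounting conventions selected by
#' [calibrate_conventions()] against the published base case.
#'
#' @return An object of class \code{ppcea_config}.
#' @export
default_config <- function() {
  load_config(system.file("extdata", "default_config.json",
                          package = "ppcea", mustWork = TRUE))
}

state_vec <- function(x, what, errs) {
  v <- unlist(x)[health_states()]
  if (any(is.na(v)))
    errs$add(sprintf("%s: must be named with mild/moderate/severe", what))
  v
}

config_from_list <- function(raw, source_path = NULL) {
  errors <- character(0)
  errs <- list(add = function(msg) errors <<- c(errors, msg))

  need <- function(block, fields) {
    miss <- setdiff(fields, names(block))
    if (length(miss)) errs$add(sprintf("missing fields: %s",
                                       paste(miss, collapse = ", ")))
    length(miss) == 0
  }

  if (!need(raw, c("model", "transitions", "costs", "productivity_loss",
                   "utility", "dsa", "psa")))
    stop(paste(c("invalid configuration:", errors), collapse = "\n  "))

  m <- raw$model
  wtp_usd <- if (!is.null(m$wtp_krw)) m$wtp_krw / m$krw_per_usd else m$wtp_per_qaly
  spec <- tryCatch(
    model_spec(cycle_length_years = m$cycle_length_years,
               horizon_cycles = m$horizon_cycles,
               annual_discount_rate = m$annual_discount_rate,
               initial_distribution = unlist(m$initial_distribution),
               wtp_per_qaly = wtp_usd,
               krw_per_usd = m$krw_per_usd,
               mild_handling_mode = m$mild_handling_mode,
               cycle_correction = m$cycle_correction,
               discount_timing = m$discount_timing),
    error = function(e) { errs$add(sprintf("model: %s", conditionMessage(e))); NULL })

  transitions <- list()
  for (a in arms()) {
    tr <- raw$transitions[[a]]
    if (is.null(tr)) { errs$add(sprintf("transitions.%s: missing", a)); next }
    transitions[[a]] <- tryCatch(
      transition_model(rows = lapply(tr$rows, unlist),
                       alphas = if (!is.null(tr$alphas)) lapply(tr$alphas, unlist),
                       arm = a,
                       mild_row_interval_cycles = tr$mild_row_interval_cycles %||% 2L),
      error = function(e) { errs$add(sprintf("transitions.%s: %s", a, conditionMessage(e))); NULL })
  }
  if (!is.null(transitions$PPT) && !is.null(transitions$PT) &&
      any(abs(transitions$PPT$rows["mild", ] - transitions$PT$rows["mild", ]) > 1e-9))
    errs$add("transitions: mild rows must be identical across arms (pooled estimate)")

  util <- state_vec(raw$utility$by_state, "utility.by_state", errs)
  prod_loss <- state_vec(raw$productivity_loss$per_cycle,
                         "productivity_loss.per_cycle", errs)

  cp <- raw$costs$PPT
  ct <- raw$costs$PT
  pt_mix <- tryCatch(
    pt_scenario_mix(scenario_costs = unlist(ct$scenarios$costs),
                    weights = unlist(ct$scenarios$weights),
                    consultation = ct$consultation,
                    beta_params = ct$scenarios$beta),
    error = function(e) { errs$add(sprintf("costs.PT.scenarios: %s", conditionMessage(e))); NULL })

  payoffs <- NULL
  if (length(errors) == 0) {
    payoffs <- list(
      PPT = payoff_schedule("PPT",
        medical_cost = sum(unlist(cp$medical_components)),
        transport_cost = cp$transport, time_cost = cp$time,
        productivity_loss = prod_loss, utility = util,
        cycle_length_years = spec$cycle_length_years),
      PT = payoff_schedule("PT",
        medical_cost = pt_cycle_cost(pt_mix),
        transport_cost = ct$transport, time_cost = ct$time,
        productivity_loss = prod_loss, utility = util,
        cycle_length_years = spec$cycle_length_years))
  }

  if (length(errors))
    stop(paste(c("invalid configuration:", errors), collapse = "\n  "))

  structure(
    list(model = spec,
         transitions = transitions,
         payoffs = payoffs,
         pt_mix = pt_mix,
         utility = list(by_state = util,
                        qaly_beta = lapply(raw$utility$qaly_beta, unlist)),
         costs = list(
           PPT = list(medical_components = unlist(cp$medical_components),
                      transport = cp$transport, time = cp$time,
                      time_se = cp$time_se),
           PT = list(consultation = ct$consultation,
                     transport = ct$transport, time = ct$time,
                     time_se = ct$time_se)),
         productivity = list(per_cycle = prod_loss,
                             se = state_vec(raw$productivity_loss$se,
                                            "productivity_loss.se", errs)),
         dsa = raw$dsa,
         psa = raw$psa,
         trial = raw$trial,
         raw = raw,
         source_path = source_path),
    class = "ppcea_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Serialize a configuration back to JSON
#'
#' Writes the raw configuration tree; \code{load_config(write_config(cfg))}
#' yields an equivalent configuration (round trip).
#'
#' @param config A \code{ppcea_config}.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "ppcea_config"))
  jsonlite::write_json(config$raw, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' MD5 hash of a configuration
#'
#' Hash of the canonical JSON serialization, recorded in every output so
#' runs can be regenerated exactly.
#'
#' @param config A \code{ppcea_config}.
#' @return Character MD5 digest.
#' @export
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config$raw, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

#' @export
print.ppcea_config <- function(x, ...) {
  cat("ppcea analysis configuration\n")
  print(x$model)
  cat(sprintf("PPT medical cost/cycle %.2f USD; PT %.2f USD (consultation + scenario mix)\n",
              x$payoffs$PPT$medical_cost_per_treated_cycle,
              x$payoffs$PT$medical_cost_per_treated_cycle))
  cat(sprintf("utilities: %s\n",
              paste(sprintf("%s %.3f", health_states(), x$utility$by_state),
                    collapse = ", ")))
  invisible(x)
}
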