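#' Sample one Dirichlet draw
#'
#' Standard Gamma-ratio construction; used for transition-row uncertainty.
#'
#' @param alpha Positive concentration vector.
#' @return One probability vector of the same length.
#' @export
rdirichlet1 <- function(alpha) {
  stopifnot(all(alpha > 0))
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  while (sum(g) == 0) g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  g / sum(g)
}

# Gamma draw parameterized by mean and standard error:
# shape = mean^2/se^2, scale = se^2/mean.
rgamma_mean_se <- function(n, mean, se) {
  stopifnot(mean > 0, se > 0)
  stats::rgamma(n, shape = mean^2 / se^2, scale = se^2 / mean)
}

#' Draw one sampled parameter configuration
#'
#' Implements the probabilistic-sensitivity-analysis distributions: Beta
#' for per-cycle QALY weights (the published concentrations' means match
#' the per-cycle values, so draws are used as QALY weights directly, not
#' re-multiplied by cycle length) and for the four physiotherapy scenario
#' weights (renormalized to the simplex after sampling); Gamma
#' (mean = base value, SD = published SE) for time and productivity costs;
#' Gamma with SE fixed at 10% of the mean for transportation; Dirichlet
#' with the published concentrations for transition rows, the pooled mild
#' row drawn once and shared by both arms. Medical unit costs are fixed
#' and never sampled. Uses the current RNG state; seed management belongs
#' to [run_psa()].
#'
#' @param config Base \code{ppcea_config}.
#' @return A new \code{ppcea_config} with sampled values in place.
#' @export
sample_parameters <- function(config) {
  stopifnot(inherits(config, "ppcea_config"))
  cfg <- config
  states <- health_states()

  # transition rows: pooled mild once, then per-arm moderate/severe
  mild_alpha <- config$transitions$PPT$dirichlet_alpha["mild", ]
  if (is.null(mild_alpha)) stop("missing Dirichlet concentrations for the mild row")
  mild_row <- rdirichlet1(mild_alpha)
  for (a in arms()) {
    tm <- cfg$transitions[[a]]
    if (is.null(tm$dirichlet_alpha))
      stop(sprintf("missing Dirichlet concentrations for arm %s", a))
    tm$rows["mild", ] <- mild_row
    for (s in c("moderate", "severe"))
      tm$rows[s, ] <- rdirichlet1(tm$dirichlet_alpha[s, ])
    cfg$transitions[[a]] <- tm
  }

  # per-cycle QALY weights: Beta draws used directly
  qb <- config$utility$qaly_beta
  if (is.null(qb) || !all(states %in% names(qb)))
    stop("missing Beta concentrations for per-cycle QALY weights")
  q <- vapply(states, function(s) stats::rbeta(1, qb[[s]][1], qb[[s]][2]),
              numeric(1))

  # costs: Gamma around base values
  se_frac <- config$psa$transport_se_fraction %||% 0.10
  prod_draw <- vapply(states, function(s)
    rgamma_mean_se(1, config$productivity$per_cycle[[s]],
                   config$productivity$se[[s]]), numeric(1))
  for (a in arms()) {
    po <- cfg$payoffs[[a]]
    tr_mean <- config$costs[[a]]$transport
    po$transport_cost_per_treated_cycle <-
      rgamma_mean_se(1, tr_mean, se_frac * tr_mean)
    po$time_cost_per_treated_cycle <-
      rgamma_mean_se(1, config$costs[[a]]$time, config$costs[[a]]$time_se)
    po$productivity_loss_per_cycle_by_state[states] <- prod_draw
    po$per_cycle_qaly_by_state[states] <- q
    cfg$payoffs[[a]] <- po
  }

  # physiotherapy scenario weights: marginal Betas, renormalized
  bp <- config$pt_mix$beta_params
  if (!is.null(bp)) {
    w <- vapply(1:4, function(i) stats::rbeta(1, bp[i, 1], bp[i, 2]),
                numeric(1))
    cfg$pt_mix$weights <- w / sum(w)
    cfg$payoffs$PT$medical_cost_per_treated_cycle <- pt_cycle_cost(cfg$pt_mix)
  }
  # PPT medical components and PT consultation are fixed unit costs
  cfg
}

#' Probabilistic sensitivity analysis
#'
#' Monte-Carlo simulation: each iteration draws one complete parameter
#' configuration with [sample_parameters()] and runs the full deterministic
#' base case, storing per-iteration arm-level discounted costs (per
#' perspective) and QALYs. A master seed yields one sub-seed per iteration,
#' so results are reproducible and independent of evaluation order.
#'
#' @param config Base \code{ppcea_config}.
#' @param n_iterations Number of Monte-Carlo iterations (published
#'   analysis: 1,000).
#' @param seed Master RNG seed; defaults to the config's PSA seed.
#' @return An object of class \code{ppcea_psa_results} with the per-
#'   iteration \code{draws} data.frame, per-perspective summaries, the
#'   seed, and the WTP threshold.
#' @export
run_psa <- function(config, n_iterations = config$psa$n_iterations,
                    seed = config$psa$seed) {
  stopifnot(inherits(config, "ppcea_config"), n_iterations >= 1)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, n_iterations)

  cols <- c("qaly_ppt", "qaly_pt",
            paste0("cost_ppt_", perspectives()),
            paste0("cost_pt_", perspectives()))
  draws <- matrix(NA_real_, n_iterations, length(cols),
                  dimnames = list(NULL, cols))
  for (i in seq_len(n_iterations)) {
    set.seed(sub_seeds[i])
    cfg_i <- sample_parameters(config)
    bc <- run_base_case(cfg_i)
    draws[i, "qaly_ppt"] <- bc$results$healthcare$total_qaly[["PPT"]]
    draws[i, "qaly_pt"]  <- bc$results$healthcare$total_qaly[["PT"]]
    for (p in perspectives()) {
      draws[i, paste0("cost_ppt_", p)] <- bc$results[[p]]$total_cost[["PPT"]]
      draws[i, paste0("cost_pt_", p)]  <- bc$results[[p]]$total_cost[["PT"]]
    }
  }
  draws <- as.data.frame(draws)
  if (any(!is.finite(as.matrix(draws)))) stop("non-finite PSA draw encountered")

  summaries <- do.call(rbind, lapply(perspectives(), function(p) {
    data.frame(
      perspective = p,
      arm = arms(),
      mean_cost = c(mean(draws[[paste0("cost_ppt_", p)]]),
                    mean(draws[[paste0("cost_pt_", p)]])),
      sd_cost = c(stats::sd(draws[[paste0("cost_ppt_", p)]]),
                  stats::sd(draws[[paste0("cost_pt_", p)]])),
      mean_qaly = c(mean(draws$qaly_ppt), mean(draws$qaly_pt)),
      sd_qaly = c(stats::sd(draws$qaly_ppt), stats::sd(draws$qaly_pt)),
      stringsAsFactors = FALSE)
  }))

  structure(list(n_iterations = n_iterations, seed = seed, draws = draws,
                 summaries = summaries,
                 wtp_per_qaly = config$model$wtp_per_qaly),
            class = "ppcea_psa_results")
}

#' @export
print.ppcea_psa_results <- function(x, ...) {
  cat(sprintf("PSA: %d iterations (seed %s)\n", x$n_iterations,
              format(x$seed)))
  print(transform(x$summaries,
                  mean_cost = round(mean_cost, 2), sd_cost = round(sd_cost, 2),
                  mean_qaly = round(mean_qaly, 3), sd_qaly = round(sd_qaly, 3)))
  for (p in perspectives())
    cat(sprintf("P(cost-effective at WTP %.0f), %s: %.3f\n",
                x$wtp_per_qaly, p, prob_cost_effective(x, x$wtp_per_qaly, p)))
  invisible(x)
}

psa_nmb <- function(results, wtp, perspective) {
  d <- results$draws
  dq <- d$qaly_ppt - d$qaly_pt
  dc <- d[[paste0("cost_ppt_", perspective)]] -
    d[[paste0("cost_pt_", perspective)]]
  wtp * dq - dc
}

#' Probability that pharmacopuncture is cost-effective
#'
#' Fraction of PSA iterations with positive net monetary benefit at the
#' given willingness-to-pay.
#'
#' @param results A [run_psa()] result.
#' @param wtp Willingness-to-pay, USD per QALY; defaults to the model
#'   threshold.
#' @param perspective Costing perspective.
#' @return A fraction in [0, 1].
#' @export
prob_cost_effective <- function(results, wtp = results$wtp_per_qaly,
                                perspective = c("healthcare",
                                                "restricted_societal",
                                                "full_societal")) {
  stopifnot(inherits(results, "ppcea_psa_results"),
            results$n_iterations >= 1, wtp >= 0)
  perspective <- match.arg(perspective)
  mean(psa_nmb(results, wtp, perspective) > 0)
}

#' Cost-effectiveness acceptability curve
#'
#' [prob_cost_effective()] evaluated over a grid of willingness-to-pay
#' values.
#'
#' @param results A [run_psa()] result.
#' @param wtp_grid Non-negative, non-empty numeric grid of WTP values.
#' @param perspective Costing perspective.
#' @return A data.frame with columns \code{wtp} and
#'   \code{prob_cost_effective}.
#' @export
ceac <- function(results, wtp_grid = seq(0, 60000, by = 500),
                 perspective = c("healthcare", "restricted_societal",
                                 "full_societal")) {
  stopifnot(length(wtp_grid) >= 1, all(wtp_grid >= 0))
  perspective <- match.arg(perspective)
  data.frame(
    wtp = wtp_grid,
    prob_cost_effective = vapply(wtp_grid, function(l)
      prob_cost_effective(results, l, perspective), numeric(1)))
}

#' Write PSA artifacts to CSV
#'
#' Writes the cost-effectiveness-plane points (incremental QALY and cost
#' per iteration), the CEAC table and the summary statistics, as three CSV
#' files sharing a path prefix.
#'
#' @param results A [run_psa()] result.
#' @param prefix Path prefix; files are \code{<prefix>_ce_plane.csv},
#'   \code{<prefix>_ceac.csv}, \code{<prefix>_summary.csv}.
#' @param perspective Costing perspective for the CE plane and CEAC.
#' @param wtp_grid Grid for the CEAC.
#' @return Character vector of the written paths, invisibly.
#' @export
write_psa_csv <- function(results, prefix,
                          perspective = "healthcare",
                          wtp_grid = seq(0, 60000, by = 500)) {
  stopifnot(inherits(results, "ppcea_psa_results"))
  perspective <- match_perspective(perspective)
  d <- results$draws
  plane <- data.frame(
    iteration = seq_len(nrow(d)),
    incremental_qaly = d$qaly_ppt - d$qaly_pt,
    incremental_cost = d[[paste0("cost_ppt_", perspective)]] -
      d[[paste0("cost_pt_", perspective)]])
  paths <- paste0(prefix, c("_ce_plane.csv", "_ceac.csv", "_summary.csv"))
  utils::write.csv(plane, paths[1], row.names = FALSE)
  utils::write.csv(ceac(results, wtp_grid, perspective), paths[2],
                   row.names = FALSE)
  utils::write.csv(results$summaries, paths[3], row.names = FALSE)
  invisible(paths)
}
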