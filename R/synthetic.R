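#' Specification for a synthetic pragmatic trial
#'
#' Describes the data-generating process the analysis assumes: patients
#' enrolled in moderate or severe pain (12:88 by default), randomized to
#' the two arms, assessed at baseline, end of treatment and 3 months, with
#' severity advanced by the arm's true per-interval transition matrix and
#' EQ-5D-5L utilities drawn from a truncated normal around the state mean.
#'
#' @param n_per_arm Patients per arm.
#' @param transition_rows Named list (\code{PPT}, \code{PT}) of 3x3
#'   per-interval transition matrices (state order mild, moderate, severe);
#'   the mild rows must agree across arms (pooled behaviour).
#' @param baseline_distribution Named probability pair over moderate and
#'   severe.
#' @param utility_means Named per-state utility means.
#' @param utility_sd Common patient-level utility standard deviation
#'   (truncated-normal noise).
#' @param productivity_by_state Named per-state productivity loss per
#'   cycle, USD.
#' @param seed RNG seed.
#' @return An object of class \code{ppcea_trial_spec}.
#' @export
trial_spec <- function(n_per_arm,
                       transition_rows,
                       baseline_distribution = c(moderate = 0.12, severe = 0.88),
                       utility_means = c(mild = 0.837, moderate = 0.782, severe = 0.750),
                       utility_sd = 0.1,
                       productivity_by_state = c(mild = 1645.46, moderate = 2585.98,
                                                 severe = 3405.16),
                       seed = 1L) {
  stopifnot(n_per_arm >= 1, utility_sd >= 0)
  bd <- baseline_distribution[c("moderate", "severe")]
  if (any(is.na(bd)) || abs(sum(bd) - 1) > 1e-9)
    stop("`baseline_distribution` must be named (moderate, severe) and sum to 1")
  for (a in arms()) {
    M <- as.matrix(transition_rows[[a]])
    if (is.null(M) || !all(dim(M) == c(3, 3)))
      stop(sprintf("`transition_rows$%s` must be a 3x3 matrix", a))
    if (any(M < 0) || any(abs(rowSums(M) - 1) > 1e-6))
      stop(sprintf("`transition_rows$%s` rows must be probability vectors", a))
    dimnames(M) <- list(health_states(), health_states())
    transition_rows[[a]] <- M
  }
  if (any(abs(transition_rows$PPT[1, ] - transition_rows$PT[1, ]) > 1e-9))
    stop("mild rows must be identical across arms (pooled)")
  um <- utility_means[health_states()]
  if (any(is.na(um)) || any(um < 0 | um > 1))
    stop("`utility_means` must be named state utilities in [0, 1]")
  structure(list(n_per_arm = as.integer(n_per_arm),
                 transition_rows = transition_rows,
                 baseline_distribution = bd,
                 utility_means = um,
                 utility_sd = utility_sd,
                 productivity_by_state = productivity_by_state[health_states()],
                 seed = as.integer(seed)),
            class = "ppcea_trial_spec")
}

timepoints <- function() c("baseline", "end_of_treatment", "month3")

rtruncnorm01 <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  x <- stats::rnorm(n, mean, sd)
  bad <- x < 0 | x > 1
  while (any(bad)) {
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
    bad <- x < 0 | x > 1
  }
  x
}

#' Generate patient-level records from a synthetic trial
#'
#' Baseline severity is drawn from the moderate/severe enrollment split;
#' each follow-up interval advances severity one step through the arm's
#' transition matrix; utilities at each assessment are truncated-normal
#' around the current state's mean. Deterministic for a fixed seed.
#'
#' @param spec A [trial_spec()].
#' @return A data.frame of class \code{ppcea_trial_records}, one row per
#'   patient-timepoint: \code{patient_id}, \code{arm}, \code{timepoint},
#'   \code{severity}, \code{eq5d_utility},
#'   \code{productivity_loss_per_cycle}.
#' @export
simulate_trial <- function(spec) {
  stopifnot(inherits(spec, "ppcea_trial_spec"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(spec$seed)
  states <- health_states()
  tps <- timepoints()

  out <- list()
  for (a in arms()) {
    n <- spec$n_per_arm
    M <- spec$transition_rows[[a]]
    sev <- matrix(NA_integer_, n, 3)
    sev[, 1] <- sample(2:3, n, replace = TRUE,
                       prob = spec$baseline_distribution)
    for (k in 2:3) {
      for (s in 1:3) {
        idx <- which(sev[, k - 1] == s)
        if (length(idx))
          sev[idx, k] <- sample.int(3, length(idx), replace = TRUE,
                                    prob = M[s, ])
      }
    }
    util <- matrix(NA_real_, n, 3)
    for (k in 1:3)
      util[, k] <- rtruncnorm01(n, spec$utility_means[sev[, k]],
                                spec$utility_sd)
    out[[a]] <- data.frame(
      patient_id = rep(sprintf("%s-%04d", a, seq_len(n)), each = 3),
      arm = a,
      timepoint = rep(tps, n),
      severity = states[as.vector(t(sev))],
      eq5d_utility = as.vector(t(util)),
      productivity_loss_per_cycle =
        unname(spec$productivity_by_state[states[as.vector(t(sev))]]),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("ppcea_trial_records", class(res))
  res
}

#' Estimate transition probabilities from patient records
#'
#' Row probabilities are transition counts divided by row totals between
#' the two timepoints; Dirichlet concentrations are the counts themselves
#' plus an optional pseudo-count. A source state with no observed
#' departures yields an unavailable (all-NA) row rather than an invented
#' one -- callers must then supply a pooled row.
#'
#' @param records A [simulate_trial()] data.frame (or equivalent).
#' @param arm Arm to estimate for.
#' @param from_timepoint,to_timepoint Assessment labels bounding the
#'   interval.
#' @param pseudo_count Added to every count when forming concentrations.
#' @return List with \code{rows}, \code{alphas} (3x3 matrices; NA rows
#'   where unobserved) and \code{counts}.
#' @export
estimate_transitions <- function(records, arm,
                                 from_timepoint = "end_of_treatment",
                                 to_timepoint = "month3",
                                 pseudo_count = 0) {
  arm <- match_arm(arm)
  stopifnot(all(c("patient_id", "arm", "timepoint", "severity") %in%
                  names(records)))
  states <- health_states()
  r <- records[records$arm == arm, ]
  a_from <- r[r$timepoint == from_timepoint, c("patient_id", "severity")]
  a_to <- r[r$timepoint == to_timepoint, c("patient_id", "severity")]
  merged <- merge(a_from, a_to, by = "patient_id",
                  suffixes = c("_from", "_to"))
  if (nrow(merged) == 0) stop("no paired observations for the interval")
  counts <- table(factor(merged$severity_from, levels = states),
                  factor(merged$severity_to, levels = states))
  counts <- matrix(as.numeric(counts), 3, 3,
                   dimnames = list(states, states))
  rows <- counts
  alphas <- counts + pseudo_count
  for (s in states) {
    tot <- sum(counts[s, ])
    if (tot == 0) {
      rows[s, ] <- NA_real_
      alphas[s, ] <- NA_real_
    } else {
      rows[s, ] <- counts[s, ] / tot
    }
  }
  list(rows = rows, alphas = alphas, counts = counts)
}

#' Area-under-the-curve QALYs by the trapezoidal rule
#'
#' Integrates a patient's utility trajectory over time and converts weeks
#' to years (52.18 weeks per year, the average-year convention).
#'
#' @param times_weeks Strictly increasing assessment times, weeks.
#' @param utilities Utility at each assessment, in [0, 1].
#' @param weeks_per_year Weeks-to-years conversion (default 52.18).
#' @return QALYs accrued between the first and last assessment.
#' @export
#' @examples
#' auc_qaly(c(0, 52.18), c(0.8, 0.8))  # 0.8 QALY over one year
auc_qaly <- function(times_weeks, utilities, weeks_per_year = 52.18) {
  if (length(times_weeks) < 2)
    stop("at least two assessment timepoints are required")
  stopifnot(length(times_weeks) == length(utilities),
            all(diff(times_weeks) > 0),
            all(utilities >= 0 & utilities <= 1))
  dt <- diff(times_weeks) / weeks_per_year
  sum(dt * (utilities[-length(utilities)] + utilities[-1]) / 2)
}

#' Pooled state utilities with method-of-moments Beta fits
#'
#' Pools utility observations across arms and timepoints per severity
#' state, returning the mean, variance and a method-of-moments Beta fit
#' (\code{alpha = m * (m(1-m)/v - 1)}, \code{beta = (1-m) * (m(1-m)/v - 1)}).
#' Zero-variance states return a fixed value with no Beta fit.
#'
#' @param records A [simulate_trial()] data.frame.
#' @return A data.frame, one row per state: \code{state}, \code{n},
#'   \code{mean}, \code{var}, \code{beta_alpha}, \code{beta_beta}
#'   (NA when the fit is unavailable).
#' @export
estimate_state_utilities <- function(records) {
  stopifnot(all(c("severity", "eq5d_utility") %in% names(records)))
  do.call(rbind, lapply(health_states(), function(s) {
    u <- records$eq5d_utility[records$severity == s]
    if (length(u) < 2)
      stop(sprintf("state '%s' observed fewer than twice", s))
    m <- mean(u)
    v <- stats::var(u)
    if (v == 0 || v >= m * (1 - m)) {
      ab <- c(NA_real_, NA_real_)
    } else {
      k <- m * (1 - m) / v - 1
      ab <- c(m * k, (1 - m) * k)
    }
    data.frame(state = s, n = length(u), mean = m, var = v,
               beta_alpha = ab[1], beta_beta = ab[2],
               stringsAsFactors = FALSE)
  }))
}

#' Write / read trial records as CSV
#'
#' One row per patient-timepoint with the documented header.
#'
#' @param records A [simulate_trial()] data.frame.
#' @param path File path.
#' @return The path (write) or the records data.frame (read).
#' @export
write_trial_csv <- function(records, path) {
  utils::write.csv(as.data.frame(records), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trial_csv
#' @export
read_trial_csv <- function(path) {
  res <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(res) <- c("ppcea_trial_records", class(res))
  res
}
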