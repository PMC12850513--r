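ident3 <- function() {
  m <- diag(3); dimnames(m) <- list(health_states(), health_states()); m
}

test_that("simulate_trial respects enrollment, identity dynamics and the seed", {
  sp <- trial_spec(n_per_arm = 400,
                   transition_rows = list(PPT = ident3(), PT = ident3()),
                   seed = 42)
  rec <- simulate_trial(sp)
  expect_equal(nrow(rec), 2 * 400 * 3)
  base <- rec[rec$timepoint == "baseline", ]
  expect_true(all(base$severity %in% c("moderate", "severe")))
  # identity transitions: severity never changes
  wide <- split(rec$severity, rec$patient_id)
  expect_true(all(vapply(wide, function(s) length(unique(s)) == 1, logical(1))))
  expect_true(all(rec$eq5d_utility >= 0 & rec$eq5d_utility <= 1))
  expect_equal(unique(base$productivity_loss_per_cycle[base$severity == "severe"]),
               3405.16)

  rec2 <- simulate_trial(sp)
  expect_identical(rec, rec2)
  rec3 <- simulate_trial(trial_spec(400, list(PPT = ident3(), PT = ident3()),
                                    seed = 43))
  expect_false(identical(rec$severity, rec3$severity))
})

test_that("estimate_transitions is counts over row totals with count alphas", {
  # hand-built records: 10 moderate departures split 6/3/1
  states <- health_states()
  rec <- data.frame(
    patient_id = rep(sprintf("p%02d", 1:10), 2),
    arm = "PPT",
    timepoint = rep(c("end_of_treatment", "month3"), each = 10),
    severity = c(rep("moderate", 10),
                 rep(states, times = c(6, 3, 1))),
    stringsAsFactors = FALSE)
  est <- estimate_transitions(rec, "PPT")
  expect_equal(unname(est$rows["moderate", ]), c(0.6, 0.3, 0.1))
  expect_equal(unname(est$alphas["moderate", ]), c(6, 3, 1))
  # unobserved source states flagged, not invented
  expect_true(all(is.na(est$rows["mild", ])))
  expect_true(all(is.na(est$rows["severe", ])))
  # pseudo-count shifts alphas only
  est1 <- estimate_transitions(rec, "PPT", pseudo_count = 0.5)
  expect_equal(unname(est1$alphas["moderate", ]), c(6.5, 3.5, 1.5))
  expect_equal(est1$rows, est$rows)
})

test_that("transition probabilities are recovered within 0.02 at n = 10,000", {
  sp <- trial_spec(n_per_arm = 10000,
                   transition_rows = list(PPT = ppt_rows(), PT = pt_rows()),
                   seed = 7)
  rec <- simulate_trial(sp)
  est <- pooled_transition_estimates(rec)
  for (a in arms()) {
    truth <- sp$transition_rows[[a]]
    expect_lt(max(abs(est[[a]][c("moderate", "severe"), ] -
                        truth[c("moderate", "severe"), ])), 0.02)
    # counts-based rows sum to 1 exactly
    expect_equal(unname(rowSums(est[[a]])), rep(1, 3))
  }
  # mild row is pooled across arms (and both arms share the truth)
  expect_equal(est$PPT["mild", ], est$PT["mild", ])
  expect_lt(max(abs(est$PPT["mild", ] - ppt_rows()["mild", ])), 0.02)
})

test_that("auc_qaly implements the trapezoidal rule in years", {
  expect_equal(auc_qaly(c(0, 52.18), c(0.8, 0.8)), 0.8)
  expect_equal(auc_qaly(c(0, 52.18), c(0, 1)), 0.5)
  # 13-week interval between severe and mild utilities
  expect_equal(auc_qaly(c(0, 13), c(0.750, 0.837)),
               (13 / 52.18) * (0.750 + 0.837) / 2)
  # piecewise: sum of segment trapezoids
  expect_equal(auc_qaly(c(0, 6, 13, 25), c(0.75, 0.78, 0.80, 0.84)),
               (6 * (0.75 + 0.78) / 2 + 7 * (0.78 + 0.80) / 2 +
                  12 * (0.80 + 0.84) / 2) / 52.18)
  expect_error(auc_qaly(13, 0.8), "two assessment")
  expect_error(auc_qaly(c(0, 0), c(0.8, 0.9)))
})

test_that("pooled state utilities are recovered with a consistent Beta fit", {
  sp <- trial_spec(n_per_arm = 6000,
                   transition_rows = list(PPT = ppt_rows(), PT = pt_rows()),
                   utility_sd = 0.1, seed = 3)
  rec <- simulate_trial(sp)
  est <- estimate_state_utilities(rec)
  # the estimator recovers the observation mean; with sd = 0.1 the [0, 1]
  # truncation shifts it below the location parameter, so compare against
  # the analytic truncated-normal mean
  trunc_mean <- function(mu, sd) {
    a <- (0 - mu) / sd; b <- (1 - mu) / sd
    mu + sd * (stats::dnorm(a) - stats::dnorm(b)) / (stats::pnorm(b) - stats::pnorm(a))
  }
  expect_equal(est$mean[est$state == "mild"], trunc_mean(0.837, 0.1),
               tolerance = 0.01)
  expect_equal(est$mean[est$state == "severe"], trunc_mean(0.750, 0.1),
               tolerance = 0.01)
  # method-of-moments round trip: the Beta mean returns the input mean
  for (i in seq_len(nrow(est)))
    expect_equal(est$beta_alpha[i] / (est$beta_alpha[i] + est$beta_beta[i]),
                 est$mean[i])

  # zero-variance state: fixed value, no Beta fit
  const <- data.frame(severity = rep(health_states(), each = 3),
                      eq5d_utility = rep(c(0.5, 0.7, 0.9), each = 3))
  est0 <- estimate_state_utilities(const)
  expect_equal(est0$mean, c(0.5, 0.7, 0.9))
  expect_true(all(is.na(est0$beta_alpha)))
})

test_that("end-to-end recovery reproduces base-case dominance", {
  cfg <- paper_config()
  sp <- trial_spec(n_per_arm = 5000,
                   transition_rows = list(PPT = ppt_rows(), PT = pt_rows()),
                   seed = 11)
  rec <- simulate_trial(sp)
  est <- lapply(arms(), function(a) estimate_transitions(rec, a))
  names(est) <- arms()
  # pooled mild row: combined counts across arms
  mild_counts <- est$PPT$counts["mild", ] + est$PT$counts["mild", ]
  mild_row <- mild_counts / sum(mild_counts)
  for (a in arms()) {
    rows <- est[[a]]$rows
    rows["mild", ] <- mild_row
    cfg$transitions[[a]] <- transition_model(rows, arm = a, renormalize = TRUE)
  }
  bc <- run_base_case(cfg)
  expect_identical(bc$results$healthcare$dominance, "ppt_dominant")
  expect_identical(bc$results$full_societal$dominance, "ppt_dominant")
  expect_lt(bc$results$healthcare$icer, 0)
})

test_that("trial records round-trip through CSV", {
  sp <- trial_spec(25, list(PPT = ppt_rows(), PT = pt_rows()), seed = 5)
  rec <- simulate_trial(sp)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trial_csv(rec, path)
  back <- read_trial_csv(path)
  expect_equal(as.data.frame(back), as.data.frame(rec))
})
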