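test_that("Dirichlet draws have the analytic mean and are valid rows", {
  alpha <- c(22.413, 11.299, 3.048)
  set.seed(11)
  draws <- t(replicate(20000, rdirichlet1(alpha)))
  expect_true(all(draws >= 0))
  expect_equal(rowSums(draws), rep(1, 20000), tolerance = 1e-12)
  m <- colMeans(draws)
  expect_equal(m, alpha / sum(alpha), tolerance = 0.01)
  # the concentration means sit close to the published severe-row probabilities
  expect_lt(max(abs(alpha / sum(alpha) - c(0.612, 0.321, 0.067))), 0.02)
})

test_that("published Beta concentrations center on the per-cycle QALY weights", {
  cfg <- paper_config()
  qb <- cfg$utility$qaly_beta
  means <- vapply(qb, function(ab) ab[1] / sum(ab), numeric(1))
  expect_equal(round(unname(means), 3), c(0.209, 0.195, 0.187))
})

test_that("sample_parameters keeps fixed unit costs and valid structure", {
  cfg <- paper_config()
  set.seed(5)
  for (i in 1:20) {
    s <- sample_parameters(cfg)
    # fixed medical unit costs untouched
    expect_identical(s$payoffs$PPT$medical_cost_per_treated_cycle,
                     cfg$payoffs$PPT$medical_cost_per_treated_cycle)
    expect_identical(s$pt_mix$consultation, cfg$pt_mix$consultation)
    # Dirichlet rows valid; mild row pooled across arms
    for (a in arms()) {
      expect_true(all(s$transitions[[a]]$rows >= 0))
      expect_equal(unname(rowSums(s$transitions[[a]]$rows)), rep(1, 3),
                   tolerance = 1e-12)
    }
    expect_equal(s$transitions$PPT$rows["mild", ],
                 s$transitions$PT$rows["mild", ])
    # scenario weights renormalized; PT cost consistent with the draw
    expect_equal(sum(s$pt_mix$weights), 1)
    expect_equal(s$payoffs$PT$medical_cost_per_treated_cycle,
                 pt_cycle_cost(s$pt_mix))
    # QALY weights shared across arms, positive costs
    expect_equal(s$payoffs$PPT$per_cycle_qaly_by_state,
                 s$payoffs$PT$per_cycle_qaly_by_state)
    expect_gt(s$payoffs$PPT$time_cost_per_treated_cycle, 0)
  }
})

test_that("degenerate PSA reproduces the deterministic base case", {
  cfg <- degenerate_config()
  bc <- run_base_case(cfg)
  res <- run_psa(cfg, n_iterations = 3, seed = 123)
  expect_equal(mean(res$draws$cost_ppt_healthcare),
               bc$results$healthcare$total_cost[["PPT"]], tolerance = 1e-4)
  expect_equal(mean(res$draws$cost_pt_full_societal),
               bc$results$full_societal$total_cost[["PT"]], tolerance = 1e-4)
  expect_equal(mean(res$draws$qaly_ppt),
               bc$results$healthcare$total_qaly[["PPT"]], tolerance = 1e-4)
  # dominant base case -> CEAC identically 1
  curve <- ceac(res, c(0, 10000, 26647), "healthcare")
  expect_equal(curve$prob_cost_effective, rep(1, 3))
})

test_that("PSA is reproducible for a fixed seed", {
  cfg <- paper_config()
  a <- run_psa(cfg, n_iterations = 25, seed = 77)
  b <- run_psa(cfg, n_iterations = 25, seed = 77)
  expect_identical(a$draws, b$draws)
  expect_identical(a$summaries, b$summaries)
  c_ <- run_psa(cfg, n_iterations = 25, seed = 78)
  expect_false(identical(a$draws, c_$draws))
})

test_that("prob_cost_effective and ceac obey their definitions", {
  cfg <- paper_config()
  res <- run_psa(cfg, n_iterations = 200, seed = 13)

  p <- prob_cost_effective(res)
  expect_gte(p, 0); expect_lte(p, 1)
  # wtp = 0: fraction of iterations where PPT is cost-saving
  expect_equal(prob_cost_effective(res, 0, "healthcare"),
               mean(res$draws$cost_ppt_healthcare < res$draws$cost_pt_healthcare))

  grid <- seq(0, 60000, by = 2000)
  curve <- ceac(res, grid, "healthcare")
  expect_equal(curve$prob_cost_effective[grid == res$wtp_per_qaly %/% 2000 * 2000],
               prob_cost_effective(res, res$wtp_per_qaly %/% 2000 * 2000))
  expect_true(all(curve$prob_cost_effective >= 0 &
                    curve$prob_cost_effective <= 1))

  # brute-force recount at every grid point
  d <- res$draws
  dq <- d$qaly_ppt - d$qaly_pt
  dc <- d$cost_ppt_healthcare - d$cost_pt_healthcare
  brute <- vapply(grid, function(l) mean(l * dq - dc > 0), numeric(1))
  expect_equal(curve$prob_cost_effective, brute)

  # CEAC non-decreasing whenever every iteration gains QALYs
  if (all(dq > 0)) expect_true(all(diff(curve$prob_cost_effective) >= 0))

  # single-point grid
  expect_equal(ceac(res, res$wtp_per_qaly)$prob_cost_effective, p)
})

test_that("PSA means are stable when doubling the iteration count", {
  cfg <- paper_config()
  r1 <- run_psa(cfg, n_iterations = 400, seed = 91)
  r2 <- run_psa(cfg, n_iterations = 800, seed = 91)
  for (col in c("cost_ppt_healthcare", "cost_pt_healthcare")) {
    se <- stats::sd(r1$draws[[col]]) / sqrt(400)
    expect_lt(abs(mean(r1$draws[[col]]) - mean(r2$draws[[col]])), 4 * se)
  }
})

test_that("n = 1 PSA with collapsed distributions equals the base case", {
  cfg <- degenerate_config()
  res <- run_psa(cfg, n_iterations = 1, seed = 2)
  bc <- run_base_case(cfg)
  expect_equal(res$draws$cost_ppt_healthcare,
               bc$results$healthcare$total_cost[["PPT"]], tolerance = 1e-4)
})
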