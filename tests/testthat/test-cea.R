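test_that("pt_cycle_cost is consultation plus the weighted scenario mix", {
  costs <- c(43.83, 47.23, 61.40, 64.80)
  mix <- pt_scenario_mix(costs, c(0.25, 0.61, 0.08, 0.06), 107.53)
  expect_equal(pt_cycle_cost(mix), 156.0978)

  solo <- pt_scenario_mix(costs, c(1, 0, 0, 0), 107.53)
  expect_equal(pt_cycle_cost(solo), 151.36)

  free <- pt_scenario_mix(rep(0, 4), c(0.25, 0.61, 0.08, 0.06), 107.53)
  expect_equal(pt_cycle_cost(free), 107.53)

  expect_error(pt_scenario_mix(costs, c(0.5, 0.2, 0.1, 0.1), 107.53),
               "sum to")
})

make_trace <- function(occ, arm = "PPT") {
  structure(list(arm = arm, occupancy = occ, collapsed_occupancy = occ,
                 states = health_states(), collapse = health_states(),
                 mild_handling_mode = "direct"),
            class = "ppcea_cohort_trace")
}

test_that("accrue applies the perspective definitions to the treated mass", {
  cfg <- paper_config()
  po <- cfg$payoffs$PPT
  occ_mild <- matrix(rep(c(1, 0, 0), each = 13), 13,
                     dimnames = list(0:12, health_states()))

  # nobody treated -> zero healthcare cost, full mild QALYs
  sp0 <- model_spec(annual_discount_rate = 0, cycle_correction = "none")
  acc <- accrue(make_trace(occ_mild), po, sp0, "healthcare")
  expect_equal(acc$total_cost, 0)
  expect_equal(acc$total_qaly, 12 * 0.837 * 0.25)  # 2.5110

  # productivity counts mild occupancy only under the full perspective
  acc_fs <- accrue(make_trace(occ_mild), po, sp0, "full_societal")
  expect_equal(acc_fs$total_cost, 12 * 1645.46)

  # arms must match
  expect_error(accrue(make_trace(occ_mild, arm = "PT"), po, sp0), "arm")
})

test_that("discounted totals never exceed undiscounted totals", {
  cfg <- paper_config()
  sp_disc <- cfg$model
  sp_flat <- model_spec(annual_discount_rate = 0,
                        mild_handling_mode = sp_disc$mild_handling_mode,
                        cycle_correction = sp_disc$cycle_correction)
  for (a in arms()) {
    tr <- run_cohort(sp_disc, cfg$transitions[[a]])
    for (p in c("healthcare", "restricted_societal", "full_societal")) {
      d <- accrue(tr, cfg$payoffs[[a]], sp_disc, p)
      u <- accrue(tr, cfg$payoffs[[a]], sp_flat, p)
      expect_lt(d$total_cost, u$total_cost)
      expect_lt(d$total_qaly, u$total_qaly)
    }
  }
})

test_that("compute_icer classifies dominance and reports negative ICERs", {
  r <- compute_icer(1304.33, 1384.52, 2.30, 2.23)
  expect_equal(r$incremental_cost, -80.19)
  expect_equal(r$incremental_qaly, 0.07)
  expect_equal(r$icer, -80.19 / 0.07)      # -1145.571...
  expect_equal(round(r$icer, 2), -1145.57) # as printed
  expect_identical(r$dominance, "ppt_dominant")

  r2 <- compute_icer(100, 100, 2.1, 2.0)
  expect_equal(r2$icer, 0)
  expect_identical(r2$dominance, "tradeoff")

  r3 <- compute_icer(1100, 1000, 2.05, 2.00)
  expect_equal(r3$icer, 2000)
  expect_identical(r3$dominance, "tradeoff")

  # zero incremental QALY: ICER undefined, dominance by cost sign
  r4 <- compute_icer(900, 1000, 2, 2)
  expect_true(is.na(r4$icer))
  expect_identical(r4$dominance, "ppt_dominant")
})

test_that("compute_nmb matches the definition", {
  expect_equal(compute_nmb(-80.19, 0.07, 26647), 26647 * 0.07 + 80.19)
  expect_equal(compute_nmb(0, 0, 30000), 0)
  expect_equal(compute_nmb(26647, 1, 26647), 0)
})

test_that("ppt dominance implies positive NMB at any positive WTP", {
  set.seed(7)
  for (i in 1:50) {
    dc <- stats::rnorm(1, 0, 500); dq <- stats::rnorm(1, 0, 0.2)
    r <- compute_icer(1000 + dc, 1000, 2 + dq, 2)
    if (r$dominance == "ppt_dominant")
      expect_gt(compute_nmb(r$incremental_cost, r$incremental_qaly,
                            stats::runif(1, 1, 1e5)), 0)
  }
})

test_that("base case satisfies nesting and QALY-bound invariants", {
  cfg <- paper_config()
  bc <- run_base_case(cfg)
  for (a in arms()) {
    hc <- bc$results$healthcare$total_cost[[a]]
    rs <- bc$results$restricted_societal$total_cost[[a]]
    fs <- bc$results$full_societal$total_cost[[a]]
    expect_lte(hc, rs)
    expect_lte(rs, fs)
    expect_lte(bc$results$healthcare$total_qaly[[a]],
               12 * 0.25 * max(cfg$utility$by_state))
  }
  expect_identical(bc$conventions$mild_handling_mode, "direct")
})

test_that("zero-cost configuration yields a zero ICER decided by QALYs", {
  cfg <- paper_config()
  for (a in arms()) {
    cfg$payoffs[[a]]$medical_cost_per_treated_cycle <- 0
    cfg$payoffs[[a]]$transport_cost_per_treated_cycle <- 0
    cfg$payoffs[[a]]$time_cost_per_treated_cycle <- 0
    cfg$payoffs[[a]]$productivity_loss_per_cycle_by_state[] <- 0
  }
  bc <- run_base_case(cfg)
  r <- bc$results$healthcare
  expect_equal(r$incremental_cost, 0)
  expect_gt(r$incremental_qaly, 0)
  expect_equal(r$icer, 0)
})

test_that("calibrate_conventions recovers a known tuple and rejects empty targets", {
  cfg <- paper_config()
  tuple <- list(mild_handling_mode = "tunnel", cycle_correction = "none",
                discount_timing = "cycle_end")
  bc <- run_base_case(cfg, conventions = tuple)
  targets <- c(cost_PPT_healthcare = bc$results$healthcare$total_cost[["PPT"]],
               cost_PT_healthcare = bc$results$healthcare$total_cost[["PT"]],
               qaly_PPT_healthcare = bc$results$healthcare$total_qaly[["PPT"]],
               cost_PT_full_societal = bc$results$full_societal$total_cost[["PT"]])
  cal <- calibrate_conventions(cfg, targets)
  expect_equal(cal$best, tuple)
  expect_equal(cal$score, 0, tolerance = 1e-12)
  expect_equal(nrow(cal$residuals), 12)

  expect_error(calibrate_conventions(cfg, numeric(0)), "non-empty")
})
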