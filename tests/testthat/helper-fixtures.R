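# Shared fixtures: the packaged configuration (the published model inputs)
# and small generators used by property-style tests.

paper_config <- function() default_config()

ppt_rows <- function() rbind(mild = c(0.731, 0.268, 0.001),
                             moderate = c(0.472, 0.334, 0.194),
                             severe = c(0.612, 0.321, 0.067))

pt_rows <- function() rbind(mild = c(0.731, 0.268, 0.001),
                            moderate = c(0.052, 0.765, 0.183),
                            severe = c(0.209, 0.569, 0.222))

random_stochastic_rows <- function(n = 3) {
  m <- matrix(stats::rexp(n * n), n)
  m <- m / rowSums(m)
  dimnames(m) <- list(health_states()[1:n], health_states()[1:n])
  m
}

# Independent Monte-Carlo oracle for the cohort engine: advances a finite
# cohort through the chain by multinomial draws (each patient moves
# independently) and returns occupancy fractions per cycle.
microsim_occupancy <- function(M, init_counts, n_cycles) {
  n <- sum(init_counts)
  counts <- init_counts
  occ <- matrix(0, n_cycles + 1, length(counts))
  occ[1, ] <- counts / n
  for (t in seq_len(n_cycles)) {
    new_counts <- numeric(length(counts))
    for (s in seq_along(counts)) {
      if (counts[s] > 0)
        new_counts <- new_counts +
          stats::rmultinom(1, counts[s], M[s, ])[, 1]
    }
    counts <- new_counts
    occ[t + 1, ] <- counts / n
  }
  occ
}

# Pooled transition estimates from synthetic-trial records: counts are
# summed over both observed intervals (the same matrix generates both) and
# the mild row over both arms (the analysis pools it). Returns per-arm 3x3
# probability matrices.
pooled_transition_estimates <- function(records) {
  counts <- lapply(arms(), function(a) {
    estimate_transitions(records, a, "baseline", "end_of_treatment")$counts +
      estimate_transitions(records, a, "end_of_treatment", "month3")$counts
  })
  names(counts) <- arms()
  mild <- counts$PPT["mild", ] + counts$PT["mild", ]
  lapply(counts, function(ct) {
    ct["mild", ] <- mild
    ct / rowSums(ct)
  })
}

# Near-degenerate configuration: every PSA distribution collapsed onto the
# base-case value (huge concentrations / vanishing SEs), so PSA draws
# reproduce the deterministic base case.
degenerate_config <- function() {
  cfg <- paper_config()
  K <- 1e12
  for (a in arms())
    cfg$transitions[[a]]$dirichlet_alpha <- cfg$transitions[[a]]$rows * K + 1e-6
  q <- cfg$payoffs$PPT$per_cycle_qaly_by_state
  cfg$utility$qaly_beta <- lapply(health_states(), function(s)
    c(q[[s]] * K, (1 - q[[s]]) * K))
  names(cfg$utility$qaly_beta) <- health_states()
  for (a in arms()) cfg$costs[[a]]$time_se <- 1e-9
  cfg$productivity$se[] <- 1e-9
  cfg$psa$transport_se_fraction <- 1e-12
  wb <- cfg$pt_mix$weights * K
  cfg$pt_mix$beta_params <- cbind(wb, K - wb)
  cfg
}
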