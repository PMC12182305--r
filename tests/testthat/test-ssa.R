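# stochastic oracle: exact conservation, reproducibility, mean-field limit

ssa_mass <- function(counts) {
  N <- ncol(counts) - 2L
  as.numeric(counts[, 1] + counts[, -(1:2), drop = FALSE] %*% seq_len(N))
}

test_that("runs are reproducible and conserve integer cell mass exactly", {
  p <- kinetic_params(kp1 = 1, kn1 = 0.1,
                      kernel = kernel_spec("constant", 0.3, 0.05),
                      N = 6, S0 = 1)
  cfg <- stochastic_config(p, volume = 500,
                           initial_counts = list(C = 200, S = 500,
                                                 A = c(300, rep(0, 5))),
                           times = seq(0, 10, by = 1), seed = 17, n_runs = 4)
  r1 <- ssa_run(cfg, 1)
  expect_identical(r1$counts, ssa_run(cfg, 1)$counts)
  expect_false(identical(r1$counts, ssa_run(cfg, 2)$counts))

  for (ri in 1:4) {
    m <- ssa_mass(ssa_run(cfg, ri)$counts)
    expect_true(all(m == m[1]))
  }

  # no reachable channel may ever produce an aggregate beyond N
  big <- ssa_run(cfg, 3)$counts
  expect_identical(ncol(big), p$N + 2L)
})

test_that("a configuration with no possible events stays constant", {
  p <- const_params(kp = 2, N = 4)
  cfg <- stochastic_config(p, volume = 100,
                           initial_counts = list(C = 50, S = 0,
                                                 A = rep(0, 4)),
                           times = 0:5, seed = 3)
  r <- ssa_run(cfg)
  expect_true(all(r$counts[, "C"] == 50))
  expect_true(all(r$counts[, -(1:2)] == 0))
})

test_that("ensembles summarize runs and honor the seed contract", {
  p <- const_params(kp = 0.5, N = 4)
  cfg1 <- stochastic_config(p, volume = 200,
                            initial_counts = list(C = 0, S = 200,
                                                  A = c(200, rep(0, 3))),
                            times = 0:5, seed = 9, n_runs = 1)
  e1 <- ssa_ensemble(cfg1)
  expect_equal(e1$mean_state, ssa_run(cfg1, 1)$counts + 0,
               ignore_attr = TRUE)
  expect_true(all(e1$se_state == 0))

  cfg <- stochastic_config(p, volume = 200,
                           initial_counts = list(C = 0, S = 200,
                                                 A = c(200, rep(0, 3))),
                           times = 0:5, seed = 9, n_runs = 20)
  e <- ssa_ensemble(cfg)
  expect_identical(ssa_ensemble(cfg)[c("mean_state", "se_state")],
                   e[c("mean_state", "se_state")])
  expect_true(all(e$se_state >= 0))
})

test_that("ensemble means converge to the ODE solution as volume grows", {
  p <- kinetic_params(kp1 = 1, kn1 = 0,
                      kernel = kernel_spec("constant", 0.4, 0.02),
                      N = 4, S0 = 1)
  tms <- seq(0, 6, by = 1)
  tr <- integrate_kinetics(p, system_state(0, 1, c(1, 0, 0, 0)), tms)
  ode <- suspended_fraction(tr, 2)$suspended_fraction

  err <- sapply(c(100, 1000, 10000), function(om) {
    cfg <- stochastic_config(p, volume = om,
                             initial_counts = list(C = 0, S = om,
                                                   A = c(om, rep(0, 3))),
                             times = tms, seed = 21, n_runs = 150)
    d <- ode_ssa_discrepancy(ssa_ensemble(cfg), tr, 2)
    max(abs(d$mean_susp - ode))
  })
  expect_lt(err[3], err[1])
  expect_lte(err[2], err[1])
})

test_that("discrepancy z-scores flag only genuine mean-field mismatches", {
  p <- const_params(kp = 2, N = 4)
  # event-free configuration: SSA equals the (constant) ODE, all z = 0
  cfg0 <- stochastic_config(p, volume = 100,
                            initial_counts = list(C = 60, S = 0,
                                                  A = rep(0, 4)),
                            times = 0:4, seed = 1, n_runs = 5)
  tr0 <- integrate_kinetics(p, quiescent_state(0.6, 4), 0:4)
  d0 <- ode_ssa_discrepancy(ssa_ensemble(cfg0), tr0, 2)
  expect_identical(d0$z, rep(0, 5))
  expect_false(d0$mismatch)

  # negative control: doubling kp in the ODE only must be detected
  p2 <- const_params(kp = 0.8, N = 4)
  tms <- seq(0, 5, by = 1)
  cfg <- stochastic_config(p2, volume = 2000,
                           initial_counts = list(C = 0, S = 2000,
                                                 A = c(2000, rep(0, 3))),
                           times = tms, seed = 8, n_runs = 100)
  ens <- ssa_ensemble(cfg)
  tr_ok <- integrate_kinetics(p2, system_state(0, 1, c(1, 0, 0, 0)), tms)
  expect_false(ode_ssa_discrepancy(ens, tr_ok, 2)$mismatch)
  p2x <- const_params(kp = 1.6, N = 4)
  tr_2x <- integrate_kinetics(p2x, system_state(0, 1, c(1, 0, 0, 0)), tms)
  expect_true(ode_ssa_discrepancy(ens, tr_2x, 2)$mismatch)

  # mismatched grids are a contract error, big requests a cost warning
  tr_short <- integrate_kinetics(p2, system_state(0, 1, c(1, 0, 0, 0)), 0:3)
  expect_error(ode_ssa_discrepancy(ens, tr_short, 2), "grids differ")
  expect_warning(
    stochastic_config(const_params(N = 18), volume = 10,
                      initial_counts = list(C = 5, S = 5, A = rep(0, 18)),
                      times = 0:1, seed = 1),
    "N <= 16")
})
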