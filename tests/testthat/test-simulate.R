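# integration, observable mapping, density sweep

test_that("a flux-free configuration stays exactly at its initial state", {
  p <- const_params(kp = 5, N = 6)
  tr <- integrate_kinetics(p, quiescent_state(0.4, 6), seq(0, 30, by = 5))
  expect_equal(tr$C, rep(0.4, 7))
  expect_true(all(tr$A == 0))
  for (t in c(0, 7.5, 30)) {
    expect_equal(settled_percentage_at(tr, t), 0)
  }
})

test_that("pure dimerization matches the closed-form solution", {
  a0 <- 0.5; kp <- 1.3
  p <- const_params(kp = kp, N = 2)
  tms <- seq(0, 20, by = 0.25)
  tr <- integrate_kinetics(p, system_state(0, 0, c(a0, 0)), tms)
  exact <- a0 / (1 + 2 * kp * a0 * tms)
  expect_lt(max(abs(tr$A[, 1] - exact)), 1e-6)
  expect_lt(max(abs(tr$A[, 2] - (a0 - tr$A[, 1]) / 2)), 1e-6)
})

test_that("trajectories conserve mass for every kernel family and S mode", {
  set.seed(33)
  for (fam in c("constant", "brownian", "product")) {
    p <- kinetic_params(kp1 = 1, kn1 = 0.05,
                        kernel = kernel_spec(fam, 20, 0.02), N = 20, S0 = 1)
    for (sm in c("constant", "dynamic")) {
      tr <- integrate_kinetics(p, system_state(0.01, 1, rep(0, 20)),
                               seq(0, 60, by = 5), s_mode = sm)
      expect_lt(tr$solver_meta$mass_drift, 1e-8)
      expect_true(all(tr$A >= 0))
    }
  }
})

test_that("suspended fraction implements the threshold mass ratio", {
  # stationary state C=0.5, A1=0.25, A2=0.125 (mass 1), threshold 2 -> 0.75
  p <- const_params(kp = 1, N = 4)
  st <- system_state(C = 0.5, S = 0, A = c(0.25, 0.125, 0, 0))
  # freeze the state by removing all flux (S=0 kills silicification; set
  # kernel scales tiny enough to be irrelevant over a zero-length window)
  tr <- structure(list(times = c(0, 1),
                       C = c(0.5, 0.5), S = c(0, 0),
                       A = rbind(st$A, st$A), params = p,
                       solver_meta = list(rtol = 0, atol = 0,
                                          s_mode = "constant",
                                          n_steps = 0, mass_drift = 0)),
                  class = "kinetic_trajectory")
  obs <- suspended_fraction(tr, settle_threshold = 2)
  expect_equal(obs$suspended_fraction, c(0.75, 0.75))
  # threshold 3 keeps dimers in suspension: C + A1 + 2*A2 is the whole mass
  expect_equal(suspended_fraction(tr, 3)$suspended_fraction[1], 1.0)

  # all mass in C -> 1; all mass at the terminal size -> 0
  trC <- integrate_kinetics(p, quiescent_state(1, 4), c(0, 1))
  expect_equal(suspended_fraction(trC, 2)$suspended_fraction, c(1, 1))
  trN <- structure(list(times = c(0, 1), C = c(0, 0), S = c(0, 0),
                        A = rbind(c(0, 0, 0, 0.25), c(0, 0, 0, 0.25)),
                        params = p,
                        solver_meta = list(rtol = 0, atol = 0,
                                           s_mode = "constant",
                                           n_steps = 0, mass_drift = 0)),
                   class = "kinetic_trajectory")
  expect_equal(suspended_fraction(trN, 2)$suspended_fraction, c(0, 0))
  expect_error(suspended_fraction(trN, 5), "exceeds N")
})

test_that("settled percentage interpolates linearly and is exact on the grid", {
  p <- default_params()
  tr <- integrate_kinetics(p, system_state(0.008, 1, rep(0, 50)),
                           seq(0, 30, by = 5))
  obs <- suspended_fraction(tr, 2)
  for (i in c(1, 3, 7)) {
    expect_identical(settled_percentage_at(tr, tr$times[i], 2),
                     100 * (1 - obs$suspended_fraction[i]))
  }
  mid <- settled_percentage_at(tr, 7.5, 2)
  expect_equal(mid, mean(100 * (1 - obs$suspended_fraction[2:3])))
  expect_equal(settled_percentage_at(tr, 0, 2), 0)
  expect_error(settled_percentage_at(tr, 31, 2), "within")
})

test_that("suspension decays monotonically when fragmentation is off", {
  p <- const_params(kp = 40, kn = 0, N = 20)
  tr <- integrate_kinetics(p, system_state(0.01, 1, rep(0, 20)),
                           seq(0, 90, by = 5))
  s <- suspended_fraction(tr, 2)$suspended_fraction
  expect_true(all(diff(s) <= 1e-12))
  expect_true(all(s >= 0 & s <= 1))
})

test_that("density sweep is ordered by density and consistent with integrate", {
  p <- default_params()
  densities <- c(0.002, 0.004, 0.008, 0.012, 0.016)
  tms <- seq(0, 90, by = 5)
  sw <- density_sweep(p, densities, tms)
  expect_length(sw, 5)
  susp <- sapply(sw, function(s) s$suspended_fraction)
  # at every t > 0 the suspended fraction strictly decreases with density
  expect_true(all(apply(susp[-1, ], 1, function(r) all(diff(r) < 0))))

  single <- density_sweep(p, 0.008, tms)[[1]]
  tr <- integrate_kinetics(p, system_state(0.008, p$S0, rep(0, 50)), tms)
  expect_equal(single$suspended_fraction,
               suspended_fraction(tr, 2)$suspended_fraction)

  # doubling the density settles faster everywhere (constant kernel)
  twice <- density_sweep(p, 0.016, tms)[[1]]
  expect_true(all(twice$suspended_fraction[-1] <
                  single$suspended_fraction[-1]))

  # pre-silicified mode starts from A1 and is recorded
  sw2 <- density_sweep(p, 0.008, tms, initial_mode = "silicified")
  expect_identical(attr(sw2, "initial_mode"), "silicified")
  expect_lte(sw2[[1]]$suspended_fraction[2], single$suspended_fraction[2])
})

test_that("halving solver tolerances leaves the observable unchanged to 1e-6", {
  p <- default_params()
  tms <- seq(0, 90, by = 5)
  init <- system_state(0.016, 1, rep(0, 50))
  s1 <- suspended_fraction(integrate_kinetics(p, init, tms), 2)
  s2 <- suspended_fraction(
    integrate_kinetics(p, init, tms, rtol = 5e-9, atol = 5e-13), 2)
  expect_lt(max(abs(s1$suspended_fraction - s2$suspended_fraction)), 1e-6)
})

test_that("invalid integration requests fail loudly", {
  p <- const_params(N = 4)
  init <- system_state(1, 1, rep(0, 4))
  expect_error(integrate_kinetics(p, init, c(1, 2)), "from 0")
  expect_error(integrate_kinetics(p, init, c(0, 0, 1)), "increasing")
  expect_error(integrate_kinetics(p, system_state(1, 1, rep(0, 6)),
                                  c(0, 1)), "aggregate sizes")
})
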