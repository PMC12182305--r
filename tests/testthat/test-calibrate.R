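# calibration: residuals, least-squares fitting, parameter recovery

test_that("residuals vanish on self-generated noiseless data", {
  p <- default_params(); m <- default_mapping()
  ds <- generate_settlement_curves(p, m, densities = 2.8 * c(1, 2),
                                   t_end = 45, noise = noise_model("none"))
  r <- residuals_settlement(p, m, ds)
  expect_length(r, nrow(ds))
  expect_lt(max(abs(r)), 1e-8)
})

test_that("residual scatter tracks the generating noise level", {
  p <- default_params(); m <- default_mapping()
  nm <- noise_model("multiplicative_gaussian", cv = 0.03, seed = 31)
  ds <- generate_settlement_curves(p, m, densities = 2.8 * c(1, 2, 4),
                                   replicates = 10, noise = nm)
  r <- residuals_settlement(p, m, ds)
  d <- ds[order(ds$initial_od, ds$density_label, ds$replicate, ds$time_min), ]
  d$norm <- stats::ave(d$od600, d$density_label, d$replicate,
                       FUN = function(x) x / x[1])
  model <- d$norm - r
  late <- d$time_min > 0
  # reading noise and time-zero normalization noise both contribute ~cv
  expected <- sqrt(mean(2 * (model[late] * 0.03)^2))
  expect_lt(abs(sd(r[late]) - expected) / expected, 0.35)
})

test_that("model-data mismatch has the expected sign at early times", {
  p <- default_params(); m <- default_mapping()
  ds <- generate_settlement_curves(p, m, densities = 2.8,
                                   noise = noise_model("none"))
  fast <- p
  fast$kernel$kp_scale <- 2 * p$kernel$kp_scale
  r <- residuals_settlement(fast, m, ds)
  early <- sort(unique(ds$time_min))[2:4]
  expect_gt(mean(r[ds$time_min %in% early]), 0)
})

test_that("fitting noiseless data returns the generating parameters", {
  p <- default_params(); m <- default_mapping()
  ds <- generate_settlement_curves(p, m, densities = 2.8 * c(1, 2, 4),
                                   noise = noise_model("none"))
  prob <- calibration_problem(ds, c("kp_scale", "kn_scale"),
                              list(kp_scale = c(0.5, 5000),
                                   kn_scale = c(2e-4, 2)),
                              fixed_params = p, fixed_mapping = m)
  fit <- fit_settlement(prob, n_starts = 3, seed = 42)
  expect_lt(fit$loss_value, 1e-10)
  expect_lt(abs(fit$estimates[["kp_scale"]] / p$kernel$kp_scale - 1), 1e-4)
  expect_lt(abs(fit$estimates[["kn_scale"]] / p$kernel$kn_scale - 1), 1e-4)
  expect_true(fit$converged)

  # determinism: same problem and seed give the identical result
  fit2 <- fit_settlement(prob, n_starts = 3, seed = 42)
  expect_identical(fit$estimates, fit2$estimates)
  expect_identical(fit$loss_value, fit2$loss_value)
  expect_identical(fit$residuals, fit2$residuals)
})

test_that("settle_threshold can be recovered over its integer grid", {
  p <- default_params()
  m3 <- list(od_per_unit = 350, settle_threshold = 3L)
  ds <- generate_settlement_curves(p, m3, densities = 2.8 * c(1, 4),
                                   t_end = 45, noise = noise_model("none"))
  prob <- calibration_problem(ds, c("kp_scale", "settle_threshold"),
                              list(kp_scale = c(0.5, 5000),
                                   settle_threshold = 2:4),
                              fixed_params = p, fixed_mapping = m3)
  fit <- fit_settlement(prob, n_starts = 2, seed = 7)
  expect_identical(as.integer(fit$estimates[["settle_threshold"]]), 3L)
})

test_that("od_per_unit is unidentifiable along an exact scaling ridge", {
  # the normalized observable depends on od_per_unit only through the
  # products kp_scale * density, so jointly rescaling kp_scale and
  # od_per_unit leaves every residual unchanged — no density design can
  # separate them
  p <- default_params(); m <- default_mapping()
  nm <- noise_model("multiplicative_gaussian", cv = 0.03, seed = 5)
  ds <- generate_settlement_curves(p, m, noise = nm)
  r0 <- residuals_settlement(p, m, ds)
  for (c_scale in c(0.5, 3)) {
    p2 <- p; p2$kernel$kp_scale <- c_scale * p$kernel$kp_scale
    m2 <- m; m2$od_per_unit <- c_scale * m$od_per_unit
    expect_lt(max(abs(residuals_settlement(p2, m2, ds) - r0)), 1e-7)
  }
})

test_that("noiseless recovery is exact and richer designs recover better", {
  p <- default_params()
  rec0 <- parameter_recovery(p, design = list(cv = 0, n_starts = 2,
                                              densities = 2.8 * c(1, 4),
                                              t_end = 45),
                             n_repeats = 1, seed = 2)
  expect_lt(max(rec0$rel_rmse), 1e-4)
  expect_equal(rec0$converged_fraction, 1)

  # a single short curve is strictly less informative than the
  # five-density full design (same seeds, same noise level)
  rec_full <- parameter_recovery(
    p, design = list(cv = 0.03, n_starts = 2,
                     densities = 350 * c(0.002, 0.004, 0.008, 0.012, 0.016)),
    n_repeats = 3, seed = 3)
  rec_poor <- parameter_recovery(
    p, design = list(cv = 0.03, n_starts = 2, densities = 2.8,
                     t_end = 15, dt = 5),
    n_repeats = 3, seed = 3)
  expect_gt(rec_poor$rel_rmse[["kp_scale"]], rec_full$rel_rmse[["kp_scale"]])
  expect_gt(rec_poor$rel_rmse[["kn_scale"]], rec_full$rel_rmse[["kn_scale"]])
})

test_that("problem construction rejects malformed requests", {
  p <- default_params()
  ds <- generate_settlement_curves(p, densities = 2.8, t_end = 15,
                                   noise = noise_model("none"))
  expect_error(calibration_problem(ds, character(), list(),
                                   fixed_params = p), "nonempty")
  expect_error(calibration_problem(ds, "kp_scale",
                                   list(kp_scale = c(-1, 10)),
                                   fixed_params = p), "positive")
  expect_error(calibration_problem(ds, "volume", list(volume = c(1, 2)),
                                   fixed_params = p), "subset")
  prob <- calibration_problem(ds, "kp_scale", list(kp_scale = c(1, 100)),
                              fixed_params = p)
  expect_error(residuals_settlement(p, list(od_per_unit = -1,
                                            settle_threshold = 2), ds),
               "positive")
})
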