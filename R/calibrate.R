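#' Residuals of the kinetic model against a settlement dataset
#'
#' For every reading, the residual is
#' `observed normalized OD - model suspended fraction`, where the observed
#' value is normalized to that curve's own time-zero reading and the model
#' curve is simulated from the initial density `initial_od / od_per_unit`.
#' Residual order is deterministic: curve-major (by initial density, label,
#' then replicate), time-minor.
#'
#' @param params a [kinetic_params()].
#' @param mapping list with `od_per_unit > 0` and `settle_threshold`.
#' @param dataset a [settlement_dataset()].
#' @param s_mode,initial_mode simulation modes; see [density_sweep()].
#' @return numeric residual vector.
#' @export
residuals_settlement <- function(params, mapping, dataset,
                                 s_mode = "constant",
                                 initial_mode = "unsilicified") {
  params <- validate_params(params)
  stopifnot(inherits(dataset, "settlement_dataset"))
  if (!nrow(dataset)) stop("dataset is empty", call. = FALSE)
  if (!is.numeric(mapping$od_per_unit) || mapping$od_per_unit <= 0) {
    stop("mapping$od_per_unit must be positive", call. = FALSE)
  }

  ord <- order(dataset$initial_od, dataset$density_label,
               dataset$replicate, dataset$time_min)
  d <- dataset[ord, ]

  res <- numeric(nrow(d))
  cache <- new.env(parent = emptyenv())
  pos <- 1L
  # iterate curves explicitly (split() would reorder groups alphabetically,
  # breaking the curve-major order defined above)
  key <- paste(d$density_label, d$replicate, sep = "\r")
  for (k in unique(key)) {
    cur <- d[key == k, ]
    ckey <- format(cur$initial_od[1], digits = 15)
    model <- get0(ckey, envir = cache)
    if (is.null(model)) {
      tms <- sort(unique(c(0, d$time_min[d$initial_od == cur$initial_od[1]])))
      series <- density_sweep(params, cur$initial_od[1] / mapping$od_per_unit,
                              tms, settle_threshold = mapping$settle_threshold,
                              initial_mode = initial_mode, s_mode = s_mode)[[1]]
      model <- setNames(series$suspended_fraction, format(tms, digits = 15))
      assign(ckey, model, envir = cache)
    }
    obs_norm <- cur$od600 / cur$od600[1]
    pred <- unname(model[format(cur$time_min, digits = 15)])
    res[pos:(pos + nrow(cur) - 1L)] <- obs_norm - pred
    pos <- pos + nrow(cur)
  }
  res
}

#' Define a calibration problem
#'
#' @param dataset a [settlement_dataset()].
#' @param free_params character vector of parameters to fit, among
#'   `"kp_scale"`, `"kn_scale"`, `"kp1"`, `"kn1"`, `"od_per_unit"`,
#'   `"settle_threshold"`.
#' @param bounds named list: for each continuous free parameter a positive
#'   `c(lower, upper)` interval; for `settle_threshold` an integer grid.
#' @param fixed_params a [kinetic_params()] supplying every parameter not
#'   being fitted (fitted entries are used as fallback centers only).
#' @param fixed_mapping mapping used for entries of
#'   `{od_per_unit, settle_threshold}` that are not free.
#' @param loss `"sse"` (default; the experiments report simple replicate
#'   means) or `"weighted_sse"` (inverse replicate variance per
#'   density-time cell).
#' @param s_mode,initial_mode simulation modes.
#' @return an object of class `calibration_problem`.
#' @export
calibration_problem <- function(dataset, free_params, bounds,
                                fixed_params,
                                fixed_mapping = default_mapping(),
                                loss = c("sse", "weighted_sse"),
                                s_mode = "constant",
                                initial_mode = "unsilicified") {
  stopifnot(inherits(dataset, "settlement_dataset"))
  loss <- match.arg(loss)
  allowed <- c("kp_scale", "kn_scale", "kp1", "kn1", "od_per_unit",
               "settle_threshold")
  if (!length(free_params) || !all(free_params %in% allowed)) {
    stop("free_params must be a nonempty subset of: ",
         paste(allowed, collapse = ", "), call. = FALSE)
  }
  cont <- setdiff(free_params, "settle_threshold")
  for (p in cont) {
    b <- bounds[[p]]
    if (is.null(b) || length(b) != 2 || any(b <= 0) || b[1] >= b[2]) {
      stop("bounds for ", p, " must be a positive (lower, upper) interval",
           call. = FALSE)
    }
  }
  if ("settle_threshold" %in% free_params) {
    g <- bounds[["settle_threshold"]]
    if (is.null(g) || any(g != round(g)) || any(g < 2)) {
      stop("bounds for settle_threshold must be an integer grid >= 2",
           call. = FALSE)
    }
  }
  w <- NULL
  if (loss == "weighted_sse") {
    obs <- dataset
    obs$norm <- stats::ave(obs$od600, obs$density_label, obs$replicate,
                           FUN = function(x) x / x[1])
    v <- stats::ave(obs$norm, obs$density_label, obs$time_min,
                    FUN = stats::var)
    v[!is.finite(v) | v <= 0] <- stats::median(v[is.finite(v) & v > 0])
    ord <- order(obs$initial_od, obs$density_label, obs$replicate,
                 obs$time_min)
    w <- 1 / v[ord]
  }
  structure(list(dataset = dataset, free_params = free_params,
                 bounds = bounds, fixed_params = validate_params(fixed_params),
                 fixed_mapping = fixed_mapping, loss = loss, weights = w,
                 s_mode = s_mode, initial_mode = initial_mode),
            class = "calibration_problem")
}

# assemble (params, mapping) from the problem's fixed values plus a named
# vector of estimates for the free parameters
apply_estimates <- function(problem, est) {
  p <- problem$fixed_params
  m <- problem$fixed_mapping
  for (nm in names(est)) {
    switch(nm,
      kp_scale = { p$kernel$kp_scale <- est[[nm]] },
      kn_scale = { p$kernel$kn_scale <- est[[nm]] },
      kp1 = { p$kp1 <- est[[nm]] },
      kn1 = { p$kn1 <- est[[nm]] },
      od_per_unit = { m$od_per_unit <- est[[nm]] },
      settle_threshold = { m$settle_threshold <- as.integer(est[[nm]]) },
      stop("unknown parameter: ", nm, call. = FALSE)
    )
  }
  list(params = validate_params(p), mapping = m)
}

#' Fit kinetic parameters to a settlement dataset
#'
#' Minimizes the (optionally weighted) sum of squared residuals by
#' Levenberg-Marquardt ([minpack.lm::nls.lm()]) over log-transformed
#' continuous parameters within bounds. `n_starts` initial points are drawn
#' reproducibly (log-uniform within the bounds) from `seed`; an integer
#' `settle_threshold`, if free, is optimized by exhaustive grid. The result
#' is the best start, marked converged only if the optimizer's own
#' convergence criterion fired.
#'
#' @param problem a [calibration_problem()].
#' @param n_starts number of multi-start initial points (default 3).
#' @param seed integer seed for the start draws.
#' @return object of class `calibration_result`: `estimates` (named),
#'   `loss_value`, `n_evaluations`, `converged`, `residuals` (unweighted, at
#'   the optimum), `seed`, and the per-start table `starts`.
#' @export
fit_settlement <- function(problem, n_starts = 3, seed = 1L) {
  stopifnot(inherits(problem, "calibration_problem"))
  cont <- setdiff(problem$free_params, "settle_threshold")
  thr_grid <- if ("settle_threshold" %in% problem$free_params) {
    as.integer(problem$bounds[["settle_threshold"]])
  } else {
    as.integer(problem$fixed_mapping$settle_threshold)
  }
  lo <- log(vapply(cont, function(p) problem$bounds[[p]][1], 0))
  hi <- log(vapply(cont, function(p) problem$bounds[[p]][2], 0))

  set.seed(as.integer(seed))
  starts <- matrix(runif(n_starts * length(cont), rep(lo, each = n_starts),
                         rep(hi, each = n_starts)),
                   nrow = n_starts, dimnames = list(NULL, cont))

  n_eval <- 0L
  sqw <- if (is.null(problem$weights)) 1 else sqrt(problem$weights)
  resid_fn <- function(logpar, thr) {
    n_eval <<- n_eval + 1L
    est <- as.list(exp(logpar))
    names(est) <- cont
    est$settle_threshold <- thr
    pm <- apply_estimates(problem, est)
    r <- tryCatch(
      residuals_settlement(pm$params, pm$mapping, problem$dataset,
                           s_mode = problem$s_mode,
                           initial_mode = problem$initial_mode),
      error = function(e) rep(1e6, nrow(problem$dataset))
    )
    r * sqw
  }

  best <- NULL
  log <- list()
  for (thr in thr_grid) {
    for (s in seq_len(n_starts)) {
      fitres <- tryCatch(
        minpack.lm::nls.lm(
          par = starts[s, ], lower = lo, upper = hi,
          fn = resid_fn, thr = thr,
          control = minpack.lm::nls.lm.control(
            maxiter = 200, ftol = 1e-14, ptol = 1e-12)
        ),
        error = function(e) e
      )
      if (inherits(fitres, "error")) {
        log[[length(log) + 1L]] <- list(thr = thr, start = s,
                                        error = conditionMessage(fitres))
        next
      }
      log[[length(log) + 1L]] <- list(thr = thr, start = s,
                                      deviance = fitres$deviance,
                                      info = fitres$info)
      if (is.null(best) || fitres$deviance < best$deviance) {
        best <- fitres
        best$thr <- thr
      }
    }
  }
  if (is.null(best)) {
    stop("all calibration starts failed:\n",
         paste(vapply(log, function(x) paste0("  threshold ", x$thr,
                                              " start ", x$start, ": ",
                                              x$error), ""),
               collapse = "\n"), call. = FALSE)
  }

  est <- exp(best$par)
  names(est) <- cont
  if ("settle_threshold" %in% problem$free_params) {
    est <- c(est, settle_threshold = best$thr)
  }
  best_cont <- setNames(as.list(exp(best$par)), cont)
  full <- apply_estimates(problem, c(best_cont,
                                     list(settle_threshold = best$thr)))
  resid <- residuals_settlement(full$params, full$mapping, problem$dataset,
                                s_mode = problem$s_mode,
                                initial_mode = problem$initial_mode)
  structure(list(estimates = est, loss_value = best$deviance,
                 n_evaluations = n_eval,
                 converged = best$info %in% 1:3,
                 residuals = resid, seed = as.integer(seed),
                 starts = log, params = full$params,
                 mapping = full$mapping),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat("<calibration_result>\n  estimates:",
      paste(sprintf("%s=%.6g", names(x$estimates), x$estimates),
            collapse = ", "),
      sprintf("\n  loss=%.4g, %d evaluations, converged=%s\n",
              x$loss_value, x$n_evaluations, x$converged))
  invisible(x)
}

#' Parameter-recovery study
#'
#' Repeats a generate-then-fit cycle with independent noise seeds and
#' reports how well the fitting stage recovers the generating parameters:
#' per-parameter relative bias and relative RMSE, and the fraction of
#' converged fits.
#'
#' @param true_params the generating [kinetic_params()].
#' @param design list describing the synthetic design; recognized entries
#'   (with defaults): `mapping` ([default_mapping()]), `densities`
#'   (OD600 values, `2.8 * c(1, 2, 4, 6)`), `t_end` (90), `dt` (5),
#'   `replicates` (3), `cv` (0.03), `free_params`
#'   (`c("kp_scale", "kn_scale")`), `bounds` (true value x 1e-2 .. 1e2),
#'   `n_starts` (3).
#' @param n_repeats number of generate-fit repeats (default 20).
#' @param seed integer; forked deterministically per repeat for both the
#'   noise and the fit starts.
#' @return object of class `recovery_report`: `estimates` (repeat x
#'   parameter), `true`, `rel_bias`, `rel_rmse`, `converged_fraction`.
#' @export
parameter_recovery <- function(true_params, design = list(),
                               n_repeats = 20, seed = 1L) {
  true_params <- validate_params(true_params)
  stopifnot(n_repeats >= 1)
  dgn <- utils::modifyList(list(
    mapping = default_mapping(), densities = 2.8 * c(1, 2, 4, 6),
    t_end = 90, dt = 5, replicates = 3, cv = 0.03,
    free_params = c("kp_scale", "kn_scale"), bounds = NULL, n_starts = 3
  ), design)

  truth <- c(kp_scale = true_params$kernel$kp_scale,
             kn_scale = true_params$kernel$kn_scale,
             kp1 = true_params$kp1, kn1 = true_params$kn1,
             od_per_unit = dgn$mapping$od_per_unit)
  cont <- setdiff(dgn$free_params, "settle_threshold")
  if (is.null(dgn$bounds)) {
    dgn$bounds <- lapply(setNames(cont, cont),
                         function(p) truth[[p]] * c(1e-2, 1e2))
  }

  est <- matrix(NA_real_, n_repeats, length(dgn$free_params),
                dimnames = list(NULL, dgn$free_params))
  conv <- logical(n_repeats)
  for (r in seq_len(n_repeats)) {
    nm <- if (dgn$cv > 0) {
      noise_model("multiplicative_gaussian", cv = dgn$cv,
                  seed = fork_seed(seed, r))
    } else {
      noise_model("none", seed = fork_seed(seed, r))
    }
    ds <- generate_settlement_curves(true_params, dgn$mapping,
                                     densities = dgn$densities,
                                     t_end = dgn$t_end, dt = dgn$dt,
                                     replicates = dgn$replicates, noise = nm)
    prob <- calibration_problem(ds, dgn$free_params, dgn$bounds,
                                fixed_params = true_params,
                                fixed_mapping = dgn$mapping)
    fit <- fit_settlement(prob, n_starts = dgn$n_starts,
                          seed = fork_seed(seed, 100000L + r))
    est[r, ] <- fit$estimates[dgn$free_params]
    conv[r] <- fit$converged
  }
  rel <- sweep(est, 2, truth[colnames(est)], "/") - 1
  structure(list(estimates = est, true = truth[colnames(est)],
                 rel_bias = colMeans(rel),
                 rel_rmse = sqrt(colMeans(rel^2)),
                 converged_fraction = mean(conv),
                 n_repeats = n_repeats, seed = as.integer(seed),
                 design = dgn),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("<recovery_report> %d repeats, %.0f%% converged\n",
              x$n_repeats, 100 * x$converged_fraction))
  for (p in colnames(x$estimates)) {
    cat(sprintf("  %-12s true=%.5g  rel bias=%+.3f  rel RMSE=%.3f\n",
                p, x$true[[p]], x$rel_bias[[p]], x$rel_rmse[[p]]))
  }
  invisible(x)
}
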