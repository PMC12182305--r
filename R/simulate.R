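#' Integrate the aggregation ODE system
#'
#' Solves the coagulation-fragmentation system with [deSolve::lsoda()]
#' (adaptive, stiff-capable) on a user-supplied output grid. The trajectory
#' is checked for mass conservation (relative drift of total cell mass must
#' stay within `1e-6`, and is recorded in the solver metadata) and for
#' negative concentrations: values in `(-1e-10, 0)` are clipped to zero on
#' output, anything more negative raises an integrity error.
#'
#' @param params a [kinetic_params()].
#' @param initial a [system_state()] with `length(A) == params$N`.
#' @param times strictly increasing output grid in minutes, starting at 0.
#' @param rtol,atol relative / absolute solver tolerances.
#' @param s_mode precursor mode, `"constant"` (default) or `"dynamic"`.
#' @return an object of class `kinetic_trajectory`: list with `times`,
#'   `C`, `S` (vectors), `A` (matrix, time by size), `params`, and
#'   `solver_meta` (tolerances, S mode, step count, mass drift).
#' @examples
#' p <- kinetic_params(kp1 = 1, kernel = kernel_spec("constant", 30), N = 10)
#' s0 <- system_state(C = 0.01, S = 1, A = rep(0, 10))
#' traj <- integrate_kinetics(p, s0, times = seq(0, 60, by = 5))
#' @export
integrate_kinetics <- function(params, initial, times,
                               rtol = 1e-8, atol = 1e-12,
                               s_mode = c("constant", "dynamic")) {
  params <- validate_params(params)
  s_mode <- match.arg(s_mode)
  stopifnot(inherits(initial, "system_state"))
  if (length(initial$A) != params$N) {
    stop("initial state has ", length(initial$A),
         " aggregate sizes but params$N = ", params$N, call. = FALSE)
  }
  if (!is.numeric(times) || length(times) < 2 || times[1] != 0 ||
      any(diff(times) <= 0)) {
    stop("times must be strictly increasing from 0", call. = FALSE)
  }

  N <- params$N
  tab <- build_rate_tables(params$kernel, N)
  rhs_set_params(params$kp1, params$kn1, tab$kp, tab$kn,
                 s_mode == "dynamic")
  y0 <- c(initial$C, initial$S, initial$A)
  sol <- deSolve::lsoda(y0, times, func = "rhs_deriv", parms = NULL,
                        dllname = "silicoag",
                        rtol = rtol, atol = atol, maxsteps = 50000)
  diagn <- attributes(sol)
  if (!is.null(diagn$istate) && diagn$istate[1] < 0) {
    stop("ODE integration failed (istate = ", diagn$istate[1],
         ") near t = ", max(sol[, 1]), " min", call. = FALSE)
  }
  if (nrow(sol) != length(times)) {
    stop("ODE integration stopped early at t = ", max(sol[, 1]), " min",
         call. = FALSE)
  }

  y <- unname(sol[, -1, drop = FALSE])
  low <- min(y)
  if (low < -1e-10) {
    stop("integrity error: concentration reached ", format(low),
         " (below -1e-10)", call. = FALSE)
  }
  y[y < 0] <- 0

  mass <- y[, 1] + y[, -(1:2), drop = FALSE] %*% seq_len(N)
  drift <- max(abs(mass - mass[1])) / mass[1]
  if (!is.finite(drift) || drift > 1e-6) {
    stop("integrity error: relative cell-mass drift ", format(drift),
         " exceeds 1e-6", call. = FALSE)
  }

  structure(list(
    times = as.numeric(times),
    C = y[, 1], S = y[, 2], A = y[, -(1:2), drop = FALSE],
    params = params,
    solver_meta = list(rtol = rtol, atol = atol, s_mode = s_mode,
                       n_steps = unname(diagn$istate[3]),
                       mass_drift = drift)
  ), class = "kinetic_trajectory")
}

#' @export
print.kinetic_trajectory <- function(x, ...) {
  cat(sprintf(
    "<kinetic_trajectory> N=%d, %d time points over [0, %g] min, S %s\n  mass drift %.3g\n",
    x$params$N, length(x$times), max(x$times), x$solver_meta$s_mode,
    x$solver_meta$mass_drift))
  invisible(x)
}

#' State of a trajectory at a grid index
#'
#' @param traj a `kinetic_trajectory`.
#' @param i time-grid index.
#' @return a [system_state()].
#' @export
state_at <- function(traj, i) {
  stopifnot(inherits(traj, "kinetic_trajectory"))
  i <- as.integer(i)
  stopifnot(i >= 1, i <= length(traj$times))
  system_state(traj$C[i], traj$S[i], traj$A[i, ])
}

#' Suspended (supernatant) mass fraction of a trajectory
#'
#' Maps the size-resolved state to the measured observable: the fraction of
#' total cell mass still in suspension. Aggregates of size
#' `>= settle_threshold` are counted as settled, so at each time
#' `fraction = (C + sum_{j < threshold} j * A[j]) / mass(t = 0)`,
#' mirroring the experimental normalization of supernatant OD600 to its
#' time-zero reading.
#'
#' @param traj a `kinetic_trajectory`.
#' @param settle_threshold integer >= 2 and <= N; default 2 (every aggregate
#'   of two or more cells settles).
#' @param density_label optional text label carried on the output.
#' @return data frame of class `observable_series` with columns `time_min`
#'   and `suspended_fraction`; attributes `settle_threshold`, `density_label`.
#' @export
suspended_fraction <- function(traj, settle_threshold = 2,
                               density_label = "") {
  stopifnot(inherits(traj, "kinetic_trajectory"))
  thr <- as.integer(settle_threshold)
  if (length(thr) != 1 || is.na(thr) || thr < 2) {
    stop("settle_threshold must be an integer >= 2", call. = FALSE)
  }
  N <- traj$params$N
  if (thr > N) stop("settle_threshold exceeds N = ", N, call. = FALSE)
  mass0 <- traj$C[1] + sum(seq_len(N) * traj$A[1, ])
  if (mass0 <= 0) stop("initial state carries no cell mass", call. = FALSE)
  keep <- seq_len(thr - 1L)
  susp <- (traj$C + traj$A[, keep, drop = FALSE] %*% keep) / mass0
  susp <- pmin(pmax(as.numeric(susp), 0), 1)
  structure(
    data.frame(time_min = traj$times, suspended_fraction = susp),
    settle_threshold = thr, density_label = density_label,
    class = c("observable_series", "data.frame")
  )
}

#' Settled percentage at a time point
#'
#' `100 * (1 - suspended fraction)` at time `t`, with linear interpolation
#' between trajectory grid points (exact at grid times).
#'
#' @param traj a `kinetic_trajectory`.
#' @param t time in minutes, within the trajectory range.
#' @param settle_threshold see [suspended_fraction()].
#' @return percentage in `[0, 100]`.
#' @export
settled_percentage_at <- function(traj, t, settle_threshold = 2) {
  stopifnot(inherits(traj, "kinetic_trajectory"))
  if (!is.numeric(t) || length(t) != 1 || t < 0 || t > max(traj$times)) {
    stop("t must lie within the trajectory time range", call. = FALSE)
  }
  obs <- suspended_fraction(traj, settle_threshold)
  s <- approx(obs$time_min, obs$suspended_fraction, xout = t)$y
  100 * (1 - s)
}

#' Density sweep of settlement dynamics
#'
#' Integrates the model from a range of initial cell densities and returns
#' one suspended-fraction series per density — the simulation behind the
#' prediction that higher initial density accelerates aggregation.
#'
#' @param params a [kinetic_params()].
#' @param densities positive initial densities (model units).
#' @param times output grid (minutes, from 0).
#' @param settle_threshold see [suspended_fraction()].
#' @param initial_mode `"unsilicified"` (default: all mass starts in C) or
#'   `"silicified"` (all mass starts in A1, silicification assumed complete).
#' @param ... passed to [integrate_kinetics()].
#' @return named list of `observable_series`, one per density, with the
#'   initial-condition mode in attribute `initial_mode`.
#' @export
density_sweep <- function(params, densities, times, settle_threshold = 2,
                          initial_mode = c("unsilicified", "silicified"),
                          ...) {
  params <- validate_params(params)
  initial_mode <- match.arg(initial_mode)
  if (!is.numeric(densities) || !length(densities) || any(densities <= 0)) {
    stop("densities must be positive", call. = FALSE)
  }
  out <- lapply(densities, function(d) {
    A0 <- rep(0, params$N)
    if (initial_mode == "silicified") {
      A0[1] <- d
      init <- system_state(C = 0, S = params$S0, A = A0)
    } else {
      init <- system_state(C = d, S = params$S0, A = A0)
    }
    traj <- integrate_kinetics(params, init, times, ...)
    suspended_fraction(traj, settle_threshold,
                       density_label = format(d, digits = 6))
  })
  names(out) <- format(densities, digits = 6)
  attr(out, "initial_mode") <- initial_mode
  out
}
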