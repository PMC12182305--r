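#' Configuration for the stochastic (Gillespie) oracle
#'
#' The same reaction network as the deterministic model, simulated exactly at
#' integer copy number in a system of size `volume` (Omega). Counts relate to
#' concentrations by `count = volume * concentration`. Intended for
#' validation at modest sizes (`N <= 16`, `volume <= 1e5`); larger requests
#' only emit a cost warning.
#'
#' @param params a [kinetic_params()].
#' @param volume positive system size Omega.
#' @param initial_counts named list or vector with nonnegative integer
#'   entries `C`, `S`, and `A` (length-`N` vector of j-mer counts).
#' @param times output grid in minutes, starting at 0.
#' @param seed integer base seed; each run is seeded deterministically from
#'   `(seed, run_index)`.
#' @param n_runs number of independent runs for [ssa_ensemble()].
#' @param s_mode `"constant"` (silicification propensity `kp1 * S0 * nC`)
#'   or `"dynamic"` (`(kp1/volume) * nC * nS`).
#' @return an object of class `stochastic_config`.
#' @export
stochastic_config <- function(params, volume, initial_counts, times,
                              seed = 1L, n_runs = 1L,
                              s_mode = c("constant", "dynamic")) {
  params <- validate_params(params)
  s_mode <- match.arg(s_mode)
  stopifnot(is.numeric(volume), length(volume) == 1, volume > 0)
  if (!is.numeric(times) || times[1] != 0 || any(diff(times) <= 0)) {
    stop("times must be strictly increasing from 0", call. = FALSE)
  }
  n_runs <- as.integer(n_runs)
  if (is.na(n_runs) || n_runs < 1) stop("n_runs must be >= 1", call. = FALSE)
  cnt <- c(initial_counts$C, initial_counts$S, initial_counts$A)
  if (length(cnt) != params$N + 2 || any(cnt < 0) || any(cnt != round(cnt))) {
    stop("initial_counts must hold nonnegative integers C, S and A[1..N]",
         call. = FALSE)
  }
  if (params$N > 16 || volume > 1e5) {
    warning("stochastic oracle is intended for N <= 16 and volume <= 1e5; ",
            "this configuration may be slow", call. = FALSE)
  }
  structure(list(params = params, volume = as.numeric(volume),
                 counts0 = as.integer(round(cnt)),
                 times = as.numeric(times), seed = as.integer(seed),
                 n_runs = n_runs, s_mode = s_mode),
            class = "stochastic_config")
}

# deterministic per-run seed fork; kept below 2^31
fork_seed <- function(seed, run_index) {
  as.integer((as.numeric(seed) + 1000003 * as.numeric(run_index)) %% 2147483647)
}

#' Single exact stochastic run
#'
#' Runs the direct-method Gillespie algorithm for the full network and
#' samples the counts on the configured grid. Reproducible: the RNG is
#' seeded from `(config$seed, run_index)`.
#'
#' @param config a [stochastic_config()].
#' @param run_index 1-based run number.
#' @return list of class `ssa_trajectory` with `times` and integer `counts`
#'   (time by species, columns `C`, `S`, `A1..AN`).
#' @export
ssa_run <- function(config, run_index = 1L) {
  stopifnot(inherits(config, "stochastic_config"))
  p <- config$params
  tab <- build_rate_tables(p$kernel, p$N)
  S0conc <- config$counts0[2] / config$volume
  set.seed(fork_seed(config$seed, run_index))
  m <- ssa_run_cpp(config$counts0, config$times, p$kp1, p$kn1,
                   tab$kp, tab$kn, config$volume,
                   config$s_mode == "dynamic", S0conc)
  colnames(m) <- c("C", "S", paste0("A", seq_len(p$N)))
  structure(list(times = config$times, counts = m, run_index = run_index),
            class = "ssa_trajectory")
}

#' Ensemble of stochastic runs
#'
#' Runs `config$n_runs` independent trajectories (deterministically seeded
#' per run) and summarizes per-time means and standard errors of the counts.
#' The raw per-run counts are kept so downstream summaries (e.g. the
#' suspended fraction in [ode_ssa_discrepancy()]) can compute their own
#' standard errors.
#'
#' @param config a [stochastic_config()].
#' @return list of class `ssa_ensemble` with `times`, `mean_state`,
#'   `se_state` (time by species), `counts` (run x time x species array),
#'   `n_runs`, `seed`.
#' @export
ssa_ensemble <- function(config) {
  stopifnot(inherits(config, "stochastic_config"))
  nt <- length(config$times)
  nsp <- config$params$N + 2L
  arr <- array(0L, dim = c(config$n_runs, nt, nsp))
  for (r in seq_len(config$n_runs)) {
    arr[r, , ] <- ssa_run(config, r)$counts
  }
  mn <- apply(arr, c(2, 3), mean)
  se <- if (config$n_runs > 1) {
    apply(arr, c(2, 3), sd) / sqrt(config$n_runs)
  } else {
    matrix(0, nt, nsp)
  }
  dimnames(mn) <- dimnames(se) <-
    list(NULL, c("C", "S", paste0("A", seq_len(config$params$N))))
  structure(list(times = config$times, mean_state = mn, se_state = se,
                 counts = arr, n_runs = config$n_runs, seed = config$seed,
                 volume = config$volume),
            class = "ssa_ensemble")
}

#' Mean-field discrepancy between the stochastic ensemble and the ODE
#'
#' Compares the ensemble suspended fraction to the deterministic one,
#' per grid time, as a z-score: `z = (ensemble mean - ODE) / SE`, with the
#' standard error taken across runs. Grid times where the SE is zero and the
#' difference is zero score `z = 0` by convention. `max |z| > 3` flags a
#' mean-field mismatch.
#'
#' @param summary an [ssa_ensemble()] result.
#' @param traj a `kinetic_trajectory` on the same time grid.
#' @param settle_threshold see [suspended_fraction()].
#' @return list of class `ssa_discrepancy` with `times`, `z`, `max_abs_z`,
#'   `mismatch` flag.
#' @export
ode_ssa_discrepancy <- function(summary, traj, settle_threshold = 2) {
  stopifnot(inherits(summary, "ssa_ensemble"),
            inherits(traj, "kinetic_trajectory"))
  if (length(summary$times) != length(traj$times) ||
      max(abs(summary$times - traj$times)) > 1e-9) {
    stop("ensemble and trajectory time grids differ", call. = FALSE)
  }
  thr <- as.integer(settle_threshold)
  N <- traj$params$N
  if (thr < 2 || thr > N) stop("settle_threshold out of range", call. = FALSE)

  # per-run suspended mass fraction (counts): (C + sum_{j<thr} j*A_j)/mass0
  w <- c(1, 0, seq_len(N) * (seq_len(N) < thr))
  wm <- c(1, 0, seq_len(N))
  nruns <- summary$n_runs
  nt <- length(summary$times)
  susp <- matrix(0, nruns, nt)
  for (r in seq_len(nruns)) {
    cnts <- matrix(summary$counts[r, , ], nrow = nt)
    mass0 <- sum(wm * cnts[1, ])
    susp[r, ] <- as.numeric(cnts %*% w) / mass0
  }
  mean_susp <- colMeans(susp)
  se_susp <- if (nruns > 1) apply(susp, 2, sd) / sqrt(nruns) else rep(0, nt)

  ode_susp <- suspended_fraction(traj, thr)$suspended_fraction
  diff <- mean_susp - ode_susp
  z <- ifelse(se_susp > 0, diff / se_susp, ifelse(abs(diff) < 1e-12, 0, Inf))
  structure(list(times = summary$times, mean_susp = mean_susp,
                 se_susp = se_susp, ode_susp = ode_susp, z = z,
                 max_abs_z = max(abs(z)), mismatch = max(abs(z)) > 3),
            class = "ssa_discrepancy")
}

#' @export
print.ssa_discrepancy <- function(x, ...) {
  cat(sprintf("<ssa_discrepancy> max |z| = %.3f (%s)\n", x$max_abs_z,
              if (x$mismatch) "MEAN-FIELD MISMATCH" else "consistent"))
  invisible(x)
}
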