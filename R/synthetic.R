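#' Measurement noise model for synthetic settlement data
#'
#' Plate-reader style multiplicative Gaussian noise: each OD reading is
#' `clean * (1 + cv * eps)` with `eps ~ N(0, 1)`, truncated at zero (no
#' negative OD). `cv = 0` is canonicalized to `kind = "none"` and vice versa.
#'
#' @param kind `"none"` or `"multiplicative_gaussian"`.
#' @param cv nonnegative coefficient of variation (default 0.03 for the
#'   Gaussian kind).
#' @param seed integer RNG seed for reproducible datasets.
#' @return an object of class `noise_model`.
#' @export
noise_model <- function(kind = c("none", "multiplicative_gaussian"),
                        cv = NULL, seed = 1L) {
  kind <- match.arg(kind)
  if (is.null(cv)) cv <- if (kind == "none") 0 else 0.03
  stopifnot(is.numeric(cv), length(cv) == 1, is.finite(cv), cv >= 0)
  if (cv == 0) kind <- "none"
  if (kind == "none") cv <- 0
  structure(list(kind = kind, cv = cv, seed = as.integer(seed)),
            class = "noise_model")
}

apply_noise <- function(clean, noise) {
  if (noise$kind == "none") return(clean)
  pmax(0, clean * (1 + noise$cv * rnorm(length(clean))))
}

#' Construct / validate a settlement dataset
#'
#' A tidy table of supernatant-OD600 settlement curves: one row per reading,
#' columns `density_label`, `initial_od`, `replicate`, `time_min`, `od600`.
#' Every curve (a `density_label` x `replicate` pair) must start at time 0
#' with strictly increasing times and nonnegative readings.
#'
#' @param df data frame with the columns above.
#' @param meta list of provenance metadata (generator parameters or
#'   `source = "experimental"`, noise, seed).
#' @return the validated data frame with class `settlement_dataset` and
#'   attribute `meta`.
#' @export
settlement_dataset <- function(df, meta = list()) {
  need <- c("density_label", "initial_od", "replicate", "time_min", "od600")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("settlement dataset is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (nrow(df)) {
    if (any(!is.finite(df$od600)) || any(df$od600 < 0)) {
      stop("od600 readings must be finite and nonnegative", call. = FALSE)
    }
    if (any(df$initial_od <= 0)) {
      stop("initial_od must be positive", call. = FALSE)
    }
    for (key in split(df, list(df$density_label, df$replicate), drop = TRUE)) {
      id <- sprintf("(%s, replicate %s)", key$density_label[1], key$replicate[1])
      if (any(diff(key$time_min) <= 0)) {
        stop("times not strictly increasing for curve ", id, call. = FALSE)
      }
      if (key$time_min[1] != 0) {
        stop("curve ", id, " has no time-zero reading", call. = FALSE)
      }
    }
  }
  structure(df[need], meta = meta,
            class = c("settlement_dataset", "data.frame"))
}

#' Generate replicated settlement curves
#'
#' Simulates the model at each initial density, converts the suspended mass
#' fraction to a supernatant OD600 (`od = initial_od * suspended_fraction`),
#' samples on a fixed cadence, and applies i.i.d. per-reading noise per
#' replicate. This emulates the experimental design of the settlement
#' assays: readings every `dt` minutes, `replicates` biological replicates,
#' a density sweep. Fully reproducible from `noise$seed`.
#'
#' @param params a [kinetic_params()].
#' @param mapping list with `od_per_unit` (OD600 per model density unit) and
#'   `settle_threshold`; see [default_mapping()].
#' @param densities vector of positive initial OD600 values. Default: 1x,
#'   2x, 4x and 6x multiples of a base culture at OD600 2.8.
#' @param t_end,dt sampling window and cadence in minutes (defaults 90 and 5,
#'   i.e. 19 readings per curve).
#' @param replicates replicates per density (default 3).
#' @param noise a [noise_model()].
#' @param initial_mode,s_mode passed to the simulation; see [density_sweep()].
#' @return a [settlement_dataset()].
#' @export
generate_settlement_curves <- function(params, mapping = default_mapping(),
                                       densities = 2.8 * c(1, 2, 4, 6),
                                       t_end = 90, dt = 5, replicates = 3,
                                       noise = noise_model("none"),
                                       initial_mode = "unsilicified",
                                       s_mode = "constant") {
  params <- validate_params(params)
  stopifnot(inherits(noise, "noise_model"))
  if (!is.numeric(dt) || dt <= 0 || t_end < dt) {
    stop("invalid sampling cadence: need dt > 0 and t_end >= dt",
         call. = FALSE)
  }
  if (any(densities <= 0)) stop("densities must be positive", call. = FALSE)
  replicates <- as.integer(replicates)
  stopifnot(replicates >= 1)
  od_per_unit <- mapping$od_per_unit
  if (!is.numeric(od_per_unit) || od_per_unit <= 0) {
    stop("mapping$od_per_unit must be positive", call. = FALSE)
  }

  times <- seq(0, t_end, by = dt)
  set.seed(noise$seed)
  rows <- list()
  for (d in densities) {
    series <- density_sweep(params, d / od_per_unit, times,
                            settle_threshold = mapping$settle_threshold,
                            initial_mode = initial_mode,
                            s_mode = s_mode)[[1]]
    clean <- d * series$suspended_fraction
    label <- sprintf("od%.4g", d)
    for (r in seq_len(replicates)) {
      rows[[length(rows) + 1L]] <- data.frame(
        density_label = label, initial_od = d, replicate = r,
        time_min = times, od600 = apply_noise(clean, noise)
      )
    }
  }
  settlement_dataset(
    do.call(rbind, rows),
    meta = list(source = "synthetic", params = params, mapping = mapping,
                densities = densities, t_end = t_end, dt = dt,
                replicates = replicates, noise = noise,
                initial_mode = initial_mode, s_mode = s_mode)
  )
}

#' Generate an endpoint settlement assay
#'
#' Emulates the endpoint readout: for each density (a multiple of a base
#' culture), the percentage of OD600 remaining in the supernatant after
#' `t_end` minutes, normalized to the *measured* (noisy) time-zero reading —
#' the normalization an experimenter would actually perform, so realistic
#' normalization error propagates into the summary.
#'
#' @param params a [kinetic_params()].
#' @param mapping see [generate_settlement_curves()].
#' @param density_multiples multiples of the base culture (default 1, 2, 4, 6).
#' @param base_od OD600 of the 1x culture (default 2.8).
#' @param t_end endpoint time in minutes (default 90, i.e. 1.5 h).
#' @param replicates replicates per density (default 3).
#' @param noise a [noise_model()].
#' @return data frame with columns `density_label` (e.g. `"1x"`),
#'   `replicate`, `remaining_percent`.
#' @export
generate_endpoint_assay <- function(params, mapping = default_mapping(),
                                    density_multiples = c(1, 2, 4, 6),
                                    base_od = 2.8, t_end = 90,
                                    replicates = 3,
                                    noise = noise_model("none")) {
  params <- validate_params(params)
  stopifnot(t_end > 0, base_od > 0, all(density_multiples > 0))
  replicates <- as.integer(replicates)
  set.seed(noise$seed)
  times <- c(0, t_end)
  out <- list()
  for (m in density_multiples) {
    od0 <- base_od * m
    series <- density_sweep(params, od0 / mapping$od_per_unit, times,
                            settle_threshold = mapping$settle_threshold)[[1]]
    clean <- od0 * series$suspended_fraction
    for (r in seq_len(replicates)) {
      noisy <- apply_noise(clean, noise)
      out[[length(out) + 1L]] <- data.frame(
        density_label = sprintf("%gx", m), replicate = r,
        remaining_percent = 100 * noisy[2] / noisy[1]
      )
    }
  }
  do.call(rbind, out)
}
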