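#' Kinetic parameters of the aggregation model
#'
#' Bundles every rate constant of the reaction network: the silicification
#' step `C + S <-> A1` (forward `kp1`, reverse `kn1`), the coagulation /
#' fragmentation kernel for `Ai + Aj <-> A(i+j)`, the truncation size `N`
#' (maximum number of cells in an aggregate), and the precursor level `S0`.
#'
#' Units: the model is dimensionless in concentration ("model units", the
#' scale of the 0.002-0.016 density sweep); time is in minutes.
#'
#' @param kp1 positive silicification forward rate (per concentration per minute).
#' @param kn1 nonnegative silicification reverse rate (per minute).
#' @param kernel a [kernel_spec()].
#' @param N even integer >= 2, maximum aggregate size.
#' @param S0 nonnegative precursor concentration (model units).
#' @return an object of class `kinetic_params`.
#' @examples
#' kinetic_params(kp1 = 1, kn1 = 0, kernel = kernel_spec("constant", 30), N = 20)
#' @export
kinetic_params <- function(kp1, kn1 = 0, kernel, N, S0 = 1) {
  validate_params(structure(
    list(kp1 = kp1, kn1 = kn1, kernel = kernel, N = N, S0 = S0),
    class = "kinetic_params"
  ))
}

#' Validate kinetic parameters
#'
#' Checks every field of a `kinetic_params` object (or a bare list with the
#' same fields), rejecting odd or too-small `N` and negative rates, and
#' returns the canonical form. Each violation names the offending field.
#'
#' @param params a `kinetic_params` object or list with fields `kp1`, `kn1`,
#'   `kernel`, `N`, `S0`.
#' @return the validated `kinetic_params` object.
#' @export
validate_params <- function(params) {
  if (!is.list(params)) stop("params must be a list", call. = FALSE)
  need <- c("kp1", "kn1", "kernel", "N", "S0")
  miss <- setdiff(need, names(params))
  if (length(miss)) {
    stop("params is missing field(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  chk_rate <- function(x, name, strict = FALSE) {
    if (!is.numeric(x) || length(x) != 1 || !is.finite(x)) {
      stop(name, " must be a single finite number", call. = FALSE)
    }
    if (strict && x <= 0) stop(name, " must be positive", call. = FALSE)
    if (!strict && x < 0) stop(name, " must be nonnegative", call. = FALSE)
    as.numeric(x)
  }
  params$kp1 <- chk_rate(params$kp1, "kp1", strict = TRUE)
  params$kn1 <- chk_rate(params$kn1, "kn1")
  params$S0 <- chk_rate(params$S0, "S0")
  params$N <- check_N(params$N)
  if (!inherits(params$kernel, "kernel_spec")) {
    params$kernel <- kernel_spec(params$kernel$family,
                                 params$kernel$kp_scale,
                                 params$kernel$kn_scale)
  }
  structure(params[need], class = "kinetic_params")
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat(sprintf("<kinetic_params> kp1=%g kn1=%g N=%d S0=%g\n  kernel: %s (kp_scale=%g, kn_scale=%g)\n",
              x$kp1, x$kn1, x$N, x$S0,
              x$kernel$family, x$kernel$kp_scale, x$kernel$kn_scale))
  invisible(x)
}

#' Truncation logic gate phi(j)
#'
#' Gates the self-coagulation channel `A_j + A_j -> A_{2j}`: `phi(j) = 1`
#' exactly when the product still fits under the truncation (`2j <= N`),
#' else 0. In particular `phi(N/2) = 1`: the channel producing the terminal
#' aggregate A_N from two half-size aggregates exists, and this is the only
#' convention under which total cell mass is conserved.
#'
#' @param j aggregate size index (vectorized), `1 <= j <= N`.
#' @param N even integer maximum aggregate size.
#' @return integer vector of 0/1.
#' @examples
#' phi(1:20, N = 20)
#' @export
phi <- function(j, N) {
  N <- check_N(N)
  if (!is.numeric(j) || any(!is.finite(j)) || any(j != round(j))) {
    stop("j must be integer-valued", call. = FALSE)
  }
  if (any(j < 1) || any(j > N)) {
    stop("j must satisfy 1 <= j <= N", call. = FALSE)
  }
  as.integer(2 * j <= N)
}
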