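#' Coagulation/fragmentation kernel specification
#'
#' Describes how the pairwise coagulation rate `kp(i, j)` and fragmentation
#' rate `kn(i, j)` vary with the sizes of the reacting aggregates. Three
#' families are provided:
#'
#' * `"constant"`: `kp(i, j) = kp_scale` for all sizes (the default — the
#'   fewest assumptions about size dependence);
#' * `"brownian"`: `kp_scale * (i^(1/3) + j^(1/3)) * (i^(-1/3) + j^(-1/3)) / 4`,
#'   the diffusion-limited form for spherical clusters, normalized so equal
#'   sizes give exactly `kp_scale`;
#' * `"product"`: `kp_scale * i * j / N`, a strongly size-favoring kernel for
#'   sensitivity analysis.
#'
#' `kn(i, j)` uses the same family with `kn_scale`.
#'
#' @param family kernel family, one of `"constant"`, `"brownian"`, `"product"`.
#' @param kp_scale positive coagulation rate scale (per concentration per minute).
#' @param kn_scale nonnegative fragmentation rate scale (per minute).
#' @return an object of class `kernel_spec`.
#' @examples
#' kernel_spec("constant", kp_scale = 0.5)
#' @export
kernel_spec <- function(family = c("constant", "brownian", "product"),
                        kp_scale, kn_scale = 0) {
  family <- match.arg(tolower(trimws(family[[1]])),
                      c("constant", "brownian", "product"))
  if (!is.numeric(kp_scale) || length(kp_scale) != 1 || !is.finite(kp_scale) ||
      kp_scale <= 0) {
    stop("kp_scale must be a single finite positive number", call. = FALSE)
  }
  if (!is.numeric(kn_scale) || length(kn_scale) != 1 || !is.finite(kn_scale) ||
      kn_scale < 0) {
    stop("kn_scale must be a single finite nonnegative number", call. = FALSE)
  }
  structure(list(family = family, kp_scale = kp_scale, kn_scale = kn_scale),
            class = "kernel_spec")
}

#' @export
print.kernel_spec <- function(x, ...) {
  cat(sprintf("<kernel_spec> family=%s kp_scale=%g kn_scale=%g\n",
              x$family, x$kp_scale, x$kn_scale))
  invisible(x)
}

#' Build the pairwise rate tables for a kernel
#'
#' Expands a [kernel_spec()] into symmetric `N x N` tables of coagulation and
#' fragmentation rates, indexed by 1-based aggregate size. Entries with
#' `i + j > N` are populated too: the right-hand-side assembly, not the
#' table, enforces the size truncation.
#'
#' @param kernel a [kernel_spec()].
#' @param N integer maximum aggregate size, at least 2.
#' @return list with symmetric numeric matrices `kp` and `kn`.
#' @export
build_rate_tables <- function(kernel, N) {
  stopifnot(inherits(kernel, "kernel_spec"))
  N <- check_N(N)
  i <- matrix(seq_len(N), N, N)
  j <- t(i)
  shape <- switch(kernel$family,
    constant = matrix(1, N, N),
    brownian = (i^(1 / 3) + j^(1 / 3)) * (i^(-1 / 3) + j^(-1 / 3)) / 4,
    product  = i * j / N,
    stop("unknown kernel family: ", kernel$family, call. = FALSE)
  )
  list(kp = kernel$kp_scale * shape, kn = kernel$kn_scale * shape)
}

# shared N validation (evenness is a model-level requirement: the printed
# dA_N block sums to N/2, so odd N is rejected rather than floored)
check_N <- function(N) {
  if (!is.numeric(N) || length(N) != 1 || !is.finite(N) || N != round(N)) {
    stop("N must be a single integer", call. = FALSE)
  }
  N <- as.integer(N)
  if (N < 2) stop("N must be at least 2", call. = FALSE)
  if (N %% 2L != 0L) {
    stop("N must be even (the terminal-size reaction block requires N/2 ",
         "to be an integer)", call. = FALSE)
  }
  N
}
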