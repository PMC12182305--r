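#' System state at one instant
#'
#' Concentrations of unsilicified cells `C`, precursor `S`, and aggregates
#' `A[1..N]` (1-based: `A[1]` is the silicified monomer, `A[j]` the j-mer).
#'
#' @param C nonnegative unsilicified-cell concentration (model units).
#' @param S nonnegative precursor concentration (model units).
#' @param A numeric vector of length `N` of nonnegative j-mer concentrations.
#' @return an object of class `system_state`.
#' @export
system_state <- function(C, S, A) {
  stopifnot(is.numeric(C), length(C) == 1, is.numeric(S), length(S) == 1,
            is.numeric(A))
  if (!all(is.finite(c(C, S, A)))) stop("state must be finite", call. = FALSE)
  if (C < 0 || S < 0 || any(A < 0)) {
    stop("concentrations must be nonnegative", call. = FALSE)
  }
  structure(list(C = as.numeric(C), S = as.numeric(S), A = as.numeric(A)),
            class = "system_state")
}

#' Total cell mass of a state
#'
#' The conserved quantity of the reaction network: `C + sum(j * A[j])`.
#' The precursor `S` carries no cell mass.
#'
#' @param state a [system_state()].
#' @return nonnegative scalar.
#' @export
total_cell_mass <- function(state) {
  stopifnot(inherits(state, "system_state"))
  state$C + sum(seq_along(state$A) * state$A)
}

#' Time derivative of the aggregation system
#'
#' Evaluates the right-hand side of the coagulation-fragmentation ODE system:
#' the silicification step `C + S <-> A1`, pairwise coagulation
#' `Ai + Aj -> A(i+j)` for `i + j <= N`, and fragmentation of every aggregate
#' into each unordered size pair. Formation of `A_j` sums unordered pairs
#' `(i, j - i)` for `i = 1..floor(j/2)`; the self channel `A_j + A_j` is
#' gated by [phi()] and carries the conventional factor 2 in the loss of
#' `A_j`. The derivative satisfies `dC + sum(j * dA[j]) = 0` exactly.
#'
#' @param state a [system_state()] with `length(A) == params$N`.
#' @param params a [kinetic_params()].
#' @param s_mode `"constant"` (default; precursor held at its current value,
#'   `dS = 0` — the excess-precursor assumption) or `"dynamic"`
#'   (`dS = -kp1*C*S + kn1*A1`).
#' @param neg_tol concentrations more negative than `-neg_tol` are a domain
#'   error; tiny negatives within tolerance are treated as 0.
#' @return list of class `state_derivative` with `dC`, `dS`, `dA` (per minute).
#' @examples
#' p <- kinetic_params(kp1 = 0.5, kernel = kernel_spec("constant", 1), N = 4)
#' derivative(system_state(C = 1, S = 1, A = rep(0, 4)), p)
#' @export
derivative <- function(state, params, s_mode = c("constant", "dynamic"),
                       neg_tol = 1e-10) {
  stopifnot(inherits(state, "system_state"))
  params <- validate_params(params)
  s_mode <- match.arg(s_mode)
  if (length(state$A) != params$N) {
    stop("state has ", length(state$A), " aggregate sizes but params$N = ",
         params$N, call. = FALSE)
  }
  y <- c(state$C, state$S, state$A)
  if (any(y < -neg_tol)) {
    stop("negative concentration beyond tolerance", call. = FALSE)
  }
  y[y < 0] <- 0
  tab <- build_rate_tables(params$kernel, params$N)
  d <- rhs_cpp(y[1], y[2], y[-(1:2)], params$kp1, params$kn1,
               tab$kp, tab$kn, s_mode == "dynamic")
  structure(list(dC = d[1], dS = d[2], dA = d[-(1:2)]),
            class = "state_derivative")
}
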