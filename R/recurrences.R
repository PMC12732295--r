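# Catalan-like integer sequences connected to the cascade equations. All
# sequence arithmetic is exact (arbitrary-precision integers, computed in
# compiled code); terms are returned as decimal strings so that no precision
# is lost for large indices.

#' Motzkin numbers
#'
#' Exact Motzkin numbers from the convolution recurrence
#' `M_i = M_{i-1} + sum_{k=1}^{i-2} M_k M_{i-1-k}` with `M_1 = M_2 = 1`
#' (1-based indexing): 1, 1, 2, 4, 9, 21, 51, ... This is the recurrence the
#' rescaled cascade obeys when C3 merging is switched off (`c3 = 0`).
#'
#' @param n_terms Number of terms (`>= 1`).
#' @return Character vector of exact decimal integers, class `rda_intseq`.
#' @examples
#' motzkin(7)
#' @export
motzkin <- function(n_terms) {
  structure(.seq_k3_cpp(as.integer(n_terms), 0L),
            class = "rda_intseq", sequence = "motzkin")
}

#' Generalized Motzkin-type sequence for coordination number 3 (A036765)
#'
#' Exact terms of the recurrence carrying both the pairwise and the
#' three-fold convolution of the cascade:
#' `M_i = M_{i-1} + sum_k M_k M_{i-1-k}
#'  + a3 * sum_{k,l} M_k M_l M_{i-k-l-1}`
#' with `M_1 = M_2 = 1` (so `M_3 = M_2 + M_1^2 = 2`). With unit triple
#' coefficient (`triple_coefficient = 1`) this is OEIS A036765:
#' 1, 1, 2, 5, 13, 36, 104, ... — the number of ordered rooted trees with
#' all outdegrees at most 3. With `triple_coefficient = 0` it reduces
#' exactly to the Motzkin numbers.
#'
#' @param n_terms Number of terms (`>= 1`).
#' @param triple_coefficient Integer coefficient (0 or 1) of the three-fold
#'   convolution term.
#' @return Character vector of exact decimal integers, class `rda_intseq`.
#' @examples
#' generalized_k3(13)
#' @export
generalized_k3 <- function(n_terms, triple_coefficient = 1L) {
  stopifnot(triple_coefficient %in% c(0L, 1L))
  structure(.seq_k3_cpp(as.integer(n_terms), as.integer(triple_coefficient)),
            class = "rda_intseq",
            sequence = if (triple_coefficient == 1L) "A036765" else "motzkin")
}

#' @export
print.rda_intseq <- function(x, ...) {
  cat(attr(x, "sequence"), "sequence,", length(x), "terms:\n")
  print(unclass(x))
  invisible(x)
}

#' Base-10 logarithm of exact integer terms
#'
#' Helper for asymptotics: `log10` of the decimal-string terms without loss
#' for values beyond double precision.
#'
#' @param x Character vector of decimal integers (e.g. from [motzkin()]).
#' @return Numeric vector of `log10` values.
#' @export
intseq_log10 <- function(x) {
  vapply(unclass(x), function(s) {
    nd <- nchar(s)
    head <- as.numeric(substr(s, 1, min(nd, 15)))
    log10(head) + (nd - min(nd, 15))
  }, numeric(1), USE.NAMES = FALSE)
}

#' Rescale a cascade distribution to its Catalan-like sequence
#'
#' For a solved state under the `delta` law, the substitution
#' `n_i / n = (c1 x1 / c2 x2) * r^i * M_i` with
#' `r = c1 x1 / ((delta + Y) n)` turns the cascade equations into an integer-
#' type convolution recurrence: for `c3 = 0` the Motzkin form
#' `M_i = M_{i-1} + sum M_k M_{i-1-k}` with
#' `M_1 = M_2 = a2 = (c0 x0)(c2 x2)/(c1 x1)^2`, and for `c3 != 0` the
#' generalized form whose three-fold convolution carries the coefficient
#' `a3 = (c1 x1)(c3 x3)/(c2 x2)^2`. The returned `M` values are computed
#' from the cascade output and the recurrence residuals are evaluated
#' (verified, not assumed).
#'
#' @param state An `rda_steady_state` solved under the `delta` law with
#'   `c2 > 0`.
#' @param n_terms Number of rescaled terms.
#' @return Object of class `rda_scaled_seq`: list with `M`, coefficients
#'   `a2`, `a3`, ratio `r`, and `recurrence_residual` (max relative residual
#'   of the applicable recurrence over `3 <= i <= n_terms`).
#' @export
rescale_cascade <- function(state, n_terms = 200) {
  params <- state$params
  if (!.is_special_law(params))
    stop("rescaling is defined for the law mu_i = delta / i")
  cc <- params$c
  N <- state$N
  u <- cc * c(state$x0, state$x1, state$x2, state$x3) / N  # c_i x_i per cell
  if (u[3] <= 0) stop("rescaling requires c2 x2 > 0")
  n <- state$n / N
  d <- params$delta
  Y <- state$Y
  dist <- cascade(state, imax = n_terms, early_stop = FALSE)
  g <- dist$ni / state$n
  r <- u[2] / ((d + Y) * n)
  M <- g / ((u[2] / u[3]) * r^seq_len(n_terms))
  a2 <- u[1] * u[3] / u[2]^2
  a3 <- u[2] * u[4] / u[3]^2
  # verify the recurrence term by term; A[m] = sum_{j=1}^{m-1} M_j M_{m-j}
  A <- numeric(n_terms)
  for (m in 2:n_terms) A[m] <- sum(M[1:(m - 1)] * M[(m - 1):1])
  res <- 0
  for (i in 3:n_terms) {
    pred <- M[i - 1] + A[i - 1]
    if (cc[4] != 0 && i >= 4)
      pred <- pred + a3 * sum(M[1:(i - 3)] * A[(i - 2):2])
    res <- max(res, abs(M[i] - pred) / max(abs(M[i]), 1e-300))
  }
  structure(list(M = M, a2 = a2, a3 = a3, r = r,
                 recurrence_residual = res),
            class = "rda_scaled_seq")
}

#' Bookkeeping of the inverse-power scaling limits
#'
#' Works out, from the model identities, what imposing the integer-sequence
#' initial conditions `M_1 = M_2 = 1` together with exact compensation of the
#' sequence's exponential growth would require of a stationary state.
#'
#' For `type = "motzkin"` (`c3 = 0`, growth ratio 3, so
#' `c1 x1 / ((delta + Y) n) = 1/3`): the constraints give
#' `c0 x0 + c2 x2 = 2 c1 x1` (from the growth condition and the cluster
#' balance) and `(c0 x0)(c2 x2) = (c1 x1)^2` (from `M_1 = 1`) — arithmetic
#' and geometric mean equal — hence `c0 x0 = c1 x1 = c2 x2 = delta rho N / 3`
#' and, by the cluster-count balance, `delta n = 0`: the strict inverse-power
#' state is the `n -> 0` boundary of the window.
#'
#' For `type = "a036765"` (unit triple coefficient) the analogous conditions
#' force `c0 x0 = c1 x1 = c2 x2 = c3 x3 = delta rho N / 4`, and the
#' cluster-count balance then gives `delta n = -delta rho N / 2 < 0`, which
#' no state can satisfy: an error `"unreachable initial condition"` is
#' signalled.
#'
#' @param type `"motzkin"` or `"a036765"`.
#' @param delta_rhoN The product `delta * rho * N` setting the overall scale
#'   (any positive number; the relations are homogeneous).
#' @return For `"motzkin"`, a list with the forced values `c0x0`, `c1x1`,
#'   `c2x2` and `delta_n` (always 0).
#' @export
scaling_limit <- function(type = c("motzkin", "a036765"), delta_rhoN = 1) {
  type <- match.arg(type)
  stopifnot(delta_rhoN > 0)
  if (type == "motzkin") {
    # u0 + u2 = 2 u1 and u0 u2 = u1^2  =>  (u0 - u2)^2 = (u0+u2)^2 - 4 u0 u2 = 0
    u1 <- delta_rhoN / 3
    disc <- (2 * u1)^2 - 4 * u1^2          # = 0: double root u0 = u2 = u1
    u0 <- (2 * u1 + sqrt(max(disc, 0))) / 2
    u2 <- 2 * u1 - u0
    list(c0x0 = u0, c1x1 = u1, c2x2 = u2, delta_n = u0 - u2)
  } else {
    u <- rep(delta_rhoN / 4, 4)
    delta_n <- u[1] - u[3] - 2 * u[4]      # cluster-count balance
    stopifnot(delta_n < 0)
    stop(structure(
      class = c("rda_unreachable", "error", "condition"),
      list(message = paste0(
        "unreachable initial condition: M1 = M2 = 1 with unit triple ",
        "coefficient would require delta n = ", delta_n * 4 / delta_rhoN,
        " * delta rho N / 4 < 0"), call = sys.call(-1))))
  }
}
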