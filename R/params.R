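#' Model parameters for the Random Domino Automaton on the Bethe lattice
#'
#' Bundles the occupation probabilities of the four empty-cell types together
#' with the avalanche law and the reference system size. An empty cell with
#' `t` occupied neighbours (t = 0..3 on the 3-regular lattice) becomes
#' occupied, when selected, with probability `c_t`; an occupied cell belonging
#' to a cluster of size `i` triggers the removal of the whole cluster with
#' probability `mu_i`. The solvable avalanche law is `mu_i = delta / i`,
#' which makes the removal probability of a cluster independent of its size.
#'
#' A necessary condition for a stationary state is `c0 > min(c2, c3)`:
#' otherwise merging removes clusters faster than creation at size 1 can
#' replace them and the cluster count decays.
#'
#' @param c0,c1,c2,c3 Occupation probabilities in `[0, 1]` for creating,
#'   enlarging, C2-merging and C3-merging cells respectively.
#' @param delta Avalanche parameter in `(0, 1)` for the size-independent
#'   cluster-removal law `mu_i = delta / i`. Exactly one of `delta` and `mu`
#'   must be supplied.
#' @param mu General avalanche law: a function of the cluster size `i`
#'   returning the trigger probability `mu_i` in `[0, 1]`.
#' @param N Reference system size (number of cells) used when reporting
#'   counts; the solver itself works per cell and is invariant under `N`.
#' @param k Coordination number of the Bethe lattice. Only `k = 3` is
#'   supported.
#' @return An object of class `rda_params`.
#' @examples
#' p <- rda_params(1, 0.5, 0.25, 0.125, delta = 0.28)
#' p
#' @export
rda_params <- function(c0, c1, c2, c3, delta = NULL, mu = NULL,
                       N = 1e6, k = 3) {
  ci <- c(c0 = c0, c1 = c1, c2 = c2, c3 = c3)
  if (anyNA(ci) || any(ci < 0) || any(ci > 1))
    stop("all occupation probabilities c0..c3 must lie in [0, 1]")
  if (k != 3)
    stop("only coordination number k = 3 is supported")
  if (!(c0 > min(c2, c3)))
    stop("inadmissible parameters: c0 > min(c2, c3) is required for a ",
         "stationary state")
  if (is.null(delta) == is.null(mu))
    stop("supply exactly one of `delta` (law mu_i = delta/i) or `mu`")
  if (!is.null(delta)) {
    if (!is.numeric(delta) || length(delta) != 1L || delta <= 0 || delta >= 1)
      stop("`delta` must be a single number in (0, 1)")
  } else {
    if (!is.function(mu))
      stop("`mu` must be a function of the cluster size i")
    probe <- vapply(1:8, mu, numeric(1))
    if (any(probe < 0) || any(probe > 1))
      stop("`mu(i)` must return probabilities in [0, 1]")
  }
  if (!is.numeric(N) || N <= 0) stop("`N` must be positive")
  structure(
    list(c = unname(ci), delta = delta, mu = mu, N = N, k = 3L),
    class = "rda_params")
}

#' @export
print.rda_params <- function(x, ...) {
  cat("Random Domino Automaton parameters (Bethe lattice, k = 3)\n")
  cat(sprintf("  c = (%s)   [creating, enlarging, C2, C3]\n",
              paste(format(x$c), collapse = ", ")))
  if (!is.null(x$delta))
    cat(sprintf("  avalanche law: mu_i = delta / i, delta = %g\n", x$delta))
  else
    cat("  avalanche law: general mu(i)\n")
  cat(sprintf("  reference size N = %g\n", x$N))
  invisible(x)
}

#' Evaluate the avalanche law
#'
#' Returns `mu_i` for the sizes `i`, either `delta / i` or the user-supplied
#' general law.
#'
#' @param params An [rda_params] object.
#' @param i Vector of cluster sizes (positive integers).
#' @return Numeric vector of trigger probabilities.
#' @export
avalanche_mu <- function(params, i) {
  stopifnot(inherits(params, "rda_params"), all(i >= 1))
  if (!is.null(params$delta)) params$delta / i
  else vapply(i, params$mu, numeric(1))
}

.is_special_law <- function(params) !is.null(params$delta)
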