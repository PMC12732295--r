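#' Perimeter of a cluster on the Bethe lattice
#'
#' A connected set of `i` cells on the Bethe lattice of coordination number
#' `k` is adjacent to exactly `i (k - 2) + 2` cells outside the set (proof by
#' induction on `i`: a single cell has `k` neighbours and attaching one more
#' cell consumes one perimeter site while adding `k - 1`). For `k = 3` the
#' perimeter is `i + 2`.
#'
#' @param i Cluster size(s), positive integers.
#' @param k Coordination number, `k >= 2`.
#' @return Integer vector of perimeter sizes.
#' @examples
#' bethe_perimeter(1, 3)  # 3
#' bethe_perimeter(7, 3)  # 9
#' @export
bethe_perimeter <- function(i, k = 3) {
  if (any(i < 1) || any(i != round(i))) stop("cluster size i must be a positive integer")
  if (any(k < 2)) stop("coordination number k must be >= 2")
  i * (k - 2) + 2
}

#' Cell-type composition of an empty cluster
#'
#' On the 3-regular Bethe lattice the shape of an empty cluster is determined,
#' up to the counts that matter for the dynamics, by its size `i` and its
#' number of creating cells `j` (empty cells all of whose neighbours are
#' empty). For `i >= 2` the cluster then contains exactly `j + 2` merging
#' cells of C2-type, `i - 2j - 2` enlarging cells, and no C3 cells; `j`
#' ranges from 0 to `floor(i/2) - 1`. The single cell of an empty 1-cluster
#' is of C3-type (all three neighbours occupied).
#'
#' @param i Empty-cluster size, `i >= 1`.
#' @param j Number of creating cells, `0 <= j <= floor(i/2) - 1` (must be 0
#'   for `i = 1`).
#' @return A list of class `rda_composition` with fields `i`, `j`,
#'   `n_creating`, `n_enlarging`, `n_C2`, `n_C3`.
#' @examples
#' empty_cluster_composition(7, 0)  # 2 C2 cells, 5 enlarging
#' @export
empty_cluster_composition <- function(i, j) {
  if (length(i) != 1L || length(j) != 1L || i != round(i) || j != round(j))
    stop("i and j must be single integers")
  if (i < 1) stop("empty-cluster size i must be >= 1")
  if (i == 1) {
    if (j != 0) stop("an empty 1-cluster has no creating cell (j must be 0)")
    out <- list(i = 1L, j = 0L, n_creating = 0L, n_enlarging = 0L,
                n_C2 = 0L, n_C3 = 1L)
  } else {
    if (j < 0 || j > floor(i / 2) - 1)
      stop(sprintf("for i = %d, j must lie in [0, %d]", i, floor(i / 2) - 1))
    out <- list(i = as.integer(i), j = as.integer(j),
                n_creating = as.integer(j),
                n_enlarging = as.integer(i - 2 * j - 2),
                n_C2 = as.integer(j + 2), n_C3 = 0L)
  }
  class(out) <- "rda_composition"
  out
}

#' @export
print.rda_composition <- function(x, ...) {
  cat(sprintf(
    "empty %d-cluster with %d creating cell(s): %d enlarging, %d C2, %d C3\n",
    x$i, x$j, x$n_enlarging, x$n_C2, x$n_C3))
  invisible(x)
}

#' Aggregate quantities from the empty-cell counts
#'
#' Converts the four empty-cell counts by type, `x0..x3`, into the aggregate
#' description of the state: density `rho = 1 - sum(x)/N`, number of empty
#' clusters `n0 = (x2 + 2 x3 - x0) / 2`, number of size-1 empty clusters
#' `n1_0 = x3`, and number of creating cells `nhat0 = x0`. The pair of
#' variable sets `{x0..x3}` and `{rho, n0, n1_0, nhat0}` is a change of
#' variables (see [x_from_aggregates()] for the inverse).
#'
#' A state is admissible only if `x2 > x0` (equivalently `n0 > n1_0`);
#' otherwise an error of class `rda_inadmissible` is signalled.
#'
#' @param x0,x1,x2,x3 Counts of creating, enlarging, C2 and C3 cells.
#' @param N System size (same scale as the counts).
#' @return List with `rho`, `n0`, `n1_0`, `nhat0`.
#' @export
aggregates_from_x <- function(x0, x1, x2, x3, N) {
  x <- c(x0, x1, x2, x3)
  if (any(x < 0)) stop("empty-cell counts must be nonnegative")
  if (sum(x) > N + 1e-9 * N) stop("empty-cell counts exceed system size N")
  rho <- 1 - sum(x) / N
  all_empty_singletons <- (x0 == 0 && x1 == 0 && x2 == 0)
  if (!(x2 > x0) && !all_empty_singletons && sum(x) > 0)
    stop(structure(
      class = c("rda_inadmissible", "error", "condition"),
      list(message = "no admissible state: x2 > x0 is violated (n0 <= n1_0)",
           call = sys.call(-1))))
  list(rho = rho, n0 = (x2 + 2 * x3 - x0) / 2, n1_0 = x3, nhat0 = x0)
}

#' Empty-cell counts from aggregate quantities
#'
#' Inverse of [aggregates_from_x()]: reconstructs the per-type empty-cell
#' counts from `{rho, n0, n1_0, nhat0}` via `x0 = nhat0`, `x3 = n1_0`,
#' `x2 = nhat0 + 2 n0 - 2 n1_0`, `x1 = (1 - rho) N - 2 nhat0 - 2 n0 + n1_0`.
#'
#' @param rho Density in `[0, 1]`.
#' @param n0 Number of empty clusters.
#' @param n1_0 Number of empty clusters of size 1.
#' @param nhat0 Number of creating cells.
#' @param N System size.
#' @return Numeric vector `c(x0, x1, x2, x3)`.
#' @export
x_from_aggregates <- function(rho, n0, n1_0, nhat0, N) {
  c(x0 = nhat0,
    x1 = (1 - rho) * N - 2 * nhat0 - 2 * n0 + n1_0,
    x2 = nhat0 + 2 * n0 - 2 * n1_0,
    x3 = n1_0)
}

#' Mean empty-cluster sizes
#'
#' Computes the mean empty-cluster size `<i0> = (1 - rho) N / n0` and the
#' mean over clusters of size at least 2,
#' `<i0>_{2+} = (<i0> n0 - n1_0) / (n0 - n1_0)`.
#'
#' @param state An `rda_steady_state` object (see [rda_solve()]), or `NULL`
#'   if the scalar arguments are given directly.
#' @param rho,n0,n1_0,N Scalars, used when `state` is `NULL`.
#' @return List with `mean_i0` and `mean_i0_2plus` (`NA` with a warning when
#'   all empty clusters have size 1, i.e. `n0 == n1_0`).
#' @export
empty_cluster_means <- function(state = NULL, rho = NULL, n0 = NULL,
                                n1_0 = NULL, N = NULL) {
  if (!is.null(state)) {
    stopifnot(inherits(state, "rda_steady_state"))
    rho <- state$rho; n0 <- state$n0; n1_0 <- state$n1_0; N <- state$N
  }
  if (n0 <= 0) stop("n0 must be positive")
  mean_i0 <- (1 - rho) * N / n0
  if (n0 <= n1_0) {
    warning("all empty clusters of size 1: <i0>_{2+} undefined")
    mean_i0_2plus <- NA_real_
  } else {
    mean_i0_2plus <- (mean_i0 * n0 - n1_0) / (n0 - n1_0)
  }
  list(mean_i0 = mean_i0, mean_i0_2plus = mean_i0_2plus)
}
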