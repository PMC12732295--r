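# Cascade recursion for the cluster-size distribution. Internally the arrays
# store g_i = n_i / n, which keeps the numbers O(1); counts are rescaled on
# output. The pair convolution A_m = sum_{k} g_k g_{m-k} is cached so that the
# triple sum B_m = sum_k g_k A_{m-k} costs O(m) per term and the whole cascade
# O(imax^2).

#' Cluster-size distribution from the cascade equations
#'
#' Computes the stationary distribution `n_i` of cluster sizes from the
#' triangular cascade system: `n_1 (mu_1 + Y) = c0 x0`, and for `i >= 2`
#' `n_i (i mu_i + Y) = c1 x1 g_{i-1} + c2 x2 sum_k g_k g_{i-k-1}
#'  + c3 x3 sum_{k,l} g_k g_l g_{i-k-l-1}` with `g_i = n_i / n` and the
#' merging rate `Y = (c1 x1 + 2 c2 x2 + 3 c3 x3) / n`. Each `n_i` depends
#' only on smaller sizes, so the system is evaluated in increasing `i`.
#'
#' @param state An `rda_steady_state` from [rda_solve()] (or a compatible
#'   list with `x0..x3`, `n`, `rho`, `N` and `params`).
#' @param imax Truncation size (`>= 4`).
#' @param mu Optional avalanche-law override: a function of `i`; defaults to
#'   the law stored in `state$params`.
#' @param early_stop Stop once `i * n_i < 1e-12 * rho * N` (the tail no
#'   longer contributes mass at double precision).
#' @return Object of class `rda_cluster_dist`: list with `i`, `ni` (counts
#'   per `N` cells), `imax` (effective truncation), `captured_mass`
#'   (`sum i n_i / (rho N)`), `captured_count` (`sum n_i / n`) and `Y`.
#' @examples
#' st <- rda_solve(rda_params(1, 0.5, 0.25, 0.125, delta = 0.28))
#' d <- cascade(st, imax = 1000)
#' d$captured_mass
#' @export
cascade <- function(state, imax = 1e4, mu = NULL, early_stop = TRUE) {
  params <- state$params
  stopifnot(inherits(params, "rda_params"), imax >= 4)
  imax <- as.integer(imax)
  if (is.null(mu)) {
    imui <- if (.is_special_law(params)) rep(params$delta, imax)
            else seq_len(imax) * vapply(seq_len(imax), params$mu, numeric(1))
  } else {
    imui <- seq_len(imax) * vapply(seq_len(imax), mu, numeric(1))
  }
  N <- state$N
  x <- c(state$x0, state$x1, state$x2, state$x3) / N
  n <- state$n / N
  if (n <= 0) stop("state must have n > 0")
  cc <- params$c
  Y <- (cc[2] * x[2] + 2 * cc[3] * x[3] + 3 * cc[4] * x[4]) / n
  u1 <- cc[2] * x[2] / n; u2 <- cc[3] * x[3] / n; u3 <- cc[4] * x[4] / n
  den <- imui + Y
  if (any(den == 0)) stop("i * mu_i + Y vanishes: cascade undefined")

  g <- numeric(imax)                 # g_i = n_i / n
  A <- numeric(imax)                 # A_m = sum_{k=1}^{m-1} g_k g_{m-k}
  g[1] <- cc[1] * x[1] / (den[1] * n)
  last <- imax
  thresh <- 1e-12 * state$rho / n    # on i * g_i
  for (i in 2:imax) {
    A[i - 1] <- if (i >= 3) sum(g[1:(i - 2)] * g[(i - 2):1]) else 0
    s3 <- if (i >= 4) sum(g[1:(i - 3)] * A[(i - 2):2]) else 0
    g[i] <- (u1 * g[i - 1] + u2 * A[i - 1] + u3 * s3) / den[i]
    if (early_stop && i * g[i] < thresh) { last <- i; break }
  }
  g <- g[seq_len(last)]
  ii <- seq_len(last)
  structure(list(
    i = ii, ni = g * n * N, imax = last,
    captured_mass = sum(ii * g) * n / state$rho,
    captured_count = sum(g),
    Y = Y, N = N), class = "rda_cluster_dist")
}

#' @export
print.rda_cluster_dist <- function(x, ...) {
  cat(sprintf(
    "cluster-size distribution, i = 1..%d: mass captured %.4f, count %.4f\n",
    x$imax, x$captured_mass, x$captured_count))
  invisible(x)
}

#' Mean cluster size
#'
#' Two values are reported: the exact mean `rho N / n` implied by the solved
#' state (equivalently `Y / delta + 1` under the `delta` law), and the mean
#' of the truncated cascade distribution `sum i n_i / sum n_i`, which is
#' smaller whenever the truncation discards tail mass. They are returned
#' under explicit labels and are not interchangeable.
#'
#' @param state An `rda_steady_state`.
#' @param dist Optional `rda_cluster_dist` for the truncated mean.
#' @return List with `exact` and (when `dist` is given) `truncated`.
#' @export
mean_cluster_size <- function(state, dist = NULL) {
  if (state$n <= 0) stop("n must be positive")
  out <- list(exact = state$rho * state$N / state$n)
  if (!is.null(dist))
    out$truncated <- sum(dist$i * dist$ni) / sum(dist$ni)
  out
}

#' Invert the cascade for the avalanche law
#'
#' Given a target distribution `n_i` and the aggregate quantities of a state
#' (`x0..x3`, `n`, hence `Y`), each cascade equation can be solved for
#' `i mu_i`:
#' `i mu_i = (c1 x1 g_{i-1} + c2 x2 A_{i-1} + c3 x3 B_{i-1}) / g_i - Y`
#' (with the `c0 x0` numerator at `i = 1`), yielding the unique avalanche law
#' that reproduces the target. Entries with implied `mu_i` outside `[0, 1]`
#' are flagged: the target is not realizable there.
#'
#' @param target_ni Positive numeric vector of target counts `n_1..n_imax`
#'   (per `N` cells, same scale as `state`).
#' @param state An `rda_steady_state` (or compatible list).
#' @return List with `mu` (numeric vector) and `realizable` (logical vector,
#'   `FALSE` where the implied `mu_i` falls outside `[0, 1]`).
#' @export
invert_for_mu <- function(target_ni, state) {
  params <- state$params
  stopifnot(all(target_ni > 0))
  imax <- length(target_ni)
  N <- state$N
  x <- c(state$x0, state$x1, state$x2, state$x3) / N
  n <- state$n / N
  cc <- params$c
  Y <- (cc[2] * x[2] + 2 * cc[3] * x[3] + 3 * cc[4] * x[4]) / n
  g <- target_ni / (n * N)
  mu <- numeric(imax)
  mu[1] <- cc[1] * x[1] / (n * g[1]) - Y
  A <- numeric(imax)
  for (i in 2:imax) {
    A[i - 1] <- if (i >= 3) sum(g[1:(i - 2)] * g[(i - 2):1]) else 0
    s3 <- if (i >= 4) sum(g[1:(i - 3)] * A[(i - 2):2]) else 0
    imui <- (cc[2] * x[2] * g[i - 1] + cc[3] * x[3] * A[i - 1] +
               cc[4] * x[4] * s3) / (n * g[i]) - Y
    mu[i] <- imui / i
  }
  list(mu = mu, realizable = mu >= 0 & mu <= 1)
}

#' Log-log tail slope of a distribution
#'
#' Least-squares slope of `log n_i` against `log i` on the index range
#' `[i_lo, i_hi]`; the standard estimate of a power-law exponent on the
#' straight section of a log-log plot.
#'
#' @param dist An `rda_cluster_dist` or a list with `i` and `ni`.
#' @param i_lo,i_hi Index range, `i_hi > i_lo >= 2`, at least 3 points.
#' @return The fitted slope (a negative number for a decaying tail).
#' @export
tail_slope <- function(dist, i_lo, i_hi) {
  if (!(i_hi > i_lo && i_lo >= 2)) stop("need i_hi > i_lo >= 2")
  sel <- dist$i >= i_lo & dist$i <= i_hi
  if (sum(sel) < 3) stop("fewer than 3 points in the range")
  if (any(dist$ni[sel] <= 0)) stop("distribution must be positive on range")
  unname(stats::coef(stats::lm(log(dist$ni[sel]) ~ log(dist$i[sel])))[2])
}
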