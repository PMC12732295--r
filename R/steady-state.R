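# Steady-state machinery. Everything internal works per cell (N = 1): the
# unknowns are nu = n/N and rho, and the empty-cell counts x0..x3 are per-cell
# fractions. Counts at the user's reference scale N are produced only when the
# state object is assembled.

# --- linear elimination -----------------------------------------------------
#
# For the solvable law mu_i = delta/i the six balance equations reduce, for
# fixed (nu, rho), to a 4x4 *linear* system for x = (x0, x1, x2, x3):
#   (i)   sum(x)                    = 1 - rho
#   (ii)  sum(c * x)                = delta rho
#   (iii) c0 x0 - c2 x2 - 2 c3 x3   = delta nu
#   (iv)  6 c0 x0 + (4 c1 - 2 delta) x1 + (c2 - 6 delta) x2
#           - (11 c3 + 18 delta) x3 = 0
# Row (iv) is the T-elimination row: it comes from substituting the three
# T-product identities 3Tx0 = delta rho + delta x1 - c0 x0,
# 2Tx1 = (c2 + 2 delta) x2 + c3 x3 and Tx2 = (3 delta + c3) x3 into the
# definition T (x0+x1+x2) = c0 x0 + c1 x1 + c2 x2 and eliminating
# delta rho via (ii). Hence each x_i is affine in (nu, rho).

.x_matrix <- function(params) {
  cc <- params$c; d <- params$delta
  rbind(c(1, 1, 1, 1),
        cc,
        c(cc[1], 0, -cc[3], -2 * cc[4]),
        c(6 * cc[1], 4 * cc[2] - 2 * d, cc[3] - 6 * d, -(11 * cc[4] + 18 * d)))
}

# 4x3 matrix: row i gives the affine coefficients (const, nu, rho) of x_{i-1}
.x_affine <- function(params) {
  d <- params$delta
  rhs <- cbind(const = c(1, 0, 0, 0), nu = c(0, 0, d, 0), rho = c(-1, d, 0, 0))
  sol <- solve(.x_matrix(params), rhs)
  dimnames(sol) <- list(c("x0", "x1", "x2", "x3"), c("const", "n", "rho"))
  sol
}

.x_at <- function(xaff, nu, rho) as.numeric(xaff %*% c(1, nu, rho))

# product of two affine forms (const, n, rho) -> quadratic
# (1, n, rho, nn, nrho, rhorho)
.aff_prod <- function(a, b) {
  c(`1`      = a[1] * b[1],
    n        = a[1] * b[2] + a[2] * b[1],
    rho      = a[1] * b[3] + a[3] * b[1],
    nn       = a[2] * b[2],
    nrho     = a[2] * b[3] + a[3] * b[2],
    rhorho   = a[3] * b[3])
}

#' Conic pair of the elimination-based solver
#'
#' After the linear elimination, the two remaining balance relations
#' (the creating-cell and enlarging-cell equations, with `T` taken from the
#' C3 equation `T x2 = (3 delta + c3) x3` and multiplied through by `x2`)
#' are two quadratics ("ellipses") in the unknowns `(n, rho)`:
#' `p_nn n^2 + p_nrho n rho + p_rhorho rho^2 + p_n n + p_rho rho + p_1 = 0`
#' and likewise with `q`. The admissibility half-plane `x2 - x0 > 0` is the
#' affine condition `s_n n + s_rho rho + s_1 > 0`. All coefficients depend on
#' the parameters `c0..c3` and `delta` only; `n` here is per cell (`n / N`).
#'
#' @param params An [rda_params] object with the `delta` law.
#' @return Object of class `rda_conic_pair`: list with numeric vectors `p`,
#'   `q` (named `1, n, rho, nn, nrho, rhorho`) and `s` (named `1, n, rho`).
#' @export
conic_pair <- function(params) {
  stopifnot(inherits(params, "rda_params"))
  if (!.is_special_law(params))
    stop("the elimination-based solver requires the law mu_i = delta / i")
  cc <- params$c; d <- params$delta
  xa <- .x_affine(params)
  x0 <- xa[1, ]; x1 <- xa[2, ]; x2 <- xa[3, ]; x3 <- xa[4, ]
  drho <- c(0, 0, d)                      # affine form of delta * rho
  tq <- 3 * d + cc[4]                     # T x2 = tq * x3 at the solution
  p <- 3 * tq * .aff_prod(x3, x0) -
    .aff_prod(x2, drho + d * x1 - cc[1] * x0)
  q <- 2 * tq * .aff_prod(x3, x1) -
    .aff_prod(x2, (cc[3] + 2 * d) * x2 + cc[4] * x3)
  s <- x2 - x0
  names(s) <- c("1", "n", "rho")
  structure(list(p = p, q = q, s = s, params = params),
            class = "rda_conic_pair")
}

.quad_eval <- function(co, nu, rho)
  co[1] + co[2] * nu + co[3] * rho + co[4] * nu^2 + co[5] * nu * rho +
    co[6] * rho^2

.quad_grad <- function(co, nu, rho)
  c(co[2] + 2 * co[4] * nu + co[5] * rho,
    co[3] + co[5] * nu + 2 * co[6] * rho)

# Newton iteration for the intersection of the two conics; returns NULL when
# it fails to converge to a genuine root.
.newton_conics <- function(cp, start, tol = 1e-14, maxit = 200) {
  z <- start
  for (it in seq_len(maxit)) {
    f <- c(.quad_eval(cp$p, z[1], z[2]), .quad_eval(cp$q, z[1], z[2]))
    J <- rbind(.quad_grad(cp$p, z[1], z[2]), .quad_grad(cp$q, z[1], z[2]))
    dz <- tryCatch(solve(J, f), error = function(e) NULL)
    if (is.null(dz)) return(NULL)
    z <- z - dz
    if (sum(abs(dz)) < tol) break
  }
  scale <- max(abs(unlist(cp[c("p", "q")]))) # residual tolerance, coef scale
  f <- c(.quad_eval(cp$p, z[1], z[2]), .quad_eval(cp$q, z[1], z[2]))
  if (max(abs(f)) > 1e-10 * max(scale, 1)) NULL else z
}

# all distinct conic intersections found from a multistart grid
.all_intersections <- function(cp, nu_grid = seq(-0.05, 0.35, length.out = 9),
                               rho_grid = seq(0.05, 0.95, length.out = 9)) {
  roots <- list()
  for (nu0 in nu_grid) for (rho0 in rho_grid) {
    z <- .newton_conics(cp, c(nu0, rho0))
    if (is.null(z)) next
    if (!any(vapply(roots, function(r) sum(abs(r - z)) < 1e-8, logical(1))))
      roots[[length(roots) + 1L]] <- z
  }
  roots
}

# --- state assembly and admissibility --------------------------------------

.make_state <- function(params, nu, rho, xaff = NULL) {
  nu <- unname(nu); rho <- unname(rho)
  if (is.null(xaff)) xaff <- .x_affine(params)
  x <- .x_at(xaff, nu, rho)
  cc <- params$c; N <- params$N
  Tv <- (cc[1] * x[1] + cc[2] * x[2] + cc[3] * x[3]) / (x[1] + x[2] + x[3])
  Y <- if (nu > 0) (cc[2] * x[2] + 2 * cc[3] * x[3] + 3 * cc[4] * x[4]) / nu
       else NA_real_
  structure(list(
    rho = rho, n = nu * N,
    n0 = (x[3] + 2 * x[4] - x[1]) / 2 * N,
    n1_0 = x[4] * N, nhat0 = x[1] * N,
    x0 = x[1] * N, x1 = x[2] * N, x2 = x[3] * N, x3 = x[4] * N,
    T = Tv, Y = Y, N = N, params = params),
    class = "rda_steady_state")
}

# admissibility of a per-cell root (nu, rho) given the x affine map
.admissibility <- function(params, nu, rho, xaff) {
  x <- .x_at(xaff, nu, rho)
  d <- params$delta
  Tv <- (3 * d + params$c[4]) * x[4] / x[3]
  fails <- character(0)
  if (!(nu > 1e-12)) fails <- c(fails, "n <= 0 branch")
  if (!(rho > 0 && rho < 1)) fails <- c(fails, "rho outside (0, 1)")
  if (!all(x > -1e-13)) fails <- c(fails, "negative empty-cell count")
  if (!(x[3] > x[1])) fails <- c(fails, "x2 <= x0 (condition (47))")
  if (!(Tv > 0 && Tv < 1)) fails <- c(fails, "T outside (0, 1)")
  if (!(rho < 1 / (1 + d))) fails <- c(fails, "rho >= 1/(1+delta)")
  fails
}

#' Solve the steady state for the solvable avalanche law
#'
#' Finds the unique physically admissible stationary state of the automaton
#' for the law `mu_i = delta / i` by the elimination procedure: the
#' empty-cell counts are solved from a 4x4 linear system as affine functions
#' of `(n, rho)`, the two remaining balance equations become two conics in
#' `(n, rho)`, and their intersections are located by multistart Newton and
#' filtered by admissibility (`n > 0`, `0 < rho < 1`, all `x_i >= 0`,
#' `x2 > x0`, `T` in `(0, 1)`, `rho < 1/(1 + delta)`).
#'
#' @param params An [rda_params] object using the `delta` law.
#' @return An object of class `rda_steady_state` with fields `rho`, `n`,
#'   `n0`, `n1_0`, `nhat0`, `x0..x3`, `T`, `Y` (counts at scale `params$N`).
#'   Signals an error of class `rda_no_stationary_state`, naming the failed
#'   admissibility test, when no admissible intersection exists.
#' @examples
#' st <- rda_solve(rda_params(1, 0.5, 0.5, 0.5, delta = 0.4))
#' st$rho
#' @export
rda_solve <- function(params) {
  cp <- conic_pair(params)
  xaff <- .x_affine(params)
  roots <- .all_intersections(cp)
  adm <- Filter(function(z)
    length(.admissibility(params, z[1], z[2], xaff)) == 0L, roots)
  if (length(adm) == 1L)
    return(.make_state(params, adm[[1]][1], adm[[1]][2], xaff))
  if (length(adm) > 1L) {
    warning("multiple admissible roots found; returning the one with ",
            "largest n (uniqueness is expected to hold)")
    nu <- vapply(adm, `[`, numeric(1), 1)
    z <- adm[[which.max(nu)]]
    return(.make_state(params, z[1], z[2], xaff))
  }
  # no admissible root: name the most informative failure
  fails <- lapply(roots, function(z) .admissibility(params, z[1], z[2], xaff))
  nf <- vapply(fails, length, integer(1))
  reason <- if (length(roots) == 0L) "no conic intersection found"
            else fails[[which.min(nf)]][1]
  stop(structure(
    class = c("rda_no_stationary_state", "error", "condition"),
    list(message = paste0("no stationary state: ", reason),
         call = sys.call(-1))))
}

# --- branch continuation and the delta window -------------------------------

# Solve the conics at `delta` from a seed (continuation step). Returns the
# root (nu, rho) or NULL.
.branch_root <- function(params, delta, seed) {
  p2 <- params; p2$delta <- delta
  .newton_conics(conic_pair(p2), seed)
}

#' Stability window in the avalanche parameter
#'
#' For fixed occupation probabilities `c0..c3`, a stationary state exists for
#' `delta` in an interval `(delta_min, delta_max)` inside `(0, 1)`. The lower
#' boundary is where the cluster count `n` on the admissible solution branch
#' crosses 0 (the inverse-power limit of the cluster-size distribution); the
#' upper boundary is where `x2 = x0` (the boundary of the admissibility
#' half-plane, the near-exponential limit). The crossover `delta_eq` is where
#' the number of clusters equals the number of empty clusters, `n = n0`.
#' Each boundary is located by bisection along the solution branch, tracked
#' by Newton continuation, and refined to `|d delta| < 1e-10`.
#'
#' @param params An [rda_params] object using the `delta` law; the value of
#'   `params$delta` itself is ignored.
#' @param delta_grid Grid scanned to anchor the admissible branch.
#' @return Object of class `rda_delta_range`: list with `delta_min`,
#'   `delta_max`, `delta_eq`, the branch states at the boundaries
#'   (`state_min`, `state_max`), and a `diagnostics` list (bracket widths).
#'   Boundaries not bracketed inside `(0, 1)` are reported as `NA` ("open
#'   boundary").
#' @examples
#' \donttest{
#' rng <- delta_range(rda_params(1, 0.5, 0.25, 0.125, delta = 0.3))
#' c(rng$delta_min, rng$delta_max, rng$delta_eq)
#' }
#' @export
delta_range <- function(params, delta_grid = seq(0.02, 0.98, by = 0.02)) {
  stopifnot(inherits(params, "rda_params"))
  # anchor: an admissible delta
  anchor <- NULL
  for (d in delta_grid) {
    p2 <- params; p2$delta <- d
    st <- tryCatch(rda_solve(p2), error = function(e) NULL)
    if (!is.null(st)) { anchor <- list(delta = d, st = st); break }
  }
  if (is.null(anchor))
    stop("no admissible stationary state found on the delta grid")
  # extend anchor to the middle of the admissible run for robust continuation
  seed0 <- c(anchor$st$n / params$N, anchor$st$rho)

  branch_val <- function(delta, seed, what) {
    z <- .branch_root(params, delta, seed)
    if (is.null(z)) return(NULL)
    p2 <- params; p2$delta <- delta
    x <- .x_at(.x_affine(p2), z[1], z[2])
    val <- switch(what,
      n    = z[1],
      x2x0 = x[3] - x[1],
      neq  = z[1] - (x[3] + 2 * x[4] - x[1]) / 2)
    list(val = val, z = z)
  }

  # march outward from the anchor until the branch function changes sign,
  # then bisect with continuation seeds
  locate <- function(what, dir, tol = 1e-10) {
    d0 <- anchor$delta; r0 <- branch_val(d0, seed0, what)
    step <- 0.02 * dir
    d1 <- d0; r1 <- r0
    repeat {
      d2 <- d1 + step
      if (d2 <= 1e-4 || d2 >= 1 - 1e-4) return(NULL)  # open boundary
      r2 <- branch_val(d2, r1$z, what)
      if (is.null(r2)) { step <- step / 2; next }
      if (sign(r2$val) != sign(r1$val)) { break }
      d1 <- d2; r1 <- r2
    }
    lo <- list(d = d1, r = r1); hi <- list(d = d2, r = r2)
    while (abs(hi$d - lo$d) > tol) {
      dm <- (lo$d + hi$d) / 2
      rm <- branch_val(dm, (lo$r$z + hi$r$z) / 2, what)
      if (is.null(rm)) break
      if (sign(rm$val) == sign(lo$r$val)) lo <- list(d = dm, r = rm)
      else hi <- list(d = dm, r = rm)
    }
    dm <- (lo$d + hi$d) / 2
    list(delta = dm, z = .branch_root(params, dm, (lo$r$z + hi$r$z) / 2),
         width = abs(hi$d - lo$d))
  }

  lo <- locate("n", -1)
  hi <- locate("x2x0", +1)
  eq <- locate("neq", if (branch_val(anchor$delta, seed0, "neq")$val > 0)
    -1 else +1)

  mkstate <- function(b) {
    if (is.null(b)) return(NULL)
    p2 <- params; p2$delta <- b$delta
    .make_state(p2, b$z[1], b$z[2])
  }
  structure(list(
    delta_min = if (is.null(lo)) NA_real_ else lo$delta,
    delta_max = if (is.null(hi)) NA_real_ else hi$delta,
    delta_eq  = if (is.null(eq)) NA_real_ else eq$delta,
    state_min = mkstate(lo), state_max = mkstate(hi),
    diagnostics = list(
      width_min = if (is.null(lo)) NA_real_ else lo$width,
      width_max = if (is.null(hi)) NA_real_ else hi$width,
      width_eq  = if (is.null(eq)) NA_real_ else eq$width,
      anchor_delta = anchor$delta),
    params = params), class = "rda_delta_range")
}

#' @export
print.rda_delta_range <- function(x, ...) {
  cat(sprintf("delta window: (%.6f, %.6f), n = n0 at delta = %.6f\n",
              x$delta_min, x$delta_max, x$delta_eq))
  invisible(x)
}

# --- general-law residuals ---------------------------------------------------

#' Mean-field neighbour-occupation probability T
#'
#' Probability that an empty cell adjacent to another empty cell becomes
#' occupied in a step: `T = (c0 x0 + c1 x1 + c2 x2) / (x0 + x1 + x2)` (C3
#' cells have no empty neighbour and do not enter).
#'
#' @param params An [rda_params] object.
#' @param x0,x1,x2 Empty-cell counts by type (any common scale).
#' @return The probability `T`. A value outside `[0, 1]` signals an
#'   inadmissible `x` and is reported with a warning (not clipped).
#' @export
neighbor_occupation_T <- function(params, x0, x1, x2) {
  den <- x0 + x1 + x2
  if (den <= 0) stop("x0 + x1 + x2 must be positive")
  cc <- params$c
  Tv <- (cc[1] * x0 + cc[2] * x1 + cc[3] * x2) / den
  if (Tv < 0 || Tv > 1)
    warning("T outside [0, 1]: the supplied x is not admissible")
  Tv
}

#' Residuals of the balance equations for a general avalanche law
#'
#' Evaluates, for an arbitrary (not necessarily balanced) state, the signed
#' residuals (per `N` cells) of the exact balance equations for the density,
#' the cluster count and the empty-cluster count, and of the mean-field
#' equations for the four empty-cell types. The avalanche moments
#' `S1 = sum mu_i n_i i` and `S2 = sum mu_i n_i i^2` are taken from the
#' supplied cluster-size distribution.
#'
#' Orientation: every residual is signed as avalanche inflow minus
#' occupation outflow of the quantity's own balance (for the aggregates this
#' is removal minus occupation). This is the one orientation under which
#' both exact dependency relations hold for *any* state and any `T`:
#' `res_rho == res_n0 - res_n` and `sum(res_x0..res_x3) == res_rho`.
#' At a balanced state every residual vanishes, so the orientation is
#' immaterial there.
#'
#' @param params An [rda_params] object.
#' @param state A list (or `rda_steady_state`) with fields `x0..x3` and `n`
#'   on the same scale as the distribution.
#' @param dist An `rda_cluster_dist` (see [cascade()]) or a list with fields
#'   `i` and `ni` supplying the distribution used for the moments.
#' @return Named numeric vector with elements `rho`, `n`, `n0`, `x0`, `x1`,
#'   `x2`, `x3`.
#' @export
balance_residuals <- function(params, state, dist) {
  x <- c(state$x0, state$x1, state$x2, state$x3)
  n <- state$n
  if (n <= 0) stop("state must have n > 0 (moment ratios undefined)")
  mu <- avalanche_mu(params, dist$i)
  S1 <- sum(mu * dist$ni * dist$i)
  S2 <- sum(mu * dist$ni * dist$i^2)
  cc <- params$c
  Tv <- (cc[1] * x[1] + cc[2] * x[2] + cc[3] * x[3]) / (x[1] + x[2] + x[3])
  c(rho = S2 - sum(cc * x),
    n   = S1 - (cc[1] * x[1] - cc[3] * x[3] - 2 * cc[4] * x[4]),
    n0  = (S2 + S1) - (2 * cc[1] * x[1] + cc[2] * x[2] - cc[4] * x[4]),
    x0  = S2 + x[2] / n * S1 - (cc[1] + 3 * Tv) * x[1],
    x1  = 3 * Tv * x[1] - (2 * Tv + cc[2]) * x[2] - (x[2] - 2 * x[3]) / n * S1,
    x2  = 2 * Tv * x[2] - (Tv + cc[3]) * x[3] - (2 * x[3] - 3 * x[4]) / n * S1,
    x3  = Tv * x[3] - x[4] * (cc[4] + 3 * S1 / n))
}

#' @export
print.rda_steady_state <- function(x, ...) {
  cat(sprintf("RDA steady state (delta law%s, N = %g)\n",
              if (!is.null(x$params$delta))
                sprintf(", delta = %g", x$params$delta) else "", x$N))
  cat(sprintf("  rho = %.6f   n = %.1f   n0 = %.1f   n1_0 = %.1f\n",
              x$rho, x$n, x$n0, x$n1_0))
  fr <- c(x$x0, x$x1, x$x2, x$x3) / ((1 - x$rho) * x$N) * 100
  cat(sprintf("  x fractions of empty cells: %s %%\n",
              paste(sprintf("%.1f", fr), collapse = " / ")))
  cat(sprintf("  T = %.6f   Y = %.6f   <i> = %.2f\n", x$T, x$Y,
              x$rho * x$N / x$n))
  invisible(x)
}

#' Serialize a steady state to JSON
#'
#' Writes (or returns) the canonical JSON representation with fields
#' `rho, n, n0, n1_0, x0, x1, x2, x3, T, Y` (counts at scale `N`).
#'
#' @param state An `rda_steady_state`.
#' @param path Optional output file; when `NULL` the JSON string is returned.
#' @return The JSON string, invisibly when written to `path`.
#' @export
rda_state_json <- function(state, path = NULL) {
  stopifnot(inherits(state, "rda_steady_state"))
  obj <- state[c("rho", "n", "n0", "n1_0", "x0", "x1", "x2", "x3", "T", "Y")]
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}
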