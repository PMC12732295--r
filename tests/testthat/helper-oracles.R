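# Independent oracles. Each is deliberately implemented without reusing the
# package's solution path.

# Residuals of the unreduced six-equation steady-state system (per cell),
# unknowns u = (x0, x1, x2, x3, rho, nu), with the nonlinear T from its
# definition (not the C3 elimination the package solver uses).
raw_residuals <- function(cc, delta, u) {
  x <- u[1:4]; rho <- u[5]; nu <- u[6]
  Tv <- (cc[1] * x[1] + cc[2] * x[2] + cc[3] * x[3]) / (x[1] + x[2] + x[3])
  c(sum(x) - (1 - rho),
    sum(cc * x) - delta * rho,
    cc[1] * x[1] - cc[3] * x[3] - 2 * cc[4] * x[4] - delta * nu,
    (cc[1] + 3 * Tv) * x[1] - delta * rho - delta * x[2],
    3 * Tv * x[1] - (2 * Tv + cc[2]) * x[2] - delta * (x[2] - 2 * x[3]),
    Tv * x[3] - cc[4] * x[4] - 3 * delta * x[4])
}

raw_newton <- function(cc, delta, u, tol = 1e-13, maxit = 200) {
  for (it in seq_len(maxit)) {
    f <- raw_residuals(cc, delta, u)
    J <- vapply(1:6, function(j) {
      h <- 1e-8
      up <- u; up[j] <- up[j] + h
      (raw_residuals(cc, delta, up) - f) / h
    }, numeric(6))
    du <- tryCatch(solve(J, f), error = function(e) NULL)
    if (is.null(du)) return(NULL)
    u <- u - du
    if (sum(abs(du)) < tol) break
  }
  if (max(abs(raw_residuals(cc, delta, u))) < 1e-11) u else NULL
}

# Multistart raw Newton returning all distinct admissible roots.
raw_solve_all <- function(cc, delta, n_starts = 120, seed = 11) {
  set.seed(seed)
  roots <- list()
  for (k in seq_len(n_starts)) {
    u0 <- c(runif(4, 0, 0.2), runif(1, 0.2, 0.9), runif(1, 0, 0.3))
    u <- raw_newton(cc, delta, u0)
    if (is.null(u)) next
    ok <- u[6] > 1e-9 && all(u[1:4] > 1e-12) && u[5] > 0 && u[5] < 1 &&
      u[3] > u[1]
    if (!ok) next
    if (!any(vapply(roots, function(r) sum(abs(r - u)) < 1e-7, logical(1))))
      roots[[length(roots) + 1L]] <- u
  }
  roots
}

# Raw Newton seeded from a given state (fast verification of a single root).
raw_solve_from <- function(cc, delta, rho, nu, xfrac) {
  u0 <- c(xfrac * (1 - rho), rho, nu)
  raw_newton(cc, delta, u0)
}

# Naive O(i^2)-per-term cascade (direct double/triple loops) -- oracle for
# the package's cached-convolution implementation. Returns n_i per N cells.
naive_cascade <- function(st, imax) {
  cc <- st$params$c; delta <- st$params$delta
  N <- st$N
  x <- c(st$x0, st$x1, st$x2, st$x3) / N
  n <- st$n / N
  Y <- (cc[2] * x[2] + 2 * cc[3] * x[3] + 3 * cc[4] * x[4]) / n
  g <- numeric(imax)
  g[1] <- cc[1] * x[1] / ((delta + Y) * n)
  for (i in 2:imax) {
    s2 <- 0
    if (i >= 3) for (k in 1:(i - 2)) s2 <- s2 + g[k] * g[i - k - 1]
    s3 <- 0
    if (i >= 4) for (k in 1:(i - 3)) for (l in 1:(i - k - 2))
      s3 <- s3 + g[k] * g[l] * g[i - k - l - 1]
    g[i] <- (cc[2] * x[2] * g[i - 1] + cc[3] * x[3] * s2 +
               cc[4] * x[4] * s3) / (n * (delta + Y))
  }
  g * n * N
}

# Brute-force sequence oracles.
# Double precision, exact for n_terms <= 25 (values < 2^53).
seq_oracle_dbl <- function(n_terms, triple_coef) {
  M <- c(1, 1)
  for (i in 3:n_terms) {
    v <- M[i - 1]
    for (k in 1:(i - 2)) v <- v + M[k] * M[i - 1 - k]
    if (triple_coef != 0 && i >= 4)
      for (k in 1:(i - 3)) for (l in 1:(i - k - 2))
        v <- v + M[k] * M[l] * M[i - k - l - 1]
    M[i] <- v
  }
  M[seq_len(n_terms)]
}

# Same recurrence modulo a prime (products < 2^53 for p < 9e7^0.5... use
# p ~ 6e7 so p^2 < 2^53): validates exactness of the bignum path at sizes
# far beyond double precision.
seq_oracle_mod <- function(n_terms, triple_coef, p) {
  M <- c(1, 1)
  for (i in 3:n_terms) {
    v <- M[i - 1]
    for (k in 1:(i - 2)) v <- (v + (M[k] * M[i - 1 - k]) %% p) %% p
    if (triple_coef != 0 && i >= 4)
      for (k in 1:(i - 3)) for (l in 1:(i - k - 2))
        v <- (v + ((M[k] * M[l]) %% p) * M[i - k - l - 1]) %% p
    M[i] <- v
  }
  M[seq_len(n_terms)]
}

# Decimal string modulo p (for comparing bignum output with the mod oracle).
strmod <- function(s, p) {
  v <- 0
  for (ch in strsplit(s, "")[[1]])
    v <- (v * 10 + as.integer(ch)) %% p
  v
}

# Plain-R reimplementation of one sweep of the automaton dynamics (oracle
# for the compiled stepper's stationary behaviour; uses its own RNG draws).
r_dynamics_rho <- function(lattice, cc, delta, steps, burn, sample_every) {
  adj <- lattice$adj
  n <- nrow(adj)
  occ <- rep(FALSE, n)
  acc <- numeric(0)
  for (s in seq_len(steps)) {
    u <- sample.int(n, 1)
    if (occ[u]) {
      comp <- u; head <- 1
      while (head <= length(comp)) {
        v <- comp[head]; head <- head + 1
        for (w in adj[v, ]) if (!is.na(w) && occ[w] && !(w %in% comp))
          comp <- c(comp, w)
      }
      if (runif(1) < delta / length(comp)) occ[comp] <- FALSE
    } else {
      t <- sum(occ[adj[u, ]], na.rm = TRUE)
      if (runif(1) < cc[t + 1]) occ[u] <- TRUE
    }
    if (s > burn && s %% sample_every == 0) acc <- c(acc, mean(occ))
  }
  acc
}
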