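test_that("lattice builders produce the advertised structures", {
  lat <- build_lattice("random-regular", 1000, seed = 5)
  expect_true(all(rowSums(!is.na(lat$adj)) == 3))
  expect_false(any(lat$boundary))
  # symmetric adjacency
  for (v in sample(1000, 20))
    for (w in lat$adj[v, ]) expect_true(v %in% lat$adj[w, ])
  expect_error(build_lattice("random-regular", 1001), "even")

  cb <- build_lattice("cayley-ball", 10)   # r = 2: centre, 3 interior, 6 leaves
  deg <- rowSums(!is.na(cb$adj))
  expect_equal(sum(deg == 3), 4)
  expect_equal(sum(deg == 1), 6)
  expect_equal(cb$boundary, deg < 3)
  expect_error(build_lattice("cayley-ball", 11), "2\\^r")

  # a moderately large random 3-regular graph is locally tree-like
  diag <- lattice_cycle_diagnostic(build_lattice("random-regular", 400,
                                                 seed = 2), len = 4)
  expect_gte(diag$girth, 3)
  expect_lt(diag$frac_on_short_cycle, 0.2)
})

test_that("degenerate dynamics behave as forced", {
  lat <- build_lattice("random-regular", 200, seed = 8)
  # negligible removal, positive occupation everywhere: the lattice fills
  # monotonically (c3 < c0 keeps the parameter object admissible)
  p_fill <- rda_params(1, 1, 1, 0.9, delta = 1e-12)
  res <- run_sim(sim_config(lat, p_fill, seed = 3, burn_in = 200 * 50,
                            n_samples = 5, sample_interval = 200))
  expect_equal(unname(res$mean["rho"]), 1, tolerance = 1e-6)

  # equal occupation probabilities close the density balance exactly:
  # rho = c / (c + delta), testable without any mean-field closure
  p_eq <- structure(list(c = rep(0.5, 4), delta = 0.4, mu = NULL, N = 1e6,
                         k = 3L), class = "rda_params")
  res2 <- run_sim(sim_config(lat, p_eq, seed = 4, burn_in = 200 * 200,
                             n_samples = 300, sample_interval = 200))
  expect_lt(abs(res2$mean[["rho"]] - 0.5 / 0.9),
            4 * res2$se[["rho"]] + 0.01)
})

test_that("single-step semantics and reproducibility", {
  lat <- build_lattice("random-regular", 100, seed = 1)
  p <- rda_params(1, 0.5, 0.5, 0.5, delta = 0.4)
  # empty lattice: a step can only occupy (creating cell, probability c0=1)
  set.seed(10)
  out <- sim_step(lat, rep(FALSE, 100), p)
  expect_equal(sum(out$occ), 1)
  expect_equal(out$event, 1)
  # single occupied cell: removal happens with probability mu_1 = delta
  set.seed(11)
  hits <- 0; chosen <- 0
  for (k in 1:4000) {
    occ <- c(TRUE, rep(FALSE, 99))
    out <- sim_step(lat, occ, p)
    if (!out$occ[1]) hits <- hits + 1
    if (!out$occ[1] || sum(out$occ) == 1) chosen <- chosen   # bookkeeping
  }
  # removal rate per step = (1/n) * delta
  expect_lt(abs(hits / 4000 - 0.4 / 100), 3e-3)

  # identical seed + config => identical trajectory
  cfg <- sim_config(lat, p, seed = 99, burn_in = 5000, n_samples = 10,
                    sample_interval = 100)
  r1 <- run_sim(cfg); r2 <- run_sim(cfg)
  expect_identical(r1$stats, r2$stats)
  # union-find and BFS paths produce identical trajectories
  r3 <- run_sim(cfg, use_union_find = FALSE)
  expect_identical(r1$stats, r3$stats)
})

test_that("per-snapshot identities hold exactly", {
  lat <- build_lattice("random-regular", 2000, seed = 6)
  p <- rda_params(1, 0.5, 0.25, 0.125, delta = 0.3)
  res <- run_sim(sim_config(lat, p, seed = 5, burn_in = 2000 * 60,
                            n_samples = 25, sample_interval = 2000,
                            keep_snapshots = TRUE))
  for (k in seq_len(nrow(res$stats))) {
    occ <- res$snapshots[k, ]
    s <- snapshot_stats(lat, occ)
    # compiled per-snapshot stats match the recorded ones
    expect_equal(s$n, res$stats[k, "n"][[1]])
    expect_equal(s$x, unname(res$stats[k, c("x0", "x1", "x2", "x3")]))
    # conservation: sum x_t = number of empty cells; cluster sizes sum to
    # the occupied count
    expect_equal(sum(s$x), sum(!occ))
    expect_equal(sum(s$sizes), sum(occ))
    # independent recomputation with igraph components
    g <- igraph::subgraph(rdabethe:::.lattice_igraph(lat), which(occ))
    expect_equal(igraph::components(g)$no, s$n)
  }
})

test_that("Fact 1 and the perimeter formula hold exactly on the Cayley tree", {
  lat <- build_lattice("cayley-ball", 1 + 3 * (2^9 - 1))   # 1534 cells
  p <- rda_params(1, 0.5, 0.5, 0.5, delta = 0.45)
  res <- run_sim(sim_config(lat, p, seed = 21, burn_in = lat$n_cells * 60,
                            n_samples = 25, sample_interval = lat$n_cells,
                            keep_snapshots = TRUE))
  interior <- !lat$boundary &
    !apply(lat$adj, 1, function(w) any(lat$boundary[w], na.rm = TRUE))
  checked <- 0
  for (k in seq_len(nrow(res$stats))) {
    occ <- res$snapshots[k, ]
    comp <- snapshot_composition(lat, occ)
    for (r in seq_len(nrow(comp))) {
      expected <- empty_cluster_composition(comp$i[r], comp$j[r])
      expect_identical(
        unlist(comp[r, c("n_creating", "n_enlarging", "n_C2", "n_C3")],
               use.names = FALSE),
        c(expected$n_creating, expected$n_enlarging, expected$n_C2,
          expected$n_C3))
      checked <- checked + 1
    }
    # perimeter of interior occupied clusters is size + 2
    g <- rdabethe:::.lattice_igraph(lat)
    cl <- igraph::components(igraph::subgraph(g, which(occ)))
    for (cid in seq_len(cl$no)) {
      members <- which(occ)[cl$membership == cid]
      if (!all(interior[members])) next
      outside <- setdiff(stats::na.omit(as.vector(
        lat$adj[members, , drop = FALSE])), members)
      expect_equal(length(outside), length(members) + 2)
    }
  }
  expect_gt(checked, 50)    # the test actually saw many interior clusters
})

test_that("stationary simulation satisfies the exact balance identities", {
  # the flow-balance relations for rho, n and n0 are exact properties of
  # the dynamics (no mean-field closure enters), so the stationary
  # expectation of each per-snapshot imbalance is zero; the sample mean must
  # vanish within its own batch-means error
  lat <- build_lattice("random-regular", 5000, seed = 12)
  p <- rda_params(1, 0.5, 0.25, 0.125, delta = 0.44)
  res <- run_sim(sim_config(lat, p, seed = 13, burn_in = 5000 * 100,
                            n_samples = 400, sample_interval = 5000))
  s <- res$stats / 5000           # per cell; rho column is rescaled too but
  rho <- res$stats[, "rho"]       # used directly below
  imbalance <- cbind(
    rho = s[, "x0"] + 0.5 * s[, "x1"] + 0.25 * s[, "x2"] +
      0.125 * s[, "x3"] - 0.44 * rho,
    n   = s[, "x0"] - 0.25 * s[, "x2"] - 0.25 * s[, "x3"] -
      0.44 * s[, "n"],
    n0  = 2 * s[, "x0"] + 0.5 * s[, "x1"] - 0.125 * s[, "x3"] -
      0.44 * (rho + s[, "n"]))
  for (f in colnames(imbalance)) {
    se <- rdabethe:::.batch_se(imbalance[, f])
    expect_lt(abs(mean(imbalance[, f])), 4 * se + 1e-4,
              label = paste("imbalance", f))
  }
})

test_that("compiled stationary density matches an independent R
           implementation of the dynamics", {
  lat <- build_lattice("random-regular", 300, seed = 14)
  p <- rda_params(1, 0.5, 0, 0, delta = 0.4)
  set.seed(15)
  rho_r <- r_dynamics_rho(lat, p$c, 0.4, steps = 1.2e5, burn = 3e4,
                          sample_every = 300)
  res <- run_sim(sim_config(lat, p, seed = 16, burn_in = 3e4,
                            n_samples = 300, sample_interval = 300))
  se <- sqrt(res$se[["rho"]]^2 + (stats::sd(tapply(
    rho_r, rep(1:20, length.out = length(rho_r)), mean)) / sqrt(20))^2)
  expect_lt(abs(res$mean[["rho"]] - mean(rho_r)), 4 * se + 0.01)
})

test_that("below delta_min the density swings; the drift warning detects
           non-stationary runs", {
  lat <- build_lattice("random-regular", 3000, seed = 31)
  # delta = 0.09 < delta_min = 0.121105 for this family: no steady plateau,
  # the density cycles through near-full and near-empty states
  p <- rda_params(1, 0.5, 0.25, 0.125, delta = 0.09)
  res <- suppressWarnings(
    run_sim(sim_config(lat, p, seed = 32, burn_in = 3000 * 30,
                       n_samples = 80, sample_interval = 3000)))
  expect_gt(diff(range(res$stats[, "rho"])), 0.3)
  expect_gt(stats::sd(res$stats[, "rho"]), 0.1)

  # the half-means drift detector itself: an unequilibrated filling
  # trajectory (short burn-in, negligible removal) must trigger it
  p_fill <- rda_params(1, 1, 1, 0.9, delta = 1e-9)
  expect_warning(
    res2 <- run_sim(sim_config(lat, p_fill, seed = 33, burn_in = 3000,
                               n_samples = 40, sample_interval = 150)),
    "non-stationarity")
  expect_false(res2$stationary)
})
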