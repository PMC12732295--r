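# Finite-lattice Monte-Carlo validation of the mean-field theory. The model
# is defined on the infinite Bethe lattice; any finite realization is an
# approximation. Two surrogates are provided: a uniformly sampled random
# 3-regular graph (boundary-free and locally tree-like -- the default for
# quantitative comparison with the solver) and a ball in the Cayley tree
# (exactly cycle-free, used for the exact combinatorial checks with
# measurements restricted to the interior).

#' Build a finite locally-tree-like 3-regular lattice
#'
#' @param mode `"random-regular"` (uniform random 3-regular graph; `n_cells`
#'   must be even) or `"cayley-ball"` (ball of radius `r` in the 3-regular
#'   tree; `n_cells` must equal `1 + 3 (2^r - 1)` for some integer `r >= 1`;
#'   leaves have degree 1 and are flagged as boundary).
#' @param n_cells Number of cells (`>= 100` for simulation use; smaller
#'   lattices are allowed for testing).
#' @param seed Optional RNG seed used for the random-regular sample.
#' @return Object of class `rda_lattice`: list with `adj` (integer matrix
#'   `n_cells x 3`, 1-based neighbour indices, `NA` for missing),
#'   `boundary` (logical), `mode`, `n_cells`.
#' @export
build_lattice <- function(mode = c("random-regular", "cayley-ball"),
                          n_cells, seed = NULL) {
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  if (mode == "random-regular") {
    if (n_cells %% 2 != 0) stop("random-regular requires an even n_cells")
    g <- igraph::sample_k_regular(n_cells, 3)
    adj <- matrix(NA_integer_, n_cells, 3)
    al <- igraph::as_adj_list(g)
    for (v in seq_len(n_cells)) adj[v, ] <- as.integer(al[[v]])
    boundary <- rep(FALSE, n_cells)
  } else {
    r <- log2((n_cells - 1) / 3 + 1)
    if (abs(r - round(r)) > 1e-9 || r < 1)
      stop("cayley-ball requires n_cells = 1 + 3 (2^r - 1), r >= 1")
    r <- as.integer(round(r))
    adj <- matrix(NA_integer_, n_cells, 3)
    # vertex 1 is the centre with 3 children; every other interior vertex
    # has one parent and 2 children, breadth-first numbering
    nxt <- 2L
    frontier <- 1L
    for (depth in seq_len(r)) {
      newfront <- integer(0)
      for (v in frontier) {
        nkids <- if (v == 1L) 3L else 2L
        kids <- seq.int(nxt, length.out = nkids)
        nxt <- nxt + nkids
        slot <- if (v == 1L) 1L else 2L
        adj[v, slot:(slot + nkids - 1L)] <- kids
        for (k in kids) adj[k, 1L] <- v
        newfront <- c(newfront, kids)
      }
      frontier <- newfront
    }
    boundary <- rowSums(!is.na(adj)) < 3
  }
  structure(list(adj = adj, boundary = boundary, mode = mode,
                 n_cells = as.integer(n_cells)),
            class = "rda_lattice")
}

#' Short-cycle diagnostic for a lattice
#'
#' Reports the girth of the graph and the fraction of vertices lying on a
#' cycle of length at most `len`: on a good Bethe-lattice surrogate this
#' fraction is small.
#'
#' @param lattice An `rda_lattice`.
#' @param len Cycle-length cutoff.
#' @return List with `girth` and `frac_on_short_cycle`.
#' @export
lattice_cycle_diagnostic <- function(lattice, len = 4) {
  g <- .lattice_igraph(lattice)
  girth <- suppressWarnings(igraph::girth(g)$girth)
  n <- lattice$n_cells
  on_cycle <- vapply(seq_len(n), function(v) {
    # vertex on a cycle <= len iff some neighbour is reachable in <= len-1
    # steps avoiding the direct edge
    nbs <- lattice$adj[v, ]
    nbs <- nbs[!is.na(nbs)]
    for (w in nbs) {
      h <- igraph::delete_edges(g, igraph::get_edge_ids(g, c(v, w)))
      dd <- igraph::distances(h, v = v, to = w)
      if (is.finite(dd) && dd <= len - 1) return(TRUE)
    }
    FALSE
  }, logical(1))
  list(girth = if (is.finite(girth)) girth else Inf,
       frac_on_short_cycle = mean(on_cycle))
}

.lattice_igraph <- function(lattice) {
  adj <- lattice$adj
  e <- cbind(rep(seq_len(nrow(adj)), ncol(adj)), as.vector(adj))
  e <- e[!is.na(e[, 2]) & e[, 1] < e[, 2], , drop = FALSE]
  igraph::graph_from_edgelist(e, directed = FALSE)
}

.adj0 <- function(lattice) {
  a <- lattice$adj - 1L
  a[is.na(a)] <- -1L
  a
}

#' Simulation configuration
#'
#' @param lattice An `rda_lattice` from [build_lattice()].
#' @param params An [rda_params] with the `delta` law.
#' @param burn_in Number of update steps discarded before sampling (default
#'   50 sweeps, i.e. `50 * n_cells`).
#' @param n_samples Number of snapshots.
#' @param sample_interval Steps between snapshots (default one sweep).
#' @param seed RNG seed.
#' @param keep_snapshots Store the occupancy of every snapshot (needed for
#'   composition checks; memory `n_samples * n_cells` logicals).
#' @return Object of class `rda_sim_config`.
#' @export
sim_config <- function(lattice, params, burn_in = 50 * lattice$n_cells,
                       n_samples = 200, sample_interval = lattice$n_cells,
                       seed = 1L, keep_snapshots = FALSE) {
  stopifnot(inherits(lattice, "rda_lattice"), inherits(params, "rda_params"))
  if (!.is_special_law(params))
    stop("the simulator implements the law mu_i = delta / i")
  if (burn_in < lattice$n_cells)
    stop("burn_in must be at least one sweep (n_cells steps)")
  if (sample_interval < 1) stop("sample_interval must be >= 1")
  structure(list(lattice = lattice, params = params, burn_in = burn_in,
                 n_samples = as.integer(n_samples),
                 sample_interval = sample_interval, seed = as.integer(seed),
                 keep_snapshots = keep_snapshots),
            class = "rda_sim_config")
}

#' One update step of the automaton
#'
#' Selects one cell uniformly and draws one acceptance variate `r`: an
#' occupied cell's cluster of size `i` is removed iff `r < delta / i`; an
#' empty cell with `t` occupied neighbours becomes occupied iff `r < c_t`.
#' Uses R's RNG stream.
#'
#' @param lattice An `rda_lattice`.
#' @param occ Logical occupancy vector.
#' @param params An [rda_params] with the `delta` law.
#' @return List with the updated `occ` and `event` (0 = unchanged,
#'   1 = occupation, 2 = avalanche).
#' @export
sim_step <- function(lattice, occ, params) {
  .sim_step_cpp(.adj0(lattice), occ, params$c, params$delta)
}

#' Run the Monte-Carlo simulation
#'
#' Runs the automaton from an empty initial state, discards `burn_in` steps,
#' then records `n_samples` snapshots every `sample_interval` steps. Means
#' and batch-means standard errors (20 batches) are reported for the
#' per-cell observables `rho`, `n`, `n0`, `n1_0`, `x0..x3`. A warning flag
#' is set when the first- and second-half means of `rho` differ by more than
#' 5 standard errors (non-stationarity).
#'
#' @param config An `rda_sim_config`.
#' @param use_union_find Use the incremental union-find cluster bookkeeping
#'   (default). `FALSE` recomputes cluster sizes by BFS at every avalanche
#'   test: slower, kept as the correctness oracle — both paths consume the
#'   RNG identically and must produce identical trajectories.
#' @return Object of class `rda_sim_result`: `mean`, `se` (per-cell scale),
#'   `stats` (per-snapshot matrix), `hist` (cluster-size counts accumulated
#'   over snapshots), `snapshots` (when kept), `stationary` (logical),
#'   `config`.
#' @export
run_sim <- function(config, use_union_find = TRUE) {
  stopifnot(inherits(config, "rda_sim_config"))
  set.seed(config$seed)
  lat <- config$lattice
  res <- .sim_run_cpp(.adj0(lat), rep(FALSE, lat$n_cells),
                      config$params$c, config$params$delta,
                      config$burn_in, config$n_samples,
                      config$sample_interval, config$keep_snapshots,
                      hist_max = lat$n_cells,
                      use_union_find = use_union_find)
  stats <- res$stats
  percell <- stats
  percell[, -1] <- percell[, -1] / lat$n_cells   # rho already a fraction
  mean_ <- colMeans(percell)
  se_ <- apply(percell, 2, .batch_se, n_batches = 20)
  half <- seq_len(nrow(percell)) <= nrow(percell) / 2
  drift <- abs(mean(percell[half, "rho"]) - mean(percell[!half, "rho"]))
  stationary <- drift <= 5 * max(se_["rho"], .Machine$double.eps)
  if (!stationary)
    warning("non-stationarity: first/second half rho means differ by > 5 SE")
  structure(list(mean = mean_, se = se_, stats = stats, hist = res$hist,
                 snapshots = res$snapshots, final_occ = res$final_occ,
                 stationary = stationary, config = config),
            class = "rda_sim_result")
}

.batch_se <- function(x, n_batches = 20) {
  nb <- min(n_batches, length(x))
  b <- tapply(x, cut(seq_along(x), nb, labels = FALSE), mean)
  stats::sd(b) / sqrt(nb)
}

#' @export
print.rda_sim_result <- function(x, ...) {
  cat(sprintf("RDA simulation: %d cells (%s), %d snapshots%s\n",
              x$config$lattice$n_cells, x$config$lattice$mode,
              x$config$n_samples,
              if (x$stationary) "" else "  [NON-STATIONARY]"))
  m <- rbind(mean = x$mean, se = x$se)
  print(round(m, 6))
  invisible(x)
}

#' Empty-cluster composition tallies of a snapshot
#'
#' For every empty cluster of a snapshot on a cycle-free lattice
#' (`cayley-ball`), measures the size `i`, the number of creating cells `j`,
#' and the per-type cell counts, excluding any cluster that contains or
#' touches a boundary vertex (whose neighbourhood is incomplete). Each
#' interior tally can be compared exactly with
#' [empty_cluster_composition()].
#'
#' @param lattice An `rda_lattice` (interior filtering uses its `boundary`
#'   flags; on a boundary-free lattice all clusters are measured).
#' @param occ Logical occupancy vector.
#' @return Data frame with columns `i`, `j`, `n_creating`, `n_enlarging`,
#'   `n_C2`, `n_C3`, one row per measured empty cluster.
#' @export
snapshot_composition <- function(lattice, occ) {
  adj <- lattice$adj
  n <- lattice$n_cells
  seen <- logical(n)
  rows <- list()
  for (v in seq_len(n)) {
    if (occ[v] || seen[v]) next
    # BFS the empty cluster
    comp <- v; seen[v] <- TRUE; head <- 1L
    touches_boundary <- lattice$boundary[v]
    while (head <= length(comp)) {
      u <- comp[head]; head <- head + 1L
      for (w in adj[u, ]) {
        if (is.na(w)) next
        if (!occ[w] && !seen[w]) {
          seen[w] <- TRUE; comp <- c(comp, w)
          if (lattice$boundary[w]) touches_boundary <- TRUE
        }
      }
    }
    # exclude clusters touching the boundary (incomplete neighbourhoods),
    # including clusters adjacent to it through an occupied boundary cell
    if (touches_boundary ||
        any(lattice$boundary[stats::na.omit(as.vector(adj[comp, ]))]))
      next
    occ_nb <- vapply(comp, function(u) {
      w <- adj[u, ]; sum(occ[w[!is.na(w)]])
    }, numeric(1))
    rows[[length(rows) + 1L]] <- data.frame(
      i = length(comp), j = sum(occ_nb == 0),
      n_creating = sum(occ_nb == 0), n_enlarging = sum(occ_nb == 1),
      n_C2 = sum(occ_nb == 2), n_C3 = sum(occ_nb == 3))
  }
  if (length(rows) == 0)
    return(data.frame(i = integer(0), j = integer(0),
                      n_creating = integer(0), n_enlarging = integer(0),
                      n_C2 = integer(0), n_C3 = integer(0)))
  do.call(rbind, rows)
}

#' Whole-snapshot cluster statistics (compiled path)
#'
#' Exact per-snapshot counts used by the simulator: density, number of
#' occupied clusters and their sizes, number of empty clusters, size-1 empty
#' clusters, and empty-cell counts by type.
#'
#' @param lattice An `rda_lattice`.
#' @param occ Logical occupancy vector.
#' @return List with `rho`, `n`, `n0`, `n1_0`, `x` (length 4) and `sizes`.
#' @export
snapshot_stats <- function(lattice, occ) {
  .cluster_stats_cpp(.adj0(lattice), occ)
}
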