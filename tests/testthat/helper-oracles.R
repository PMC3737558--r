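# Shared fixtures and independent oracles used across test files.

# Construct a system_state directly from coordinates (bypassing the builders)
# for hand-placed fixtures. Geometry defaults to a huge container so wall
# effects are absent unless requested.
toy_state <- function(xyz1, xyz2, topo1 = "linear", topo2 = "linear", r,
                      geom = spherocylinder(diameter = 50, aspect = 4)) {
  specs <- list(chain_spec(topo1, nrow(xyz1), r),
                chain_spec(topo2, nrow(xyz2), r))
  ringmix:::new_system_state(geom, specs, list(xyz1, xyz2))
}

# Exhaustive double-loop contact oracle: recomputes every contact probability
# by brute force, independently of the cell-list production path.
oracle_observables <- function(state) {
  r <- state$specs[[1]]$r
  cut <- 3 * r
  x1 <- state$coords[[1]]; x2 <- state$coords[[2]]
  n1 <- nrow(x1); n2 <- nrow(x2)
  d <- function(a, b) sqrt(sum((a - b)^2))
  inter <- 0L
  for (i in seq_len(n1)) for (j in seq_len(n2))
    if (d(x1[i, ], x2[j, ]) < cut) inter <- inter + 1L
  intra <- function(x, circular) {
    n <- nrow(x); cnt <- 0L; pairs <- 0L
    for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
      consec <- (j - i == 1L) || (circular && i == 1L && j == n)
      if (consec) next
      pairs <- pairs + 1L
      if (d(x[i, ], x[j, ]) < cut) cnt <- cnt + 1L
    }
    c(cnt, pairs)
  }
  c1 <- intra(x1, state$specs[[1]]$topology == "circular")
  c2 <- intra(x2, state$specs[[2]]$topology == "circular")
  ends <- function(k) {
    x <- state$coords[[k]]; other <- state$coords[[3 - k]]
    n <- nrow(x)
    res <- NULL
    for (e in c(1L, n)) {
      ei <- sum(apply(other, 1L, function(p) d(x[e, ], p) < cut))
      adj <- if (e == 1L) 2L else n - 1L
      internal <- setdiff(seq.int(2L, n - 1L), adj)
      ea <- sum(vapply(internal, function(j) d(x[e, ], x[j, ]) < cut, TRUE))
      res <- rbind(res, c(ei / nrow(other), ea / (n - 3L)))
    }
    res
  }
  lin <- which(vapply(state$specs, function(s) s$topology == "linear", TRUE))
  endtab <- if (length(lin)) do.call(rbind, lapply(lin, ends)) else NULL
  list(p_inter = inter / (n1 * n2),
       p_intra1 = c1[1] / c1[2], p_intra2 = c2[1] / c2[2],
       intra_pairs1 = c1[2], intra_pairs2 = c2[2],
       p_end_inter = if (is.null(endtab)) NA_real_ else mean(endtab[, 1]),
       p_end_intra = if (is.null(endtab)) NA_real_ else mean(endtab[, 2]))
}

# Small equilibrated system for oracle comparisons: built then briefly
# decorrelated by the engine.
small_system <- function(topo = c("circular", "circular"), n = 20, seed = 1,
                         phi = 0.05, iters = 4000) {
  geom <- spherocylinder()
  r <- solve_bead_radius(2 * n, phi, geom)
  specs <- lapply(topo, chain_spec, n = n, r = r)
  st <- build_initial_segregated(specs, geom, seed)
  cfg <- mc_config(n = n, total_iterations = iters, discard_iterations = 0,
                   sample_interval = iters, seed = seed, audit_interval = 0)
  run_mc(st, cfg)$final_state
}
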