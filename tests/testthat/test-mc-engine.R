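test_that("proposal generation respects the move-set definitions", {
  geom <- spherocylinder()
  n <- 24L
  r <- solve_bead_radius(2 * n, 0.05, geom)
  st <- build_initial_segregated(list(chain_spec("circular", n, r),
                                      chain_spec("linear", n, r)), geom, 1)
  cfg <- mc_config(n = n, seed = 5)
  set.seed(5)
  saw_terminal <- FALSE
  for (k in 1:500) {
    p <- propose_crankshaft(st, cfg)
    expect_true(p$chain %in% 1:2)
    expect_true(all(abs(p$theta) <= pi))
    expect_true(length(p$moved) <= cfg$s_max - 1L || p$terminal)
    # moved set excludes every pivot
    expect_identical(intersect(p$moved, p$pivots), integer(0))
    topo <- st$specs[[p$chain]]$topology
    if (p$terminal) {
      saw_terminal <- TRUE
      expect_identical(topo, "linear")
      expect_identical(length(p$pivots), 1L)
      # the moved set is everything strictly beyond the single pivot
      expect_true(all(p$moved < p$pivots) || all(p$moved > p$pivots))
      if (length(p$moved) && all(p$moved > p$pivots))
        expect_identical(p$moved, seq.int(p$pivots + 1L, n))
      if (length(p$moved) && all(p$moved < p$pivots))
        expect_identical(p$moved, seq.int(1L, p$pivots - 1L))
    } else if (topo == "linear") {
      expect_identical(p$moved,
                       if (diff(p$pivots) >= 2L)
                         seq.int(p$pivots[1] + 1L, p$pivots[2] - 1L)
                       else integer(0))
    } else {
      s <- (p$pivots[2] - p$pivots[1]) %% n
      expect_identical(length(p$moved), max(0L, as.integer(s) - 1L))
    }
  }
  expect_true(saw_terminal)
})

test_that("zero-angle proposals are accepted and leave coordinates unchanged", {
  geom <- spherocylinder()
  n <- 20L
  r <- solve_bead_radius(2 * n, 0.05, geom)
  st <- build_initial_segregated(list(chain_spec("circular", n, r),
                                      chain_spec("circular", n, r)), geom, 1)
  prop <- structure(list(chain = 1L, pivots = c(1L, 5L), moved = 2:4,
                         origin = st$coords[[1]][1, ],
                         axis = c(0, 0, 1), theta = 0, terminal = FALSE),
                    class = "crankshaft_proposal")
  res <- attempt_move(st, prop)
  expect_true(res$accepted)
  expect_identical(res$state$coords, st$coords)
  expect_identical(res$state$iteration_count, st$iteration_count + 1)
})

test_that("a rotation through the wall is rejected atomically", {
  r <- 0.05
  geom <- spherocylinder()
  # straight rod parallel to the axis, hugging the wall (radial 0.44 < 0.45)
  rod <- cbind(0.44, 0, (0:4) * 2 * r)
  other <- cbind(0, 0, -1.5 + (0:4) * 2 * r)
  st <- toy_state(rod, other, r = r, geom = geom)
  expect_identical(nrow(validate_state(st)), 0L)
  prop <- structure(list(chain = 1L, pivots = 4L, moved = 5L,
                         origin = rod[4, ], axis = c(1, 0, 0),
                         theta = 0.4, terminal = TRUE),
                    class = "crankshaft_proposal")
  # a small tilt keeps bead 5 inside the eroded wall
  res_ok <- attempt_move(st, prop)
  expect_true(res_ok$accepted)
  # a quarter turn swings it azimuthally out of the eroded cylinder
  prop$theta <- pi / 2
  res <- attempt_move(st, prop)
  expect_false(res$accepted)
  expect_identical(res$state$coords, st$coords)
})

test_that("the engine is deterministic given the seed", {
  geom <- spherocylinder()
  n <- 30L
  r <- solve_bead_radius(2 * n, 0.05, geom)
  st <- build_initial_segregated(list(chain_spec("circular", n, r),
                                      chain_spec("linear", n, r)), geom, 1)
  cfg <- mc_config(n = n, total_iterations = 30000,
                   discard_iterations = 6000, seed = 9)
  r1 <- run_mc(st, cfg)
  r2 <- run_mc(st, cfg)
  expect_identical(r1$samples, r2$samples)
  expect_identical(r1$final_state$coords, r2$final_state$coords)
  expect_identical(r1$acceptance, r2$acceptance)
  # a run ending at the discard threshold yields no samples but statistics
  cfg0 <- mc_config(n = n, total_iterations = 2000 * n, seed = 9)
  r0 <- run_mc(st, cfg0)
  expect_null(r0$samples)
  expect_gt(r0$acceptance$attempted, 0)
})

test_that("states remain valid and bonds do not drift over long runs", {
  geom <- spherocylinder()
  n <- 40L
  r <- solve_bead_radius(2 * n, 0.05, geom)
  for (topo in list(c("circular", "circular"), c("circular", "linear"))) {
    st <- build_initial_segregated(lapply(topo, chain_spec, n = n, r = r),
                                   geom, 1)
    cfg <- mc_config(n = n, total_iterations = 2e5, discard_iterations = 0,
                     seed = 4, audit_interval = 0)
    out <- run_mc(st, cfg)
    fin <- out$final_state
    expect_identical(nrow(validate_state(fin)), 0L)
    for (k in 1:2) {
      x <- fin$coords[[k]]
      idx <- if (topo[k] == "circular") c(2:n, 1L) else 2:n
      bl <- sqrt(rowSums((x[idx, ] - x[seq_along(idx), ])^2))
      expect_lt(max(abs(bl - 2 * r)), 1e-9 * r)
    }
    expect_gt(out$acceptance$rate, 0)
  }
})

test_that("acceptance rate falls as the volume fraction rises", {
  geom <- spherocylinder()
  n <- 50L
  rates <- vapply(c(0.02, 0.05, 0.12), function(phi) {
    r <- solve_bead_radius(2 * n, phi, geom)
    st <- build_initial_segregated(list(chain_spec("circular", n, r),
                                        chain_spec("circular", n, r)), geom, 1)
    cfg <- mc_config(n = n, total_iterations = 6e4, discard_iterations = 0,
                     seed = 2, audit_interval = 0)
    run_mc(st, cfg)$acceptance$rate
  }, numeric(1))
  expect_true(all(rates > 0))
  expect_true(all(diff(rates) < 0))
})

test_that("3-bead chain sampling matches the rejection-sampling oracle", {
  # A free 3-bead pearl necklace: the only constraint is the hard-core
  # exclusion between beads 1 and 3, so cos(bend angle at the middle bead)
  # is uniform on [-1, 1/2]. The oracle samples bond directions uniformly
  # and rejects overlaps; the engine must reproduce its histogram.
  r <- 0.02
  geom <- spherocylinder(diameter = 8, aspect = 4)  # effectively unconfined
  a <- cbind(0, 0, -8 + c(0, 2 * r, 4 * r))
  b <- cbind(0, 0, 8 + c(0, 2 * r, 4 * r))
  st <- toy_state(a, b, r = r, geom = geom)
  cfg <- mc_config(n = 3L, total_iterations = 3e5, discard_iterations = 2e3,
                   sample_interval = 50L, s_max = 1L, seed = 11,
                   audit_interval = 0)
  cosang <- function(state) {
    x <- state$coords[[1]]
    u <- x[1, ] - x[2, ]; v <- x[3, ] - x[2, ]
    sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  }
  out <- run_mc(st, cfg, observers = list(cosa = cosang))
  mc <- out$samples$cosa
  expect_true(all(mc <= 0.5 + 1e-9))
  # rejection-sampling oracle
  set.seed(99)
  nor <- 2e5
  u1 <- matrix(rnorm(3 * nor), ncol = 3); u1 <- u1 / sqrt(rowSums(u1^2))
  u2 <- matrix(rnorm(3 * nor), ncol = 3); u2 <- u2 / sqrt(rowSums(u2^2))
  # outer beads at mid + u1 and mid + u2 (bond-length units); reject overlaps
  d13 <- sqrt(rowSums((u2 - u1)^2))
  keep <- d13 >= 1                     # 2r in bond units
  oc <- rowSums(u1 * u2)[keep]
  breaks <- seq(-1, 0.5, length.out = 9)
  p_or <- as.vector(table(cut(oc, breaks))) / length(oc)
  counts_mc <- as.vector(table(cut(mc, breaks)))
  n_mc <- length(mc)
  tau <- as.numeric(suppressWarnings(autocorrelation_time(mc)))
  n_eff <- n_mc / (2 * tau)
  for (bin in seq_along(p_or)) {
    sigma <- sqrt(p_or[bin] * (1 - p_or[bin]) / n_eff)
    expect_lt(abs(counts_mc[bin] / n_mc - p_or[bin]), 3 * sigma + 1e-3)
  }
})

test_that("compiled move decisions match the R reference path exactly", {
  # the compiled engine (cell lists, candidate-pruned sweeps) and the plain R
  # implementation (exhaustive checks) must agree move by move
  geom <- spherocylinder()
  n <- 40L
  r <- solve_bead_radius(2 * n, 0.08, geom)  # denser than the study conditions
  st <- build_initial_overlapping(list(chain_spec("circular", n, r),
                                       chain_spec("linear", n, r)), geom, 1)
  cfg <- mc_config(n = n, seed = 31)
  set.seed(31)
  checked <- 0L
  for (k in 1:1500) {
    p <- propose_crankshaft(st, cfg)
    if (length(p$moved) == 0L) next
    gmoved <- if (p$chain == 1L) p$moved else p$moved + n
    cpp <- ringmix:::cpp_decide_move(
      rbind(st$coords[[1]], st$coords[[2]]), n, n, TRUE, FALSE,
      r, geom$D, geom$L, as.integer(gmoved), p$origin, p$axis, p$theta, TRUE)
    ref <- attempt_move(st, p, check_crossing = TRUE)
    expect_identical(cpp, ref$accepted)
    checked <- checked + 1L
    if (ref$accepted) st <- ref$state
  }
  expect_gt(checked, 1000L)
  expect_identical(nrow(validate_state(st)), 0L)
})

test_that("a topology audit failure aborts the run with a diagnostic", {
  # feed the engine a Hopf-linked pair of proper pearl necklaces (bond = 2r,
  # so the non-crossing sweep preserves the link): the first scheduled audit
  # must abort the run
  fh <- topology_fixture("hopf")
  r <- sin(pi / nrow(fh[[1]]))   # tangent beads on the unit circle
  st <- toy_state(fh[[1]], fh[[2]], "circular", "circular", r = r)
  cfg <- mc_config(n = nrow(fh[[1]]), total_iterations = 10,
                   discard_iterations = 0, sample_interval = 5L,
                   audit_interval = 1L, seed = 3)
  expect_error(run_mc(st, cfg), "audit failed")
})
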