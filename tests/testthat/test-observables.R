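test_that("overlap length handles coincident, gapped and abutting extents", {
  r <- 0.05
  rod <- function(x, z0) cbind(x, 0, z0 + (0:4) * 2 * r)
  # coincident chains: lambda equals the common z-extent
  st <- toy_state(rod(0, 0), rod(0.5, 0), r = r)
  expect_equal(overlap_length(st), 8 * r)
  # an axial gap of 0.3 gives lambda = -0.3
  st <- toy_state(rod(0, 0), rod(0.5, 8 * r + 0.3), r = r)
  expect_equal(overlap_length(st), -0.3)
  # exactly abutting extents give 0
  st <- toy_state(rod(0, 0), rod(0.5, 8 * r), r = r)
  expect_equal(overlap_length(st), 0)
})

test_that("overlap length is invariant under axial rotation, equivariant under reflection", {
  geom <- spherocylinder()
  n <- 40L
  r <- solve_bead_radius(2 * n, 0.05, geom)
  st <- build_initial_segregated(list(chain_spec("circular", n, r),
                                      chain_spec("linear", n, r)), geom, 1)
  lam <- overlap_length(st)
  rot <- ringmix:::rotation_matrix(c(0, 0, 1), 1.1)
  st_rot <- st
  st_rot$coords <- lapply(st$coords, function(x) x %*% t(rot))
  expect_equal(overlap_length(st_rot), lam, tolerance = 1e-12)
  st_ref <- st
  st_ref$coords <- lapply(st$coords, function(x) { x[, 3] <- -x[, 3]; x })
  expect_equal(overlap_length(st_ref), lam, tolerance = 1e-12)
})

test_that("hand-placed fixtures reproduce exhaustive pair counts", {
  r <- 0.1
  # two 3-bead chains with exactly 2 of the 9 cross pairs below 3r
  a <- cbind(0, 0, c(0, 2 * r, 4 * r))
  b <- cbind(c(2.5 * r, 2.5 * r, 10 * r), 0, c(0, 2 * r, 0))
  st <- toy_state(a, b, r = r)
  o <- oracle_observables(st)
  crossd <- as.matrix(dist(rbind(a, b)))[1:3, 4:6]
  expect_identical(sum(crossd < 3 * r), 2L)
  expect_equal(inter_contact_probability(st), 2 / 9)
  expect_equal(inter_contact_probability(st), o$p_inter)
  # chain-swap symmetry
  st_sw <- toy_state(b, a, r = r)
  expect_equal(inter_contact_probability(st_sw), 2 / 9)
  # straight rods have zero intra-chain contacts (closest eligible pair 4r)
  rod <- cbind(0, 0, (0:9) * 2 * r)
  st_rod <- toy_state(rod, rod + 5, r = r)
  expect_equal(intra_contact_probability(st_rod, 1), 0)
  expect_equal(end_contact_probabilities(st_rod)[["p_end_intra"]], 0)
})

test_that("hairpin end beads in reach of internal beads count as contacts", {
  r <- 0.1
  # 6-bead chain folded into an isosceles trapezoid hairpin: bead 1 sits at
  # exactly 2.5r from bead 4 (a contact), 3r from bead 3 (strict cutoff:
  # not a contact); bonds are exactly 2r
  h <- sqrt(4 - 0.0625) * r
  a <- rbind(c(0, 0, 0),
             c(0.25 * r, h, 0),
             c(2.25 * r, h, 0),
             c(2.5 * r, 0, 0),
             c(4.5 * r, 0, 0),
             c(6.5 * r, 0, 0))
  b <- cbind(0, 0, 5 + (0:3) * 2 * r)
  st <- toy_state(a, b, r = r)
  expect_identical(nrow(validate_state(st)), 0L)
  ep <- end_contact_probabilities(st, chain = 1)
  # end 1 contacts bead 4 only (1 of 3 eligible); end 6 contacts nothing
  expect_equal(ep[["p_end_intra"]], mean(c(1 / 3, 0)))
  expect_equal(ep[["p_end_inter"]], 0)
})

test_that("contact probabilities match the exhaustive double-loop oracle", {
  for (topo in list(c("circular", "circular"), c("circular", "linear"),
                    c("linear", "linear"))) {
    for (seed in 1:3) {
      st <- small_system(topo, n = 30, seed = seed, iters = 6000)
      o <- oracle_observables(st)
      expect_equal(inter_contact_probability(st), o$p_inter)
      expect_equal(intra_contact_probability(st, 1), o$p_intra1)
      expect_equal(intra_contact_probability(st, 2), o$p_intra2)
      if (any(topo == "linear")) {
        ep <- end_contact_probabilities(st)
        expect_equal(ep[["p_end_inter"]], o$p_end_inter)
        expect_equal(ep[["p_end_intra"]], o$p_end_intra)
      } else {
        expect_error(end_contact_probabilities(st), "linear")
      }
    }
  }
})

test_that("intra-chain pair denominators follow the combinatorial formulas", {
  st <- small_system(c("circular", "linear"), n = 30, seed = 1, iters = 2000)
  o <- oracle_observables(st)
  expect_equal(o$intra_pairs1, 30 * 27 / 2)        # N(N-3)/2 circular
  expect_equal(o$intra_pairs2, 29 * 28 / 2)        # (N-1)(N-2)/2 linear
})

test_that("chains separated by more than the contact cutoff never touch", {
  r <- 0.05
  rod <- cbind(0, 0, (0:9) * 2 * r)
  far <- rod; far[, 3] <- far[, 3] + 10 * r + 1
  st <- toy_state(rod, far, r = r)
  expect_lt(overlap_length(st), -3 * r)
  expect_equal(inter_contact_probability(st), 0)
})

test_that("fold boost is a plain ratio of contact ratios", {
  expect_equal(fold_boost(0.01, 0.01), 1)
  expect_equal(fold_boost(0.06, 0.01), 6)
  expect_equal(fold_boost(0.01, 0.06), 1 / 6)
  expect_warning(fb <- fold_boost(0.01, 0), "not computable")
  expect_true(is.na(fb))
})
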