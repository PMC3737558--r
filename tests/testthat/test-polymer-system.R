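topo_pairs <- list(c("circular", "circular"), c("circular", "linear"),
                   c("linear", "linear"))

test_that("segregated builder yields valid states with disjoint z-intervals", {
  geom <- spherocylinder()
  for (topo in topo_pairs) {
    for (n in c(20L, 200L)) {
      r <- solve_bead_radius(2 * n, 0.05, geom)
      specs <- lapply(topo, chain_spec, n = n, r = r)
      st <- build_initial_segregated(specs, geom, seed = 1)
      expect_identical(nrow(validate_state(st)), 0L)
      expect_lt(overlap_length(st), 0)
      # determinism contract: bitwise identical coordinates
      st2 <- build_initial_segregated(specs, geom, seed = 1)
      expect_identical(st$coords, st2$coords)
    }
  }
})

test_that("overlapping builder yields valid states with coincident z-intervals", {
  geom <- spherocylinder()
  for (topo in topo_pairs) {
    n <- 200L
    r <- solve_bead_radius(2 * n, 0.05, geom)
    specs <- lapply(topo, chain_spec, n = n, r = r)
    st <- build_initial_overlapping(specs, geom, seed = 1)
    expect_identical(nrow(validate_state(st)), 0L)
    extent <- min(vapply(st$coords, function(x) diff(range(x[, 3])), 1))
    expect_gte(overlap_length(st), 0.9 * extent)
    st2 <- build_initial_overlapping(specs, geom, seed = 1)
    expect_identical(st$coords, st2$coords)
  }
})

test_that("built chains have exact bond lengths (delta bond < 1e-9 r)", {
  geom <- spherocylinder()
  n <- 100L
  r <- solve_bead_radius(2 * n, 0.05, geom)
  for (topo in topo_pairs) {
    specs <- lapply(topo, chain_spec, n = n, r = r)
    for (build in list(build_initial_segregated, build_initial_overlapping)) {
      st <- build(specs, geom, 1)
      for (k in 1:2) {
        x <- st$coords[[k]]
        idx <- if (topo[k] == "circular") c(2:n, 1L) else 2:n
        bl <- sqrt(rowSums((x[idx, ] - x[seq_along(idx), ])^2))
        expect_lt(max(abs(bl - 2 * r)), 1e-9 * r)
      }
    }
  }
})

test_that("swapping identical specs gives a z-mirrored configuration", {
  geom <- spherocylinder()
  n <- 60L
  r <- solve_bead_radius(2 * n, 0.05, geom)
  a <- build_initial_segregated(list(chain_spec("circular", n, r),
                                     chain_spec("linear", n, r)), geom, 1)
  b <- build_initial_segregated(list(chain_spec("linear", n, r),
                                     chain_spec("circular", n, r)), geom, 1)
  mirror <- function(x) { x[, 3] <- -x[, 3]; x }
  expect_equal(b$coords[[1]], mirror(a$coords[[2]]), tolerance = 1e-12)
  expect_equal(b$coords[[2]], mirror(a$coords[[1]]), tolerance = 1e-12)
})

test_that("validator pinpoints single violations in hand-built states", {
  r <- 0.05
  # straight rods, bonds exact, one bead of chain 1 outside the cap
  geom <- spherocylinder(diameter = 1, aspect = 4)
  z <- (0:4) * 2 * r
  rod1 <- cbind(0, 0, z + geom$L / 2 - 4 * 2 * r - r / 2)  # last bead protrudes
  rod2 <- cbind(0.2, 0, z - 1)
  st <- toy_state(rod1, rod2, r = r, geom = geom)
  v <- validate_state(st)
  expect_identical(nrow(v), 1L)
  expect_identical(v$type, "confinement")
  expect_identical(v$i, 5L)   # the offending bead
  # exactly one excluded-volume violation at distance 1.5 r
  a <- cbind(0, 0, c(0, 2 * r))
  b <- cbind(1.5 * r, 0, c(0, -2 * r))
  st2 <- toy_state(a, b, r = r)
  v2 <- validate_state(st2)
  expect_identical(nrow(v2), 1L)
  expect_identical(v2$type, "excluded_volume")
  expect_equal(v2$magnitude, 0.5 * r, tolerance = 1e-9)
})

test_that("state JSON dump restarts exactly and XYZ frames are well-formed", {
  geom <- spherocylinder()
  n <- 30L
  r <- solve_bead_radius(2 * n, 0.05, geom)
  specs <- list(chain_spec("circular", n, r), chain_spec("linear", n, r))
  st <- build_initial_segregated(specs, geom, 1)
  st$iteration_count <- 12345
  jf <- tempfile(fileext = ".json")
  write_state_json(st, jf)
  back <- read_state_json(jf)
  expect_equal(back$coords, st$coords, tolerance = 0)
  expect_identical(back$iteration_count, 12345)
  expect_identical(back$specs[[2]]$topology, "linear")
  xf <- tempfile(fileext = ".xyz")
  write_xyz(st, xf)
  write_xyz(st, xf, append = TRUE)
  lines <- readLines(xf)
  expect_identical(length(lines), 2L * (2L * n + 2L))
  expect_identical(lines[1], as.character(2L * n))
  expect_match(lines[2], "iteration 12345")
})

test_that("builders report packing failure for impossible densities", {
  geom <- spherocylinder()
  # an odd circular ring whose regular polygon cannot fit the container
  r <- solve_bead_radius(30, 0.05, geom)
  specs <- list(chain_spec("circular", 15L, r), chain_spec("circular", 15L, r))
  expect_error(build_initial_segregated(specs, geom, 1), "packing failure")
})
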