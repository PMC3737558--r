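#' Specification of one bead chain
#'
#' A chain is a pearl necklace of `n` hard-core beads of radius `r` with the
#' distance between consecutive bead centres fixed to `2r` (tangent spheres),
#' either closed into a ring (`"circular"`, one intact topological domain) or
#' open (`"linear"`, a domain carrying a double-strand break).
#'
#' @param topology `"circular"` or `"linear"`.
#' @param n Bead count (>= 3 circular, >= 2 linear).
#' @param r Bead radius (reduced length), usually from [solve_bead_radius()].
#' @return An object of class `chain_spec`.
#' @export
chain_spec <- function(topology = c("circular", "linear"), n, r) {
  topology <- match.arg(topology)
  if (!is.numeric(n) || length(n) != 1L || n != round(n))
    stop("'n' must be a single integer")
  n <- as.integer(n)
  if (topology == "circular" && n < 3L) stop("circular chains need n >= 3")
  if (topology == "linear" && n < 2L) stop("linear chains need n >= 2")
  if (!is.numeric(r) || length(r) != 1L || r <= 0) stop("'r' must be > 0")
  structure(list(topology = topology, n = n, r = r), class = "chain_spec")
}

#' @export
print.chain_spec <- function(x, ...) {
  cat(sprintf("chain_spec: %s, %d beads, radius %g (bond length %g)\n",
              x$topology, x$n, x$r, 2 * x$r))
  invisible(x)
}

new_system_state <- function(geometry, specs, coords, iteration_count = 0L) {
  stopifnot(inherits(geometry, "spherocylinder"), length(specs) == 2L,
            length(coords) == 2L)
  structure(list(geometry = geometry, specs = specs, coords = coords,
                 iteration_count = iteration_count),
            class = "system_state")
}

#' @export
print.system_state <- function(x, ...) {
  cat("system_state: two confined bead chains\n")
  for (k in 1:2)
    cat(sprintf("  chain %d: %s, %d beads, r = %.5g\n", k,
                x$specs[[k]]$topology, x$specs[[k]]$n, x$specs[[k]]$r))
  cat(sprintf("  container: D = %g, L = %g\n", x$geometry$D, x$geometry$L))
  cat(sprintf("  iterations performed: %g\n", x$iteration_count))
  cat(sprintf("  overlap length lambda = %.5g (lambda/L = %.5g)\n",
              overlap_length(x), overlap_length(x) / x$geometry$L))
  invisible(x)
}

# ---- lattice packing -------------------------------------------------------
# Initial configurations are built on a cubic lattice with spacing 2r so that
# every axis-aligned step is exactly one bond length and all non-bonded pairs
# are at least 2r apart.

# open boustrophedon path over an nx x ny x nz cell grid, truncated to n cells
snake_cells_open <- function(n, nx, ny, nz) {
  if (n > nx * ny * nz) return(NULL)
  cells <- matrix(0L, n, 3L)
  t <- 0L
  dir_i <- 1L; dir_j <- 1L
  for (k in seq_len(ny) - 1L) {
    js <- if (dir_j > 0L) seq_len(nz) - 1L else rev(seq_len(nz) - 1L)
    for (j in js) {
      is <- if (dir_i > 0L) seq_len(nx) - 1L else rev(seq_len(nx) - 1L)
      for (i in is) {
        t <- t + 1L
        cells[t, ] <- c(i, k, j)
        if (t == n) return(cells)
      }
      dir_i <- -dir_i
    }
    dir_j <- -dir_j
  }
  cells
}

# perimeter cycle of an ny x nz rectangle in the (y, z) cell plane
perimeter_cycle <- function(ny, nz) {
  stopifnot(ny >= 2L, nz >= 2L)
  top <- cbind(0L, seq_len(nz) - 1L)
  right <- if (ny > 2L) cbind(seq.int(1L, ny - 2L), nz - 1L) else NULL
  bottom <- cbind(ny - 1L, rev(seq_len(nz)) - 1L)
  left <- if (ny > 2L) cbind(rev(seq.int(1L, ny - 2L)), 0L) else NULL
  rbind(top, right, bottom, left)
}

# closed self-avoiding lattice cycle of n cells (n even): an (y, z) perimeter
# cycle whose cells each carry an x-sweep; consecutive sweeps pair up so the
# path returns to x = 0 before every (y, z) step at even position.
snake_cells_closed <- function(n, nx, ny_rect, nz) {
  if (n %% 2L != 0L) return(NULL)
  cyc <- perimeter_cycle(ny_rect, nz)
  T <- nrow(cyc)
  if (T %% 2L != 0L || T > n || T * nx < n) return(NULL)
  P <- T %/% 2L
  base <- (n %/% 2L) %/% P
  rem <- (n %/% 2L) - base * P
  len <- rep(base, P)
  if (rem > 0L) len[seq_len(rem)] <- base + 1L
  if (any(len > nx) || any(len < 1L)) return(NULL)
  cells <- matrix(0L, n, 3L)
  t <- 0L
  for (p in seq_len(P)) {
    c1 <- cyc[2L * p - 1L, ]; c2 <- cyc[2L * p, ]
    for (i in seq_len(len[p]) - 1L) {        # ascend in x on the first cell
      t <- t + 1L; cells[t, ] <- c(i, c1[1L], c1[2L])
    }
    for (i in rev(seq_len(len[p]) - 1L)) {   # descend on the second
      t <- t + 1L; cells[t, ] <- c(i, c2[1L], c2[2L])
    }
  }
  cells
}

# width of the lattice in x available at |y| <= ymax inside the eroded
# cross-section of radius re
lattice_nx <- function(re, ymax, s) {
  w2 <- re^2 - ymax^2
  if (w2 <= 0) return(0L)
  max(0L, as.integer(floor(2 * sqrt(w2) / s)) + 1L)
}

# cells (ix, iy, iz) -> centred coordinates; x and z centred on 0
cells_to_coords <- function(cells, s) {
  xyz <- cbind(cells[, 1L] * s, cells[, 2L] * s, -cells[, 3L] * s)
  for (col in c(1L, 3L)) {
    rng <- range(xyz[, col])
    xyz[, col] <- xyz[, col] - mean(rng)
  }
  xyz
}

# build one chain's coordinates, centred at the origin, long axis = z
build_chain_coords <- function(spec, geom, z_halfspan) {
  s <- 2 * spec$r
  re <- geom$D / 2 - spec$r
  nz <- max(2L, as.integer(floor(2 * z_halfspan / s)) + 1L)
  n <- spec$n
  if (spec$topology == "linear") {
    for (ny in 1:64) {
      ymax <- (ny - 1L) * s / 2
      nx <- lattice_nx(re, ymax, s)
      if (nx < 1L) break
      cells <- snake_cells_open(n, nx, ny, nz)
      if (!is.null(cells)) {
        xyz <- cells_to_coords(cells, s)
        xyz[, 2L] <- xyz[, 2L] - (ny - 1L) * s / 2   # centre y layers
        return(xyz)
      }
    }
  } else {
    if (n %% 2L == 1L) {
      # odd rings cannot close on the lattice: use a regular n-gon in the
      # x-z plane (side exactly 2r; non-adjacent vertices >= 2r apart)
      rp <- spec$r / sin(pi / n)
      if (rp <= re && rp <= z_halfspan) {
        phi <- 2 * pi * (seq_len(n) - 1L) / n
        return(cbind(rp * cos(phi), 0, rp * sin(phi)))
      }
    } else {
      for (ny_rect in 2:64) {
        ymax <- (ny_rect - 1L) * s / 2
        nx <- lattice_nx(re, ymax, s)
        if (nx < 1L) break
        nzr <- if (ny_rect == 2L) min(nz, max(2L, ceiling(n / (2 * nx)))) else nz
        cells <- snake_cells_closed(n, nx, ny_rect, nzr)
        if (!is.null(cells)) {
          xyz <- cells_to_coords(cells, s)
          xyz[, 2L] <- xyz[, 2L] - (ny_rect - 1L) * s / 2
          return(xyz)
        }
      }
    }
  }
  stop(sprintf(paste0("packing failure: cannot build an initial %s chain of ",
                      "%d beads (r = %g) in the available region ",
                      "(attempted density %.3g beads per unit volume)"),
               spec$topology, n, spec$r, n / geom$volume))
}

#' Build a segregated initial configuration
#'
#' Places the two chains in disjoint axial halves of the container by
#' deterministic boustrophedon packing on a lattice of spacing `2r` (closed
#' lattice cycles for circular chains), so the axial overlap length is
#' negative. The construction is deterministic; `seed` is accepted for
#' interface uniformity and recorded, but no random draw is needed.
#'
#' @param specs List of two [chain_spec()] objects.
#' @param geom A [spherocylinder()].
#' @param seed Integer seed recorded with the state.
#' @return A `system_state` passing all invariants with `overlap_length() < 0`.
#' @export
build_initial_segregated <- function(specs, geom, seed = 1L) {
  check_specs(specs, geom)
  s <- 2 * specs[[1L]]$r
  half <- (geom$L - geom$D) / 2
  out <- vector("list", 2L)
  for (k in 1:2) {
    xyz <- build_chain_coords(specs[[k]], geom, z_halfspan = (half - s) / 2)
    # shift chain 1 so its top is at -s/2, chain 2 mirrored
    xyz[, 3L] <- xyz[, 3L] - max(xyz[, 3L]) - s / 2
    if (k == 2L) xyz[, 3L] <- -xyz[, 3L]
    out[[k]] <- xyz
  }
  st <- new_system_state(geom, specs, out)
  attr(st, "seed") <- seed
  assert_buildable(st)
  st
}

#' Build a fully overlapping initial configuration
#'
#' Places the two chains on interleaved lattice layers straddling the
#' container axis so their axial extents coincide (the control start used to
#' show that circular chains segregate even from a completely mixed state).
#'
#' @inheritParams build_initial_segregated
#' @return A `system_state` whose two chains share the same z-interval.
#' @export
build_initial_overlapping <- function(specs, geom, seed = 1L) {
  check_specs(specs, geom)
  s <- 2 * specs[[1L]]$r
  half <- (geom$L - geom$D) / 2
  out <- vector("list", 2L)
  for (k in 1:2) {
    spec <- specs[[k]]
    # reserve the half cross-section y < 0 for chain 1, y > 0 for chain 2;
    # build with y shifted off-centre, then push outward by r
    xyz <- build_chain_coords_half(spec, geom, z_halfspan = half - s)
    xyz[, 2L] <- xyz[, 2L] - spec$r    # layers at -r, -3r, ...
    if (k == 2L) xyz[, 2L] <- -xyz[, 2L]
    out[[k]] <- xyz
  }
  st <- new_system_state(geom, specs, out)
  attr(st, "seed") <- seed
  assert_buildable(st)
  st
}

# variant of build_chain_coords with all y layers at or below 0
build_chain_coords_half <- function(spec, geom, z_halfspan) {
  s <- 2 * spec$r
  re <- geom$D / 2 - spec$r
  nz <- max(2L, as.integer(floor(2 * z_halfspan / s)) + 1L)
  n <- spec$n
  build <- function(nlayers, maker) {
    ymax <- spec$r + (nlayers - 1L) * s      # outermost layer after the -r shift
    nx <- lattice_nx(re, ymax, s)
    if (nx < 1L) return(NULL)
    maker(nx)
  }
  if (spec$topology == "linear") {
    for (ny in 1:64) {
      cells <- build(ny, function(nx) snake_cells_open(n, nx, ny, nz))
      if (!is.null(cells)) {
        xyz <- cells_to_coords(cells, s)
        xyz[, 2L] <- -cells[, 2L] * s    # layers at 0, -s, -2s, ...
        return(xyz)
      }
    }
  } else if (n %% 2L == 0L) {
    for (ny_rect in 2:64) {
      cells <- build(ny_rect, function(nx) {
        nzr <- if (ny_rect == 2L) min(nz, max(2L, ceiling(n / (2 * nx)))) else nz
        snake_cells_closed(n, nx, ny_rect, nzr)
      })
      if (!is.null(cells)) {
        xyz <- cells_to_coords(cells, s)
        xyz[, 2L] <- -cells[, 2L] * s
        return(xyz)
      }
    }
  } else {
    rp <- spec$r / sin(pi / n)
    if (rp <= re && rp <= z_halfspan) {
      phi <- 2 * pi * (seq_len(n) - 1L) / n
      return(cbind(rp * cos(phi), 0, rp * sin(phi)))
    }
  }
  stop(sprintf("packing failure: cannot build an overlapping %s chain of %d beads",
               spec$topology, n))
}

check_specs <- function(specs, geom) {
  if (!is.list(specs) || length(specs) != 2L ||
      !all(vapply(specs, inherits, TRUE, "chain_spec")))
    stop("'specs' must be a list of two chain_spec objects")
  stopifnot(inherits(geom, "spherocylinder"))
  if (abs(specs[[1L]]$r - specs[[2L]]$r) > 1e-12 * specs[[1L]]$r)
    stop("both chains must share the same bead radius")
  if (2 * specs[[1L]]$r >= geom$D) stop("beads do not fit in the container")
  invisible(TRUE)
}

assert_buildable <- function(state) {
  v <- validate_state(state, check_topology = FALSE)
  if (nrow(v) > 0L) {
    print(utils::head(v))
    stop("internal error: freshly built state violates invariants")
  }
  invisible(state)
}

#' Validate a system state against all hard invariants
#'
#' Checks bond lengths (`2r` within `1e-9 r`), excluded volume (all non-bonded
#' pairs at distance >= `2r`), wall containment of every bead and — optionally
#' for systems with circular chains — the topological invariants (linking
#' number 0, unknotted rings).
#'
#' @param state A `system_state`.
#' @param check_topology Also run [audit_topology()] (slower). Default TRUE.
#' @return A data frame of violations (zero rows iff the state is valid) with
#'   columns `type`, `chain`, `i`, `j`, `magnitude`.
#' @export
validate_state <- function(state, check_topology = TRUE) {
  stopifnot(inherits(state, "system_state"))
  rows <- list()
  r <- state$specs[[1L]]$r
  for (k in 1:2) {
    spec <- state$specs[[k]]
    xyz <- state$coords[[k]]
    if (nrow(xyz) != spec$n)
      stop("coordinate count does not match chain spec")
    idx2 <- if (spec$topology == "circular") c(seq_len(spec$n)[-1L], 1L)
            else seq_len(spec$n)[-1L]
    idx1 <- seq_along(idx2)
    bl <- sqrt(rowSums((xyz[idx2, , drop = FALSE] - xyz[idx1, , drop = FALSE])^2))
    bad <- which(abs(bl - 2 * spec$r) > 1e-9 * spec$r)
    for (b in bad)
      rows[[length(rows) + 1L]] <- data.frame(
        type = "bond", chain = k, i = idx1[b], j = idx2[b],
        magnitude = abs(bl[b] - 2 * spec$r))
    inside <- contains_bead(state$geometry, xyz, spec$r)
    for (b in which(!inside))
      rows[[length(rows) + 1L]] <- data.frame(
        type = "confinement", chain = k, i = b, j = NA_integer_,
        magnitude = NA_real_)
  }
  ev <- cpp_ev_violations(
    rbind(state$coords[[1L]], state$coords[[2L]]),
    state$specs[[1L]]$n, state$specs[[2L]]$n,
    state$specs[[1L]]$topology == "circular",
    state$specs[[2L]]$topology == "circular", r)
  if (length(ev$i))
    for (q in seq_along(ev$i))
      rows[[length(rows) + 1L]] <- data.frame(
        type = "excluded_volume", chain = NA_integer_,
        i = ev$i[q], j = ev$j[q], magnitude = 2 * r - ev$distance[q])
  if (check_topology && any(vapply(state$specs, function(s) s$topology, "") ==
                            "circular")) {
    aud <- audit_topology(state)
    if (!aud$pass)
      rows[[length(rows) + 1L]] <- data.frame(
        type = "topology", chain = NA_integer_, i = NA_integer_,
        j = NA_integer_, magnitude = NA_real_)
  }
  if (length(rows) == 0L)
    return(data.frame(type = character(), chain = integer(), i = integer(),
                      j = integer(), magnitude = numeric()))
  do.call(rbind, rows)
}

# ---- snapshots and restart files ------------------------------------------

#' Write a snapshot in XYZ format
#'
#' One atom record per bead; the element field carries the chain label
#' (`A`/`B`), the comment line the iteration count.
#'
#' @param state A `system_state`.
#' @param path Output file.
#' @param append Append as an additional frame.
#' @export
write_xyz <- function(state, path, append = FALSE) {
  xyz <- rbind(state$coords[[1L]], state$coords[[2L]])
  lab <- rep(c("A", "B"), c(state$specs[[1L]]$n, state$specs[[2L]]$n))
  con <- file(path, if (append) "a" else "w")
  on.exit(close(con))
  writeLines(as.character(nrow(xyz)), con)
  writeLines(sprintf("iteration %g", state$iteration_count), con)
  writeLines(sprintf("%s %.12g %.12g %.12g", lab, xyz[, 1L], xyz[, 2L], xyz[, 3L]),
             con)
  invisible(path)
}

#' Dump a system state as JSON for exact restart
#' @param state A `system_state`.
#' @param path Output file.
#' @export
write_state_json <- function(state, path) {
  obj <- list(
    geometry = list(D = state$geometry$D, aspect = state$geometry$aspect),
    specs = lapply(state$specs, function(s) list(topology = s$topology,
                                                 n = s$n, r = s$r)),
    coords = lapply(state$coords, function(m) unname(m)),
    iteration_count = state$iteration_count)
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

#' Read a system state written by [write_state_json()]
#' @param path JSON file.
#' @return A `system_state`.
#' @export
read_state_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  geom <- spherocylinder(obj$geometry$D, obj$geometry$aspect)
  specs <- lapply(obj$specs, function(s) chain_spec(s$topology, s$n, s$r))
  coords <- lapply(obj$coords, function(m)
    do.call(rbind, lapply(m, function(row) as.numeric(unlist(row)))))
  new_system_state(geom, specs, coords,
                   iteration_count = as.numeric(obj$iteration_count))
}
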