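#' Gauss linking number of two closed polygonal loops
#'
#' Exact signed solid-angle summation over all segment pairs (the discrete
#' Gauss double integral). The raw sum is rounded to the nearest integer; a
#' residual above 0.2 or a near-singular segment pair (loops closer than
#' `1e-9` of the system scale) raises an error.
#'
#' @param loop_a,loop_b Matrices (>= 3 rows, 3 columns) of loop vertices;
#'   closure between the last and first vertex is implied.
#' @return Integer linking number; attribute `residual` carries the distance
#'   of the raw sum from the returned integer.
#' @examples
#' th <- seq(0, 2 * pi, length.out = 41)[-41]
#' a <- cbind(cos(th), sin(th), 0)
#' b <- cbind(1 + cos(th), 0, sin(th))
#' linking_number(a, b)   # Hopf link: +/- 1
#' @export
linking_number <- function(loop_a, loop_b) {
  loop_a <- as_loop(loop_a); loop_b <- as_loop(loop_b)
  na <- nrow(loop_a); nb <- nrow(loop_b)
  a1 <- loop_a
  a2 <- loop_a[c(2:na, 1L), , drop = FALSE]
  b1 <- loop_b
  b2 <- loop_b[c(2:nb, 1L), , drop = FALSE]
  scale <- max(apply(rbind(loop_a, loop_b), 2L, function(v) diff(range(v))))
  # near-contact guard on vertex-to-segment distances
  mind <- min(seg_point_min_dist(a1, a2, loop_b),
              seg_point_min_dist(b1, b2, loop_a))
  if (mind < 1e-9 * scale)
    stop("loops too close to evaluate the linking number reliably")
  total <- 0
  for (i in seq_len(na)) {
    p1 <- a1[i, ]; p2 <- a2[i, ]
    r13 <- sweep(b1, 2L, p1)          # b1 - p1
    r14 <- sweep(b2, 2L, p1)
    r23 <- sweep(b1, 2L, p2)
    r24 <- sweep(b2, 2L, p2)
    n1 <- unitize(rowcross(r13, r14))
    n2 <- unitize(rowcross(r14, r24))
    n3 <- unitize(rowcross(r24, r23))
    n4 <- unitize(rowcross(r23, r13))
    om <- asin(clamp1(rowSums(n1 * n2))) + asin(clamp1(rowSums(n2 * n3))) +
          asin(clamp1(rowSums(n3 * n4))) + asin(clamp1(rowSums(n4 * n1)))
    sgn <- sign(rowSums(rowcross(b2 - b1, matrix(p2 - p1, nb, 3L,
                                                 byrow = TRUE)) * r13))
    total <- total + sum(om * sgn)
  }
  lk <- total / (4 * pi)
  res <- abs(lk - round(lk))
  if (res > 0.2)
    stop(sprintf("linking number sum %.4f is not close to an integer", lk))
  structure(as.integer(round(lk)), residual = res)
}

as_loop <- function(m) {
  m <- as.matrix(m)
  if (ncol(m) != 3L || nrow(m) < 3L)
    stop("a loop needs an n x 3 coordinate matrix with n >= 3")
  storage.mode(m) <- "double"
  m
}

rowcross <- function(a, b) {
  cbind(a[, 2L] * b[, 3L] - a[, 3L] * b[, 2L],
        a[, 3L] * b[, 1L] - a[, 1L] * b[, 3L],
        a[, 1L] * b[, 2L] - a[, 2L] * b[, 1L])
}

unitize <- function(m) {
  nm <- sqrt(rowSums(m^2))
  nm[nm == 0] <- 1     # degenerate normals contribute zero solid angle
  m / nm
}

clamp1 <- function(x) pmin(1, pmax(-1, x))

# minimum distance from any point in pts to any segment (p1[i], p2[i])
seg_point_min_dist <- function(p1, p2, pts) {
  out <- Inf
  for (i in seq_len(nrow(p1))) {
    d <- p2[i, ] - p1[i, ]
    dd <- sum(d^2)
    w <- sweep(pts, 2L, p1[i, ])
    t <- clamp01(as.vector(w %*% d) / dd)
    proj <- outer(t, d)
    out <- min(out, sqrt(min(rowSums((w - proj)^2))))
  }
  out
}

clamp01 <- function(x) pmin(1, pmax(0, x))

#' Knot test by the Alexander determinant
#'
#' Computes the knot determinant `|Delta(-1)|` of a closed polygonal curve
#' from the crossing data of a generic planar projection. The value is 1 for
#' the unknot (and any diagram of it), 3 for the trefoil and 5 for the
#' figure-eight knot. This separates the unknot from the simplest knots but is
#' not a complete invariant.
#'
#' The projection direction is drawn from a deterministic RNG stream given
#' `projection_seed`; degenerate projections are re-perturbed a bounded number
#' of times.
#'
#' @param loop An `n x 3` matrix of vertices of a simple closed polygon.
#' @param projection_seed Seed for the projection perturbation (default 1).
#' @param max_attempts Re-perturbation attempts for degenerate projections.
#' @return A list with `determinant` (numeric; `NA` if too large to represent
#'   exactly), `n_crossings`, and `unknot_compatible` (TRUE iff determinant
#'   is 1).
#' @export
knot_check <- function(loop, projection_seed = 1L, max_attempts = 20L) {
  loop <- as_loop(loop)
  n <- nrow(loop)
  edges <- loop[c(2:n, 1L), , drop = FALSE] - loop
  min_edge <- sqrt(min(rowSums(edges^2)))
  with_seed(projection_seed, {
    for (att in seq_len(max_attempts)) {
      rot <- rotation_matrix(runit3(), stats::runif(1L, 0, 2 * pi))
      # tiny vertex jitter (<< bead radius) breaks the exact collinearity of
      # lattice-built rings without changing the knot type
      jit <- matrix(stats::runif(3L * n, -1, 1) * 1e-3 * min_edge, n, 3L)
      cr <- diagram_crossings(loop %*% rot + jit)
      if (!is.null(cr)) {
        det <- alexander_determinant(cr)
        return(list(determinant = det, n_crossings = nrow(cr),
                    unknot_compatible = !is.na(det) && det == 1))
      }
    }
    stop("no generic projection found after re-perturbation attempts")
  })
}

# Crossing data of the xy-projection of a closed polygon.
# Returns a data.frame with one row per crossing: positions (cyclic curve
# parameter in [0, n)) of the under- and over-strand points, or NULL if the
# projection is degenerate.
diagram_crossings <- function(v) {
  n <- nrow(v)
  nxt <- c(2:n, 1L)
  p <- v[, 1:2, drop = FALSE]
  q <- p[nxt, , drop = FALSE]
  z1 <- v[, 3L]
  z2 <- z1[nxt]
  eps <- 1e-9
  under <- numeric(0); over <- numeric(0)
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      if (j == i + 1L || (i == 1L && j == n)) next  # adjacent edges
      d1 <- q[i, ] - p[i, ]; d2 <- q[j, ] - p[j, ]
      den <- d1[1L] * d2[2L] - d1[2L] * d2[1L]
      w <- p[j, ] - p[i, ]
      if (abs(den) < eps * (sum(abs(d1)) * sum(abs(d2)) + eps)) {
        # parallel in projection: degenerate only if they overlap
        if (abs(w[1L] * d1[2L] - w[2L] * d1[1L]) < eps) return(NULL)
        next
      }
      t <- (w[1L] * d2[2L] - w[2L] * d2[1L]) / den
      u <- (w[1L] * d1[2L] - w[2L] * d1[1L]) / den
      if (t <= -eps || t >= 1 + eps || u <= -eps || u >= 1 + eps) next
      if (t < eps || t > 1 - eps || u < eps || u > 1 - eps) return(NULL)
      zi <- z1[i] + t * (z2[i] - z1[i])
      zj <- z1[j] + u * (z2[j] - z1[j])
      if (abs(zi - zj) < eps) return(NULL)
      if (zi < zj) { under <- c(under, i - 1 + t); over <- c(over, j - 1 + u) }
      else         { under <- c(under, j - 1 + u); over <- c(over, i - 1 + t) }
    }
  }
  data.frame(under = under, over = over)
}

# Knot determinant |Delta(-1)| from crossing data, via the underpass
# presentation: row k of the Alexander matrix at t = -1 has -1 at the
# incoming arc, -1 at the outgoing arc and +2 at the overpass arc (entries
# add when the arcs coincide). The determinant is any (K-1) x (K-1) minor,
# computed exactly modulo two primes and lifted by CRT when small enough.
alexander_determinant <- function(crossings) {
  K <- nrow(crossings)
  if (K <= 1L) return(1)
  ord <- order(crossings$under)
  und <- crossings$under[ord]
  ove <- crossings$over[ord]
  # arc index of a curve position: arc k spans (und[k], und[k+1]) cyclically;
  # positions before und[1] belong to arc K
  arc_of <- function(pos) {
    k <- findInterval(pos, und)
    ifelse(k == 0L, K, k)
  }
  M <- matrix(0L, K, K)
  for (k in seq_len(K)) {
    inc <- if (k == 1L) K else k - 1L
    out <- k
    c_arc <- arc_of(ove[k])
    M[k, inc] <- M[k, inc] - 1L
    M[k, out] <- M[k, out] - 1L
    M[k, c_arc] <- M[k, c_arc] + 2L
  }
  minor <- M[-K, -K, drop = FALSE]
  p1 <- 2147483647; p2 <- 2147483629
  d1 <- cpp_moddet(minor, p1)
  d2 <- cpp_moddet(minor, p2)
  s1 <- if (d1 > p1 / 2) d1 - p1 else d1
  s2 <- if (d2 > p2 / 2) d2 - p2 else d2
  if (s1 == s2) return(abs(s1))
  NA_real_  # determinant too large to lift exactly; certainly not 1
}

#' Swept-path test for chain crossing during a crankshaft move
#'
#' Subdivides the proposed rotation into the minimum number of equal angular
#' substeps such that the largest bead displacement per substep is below one
#' bead radius (chord bound `2 R_max sin(dtheta/2) < r`), and checks the
#' excluded-volume condition at every intermediate configuration. Because
#' tangent hard beads form an impenetrable tube, a strand passage would force
#' a hard-core overlap somewhere along the sweep, which such substeps cannot
#' step over.
#'
#' @param state A `system_state`.
#' @param proposal A proposal from [propose_crankshaft()] whose endpoint
#'   configuration already passes the wall and overlap tests.
#' @return TRUE iff every intermediate configuration is overlap-free.
#' @export
crossing_free <- function(state, proposal) {
  moved <- proposal$moved
  if (length(moved) == 0L || proposal$theta == 0) return(TRUE)
  r <- state$specs[[proposal$chain]]$r
  xyz <- state$coords[[proposal$chain]]
  rel <- sweep(xyz[moved, , drop = FALSE], 2L, proposal$origin)
  along <- as.vector(rel %*% proposal$axis)
  rmax <- sqrt(max(0, rowSums(rel^2) - along^2))
  nsub <- if (rmax <= r / 2) 1L else
    max(1L, ceiling(abs(proposal$theta) / (2 * asin(min(1, r / (2 * rmax))))))
  if (nsub <= 1L) return(TRUE)
  for (k in seq_len(nsub - 1L)) {
    midstate <- apply_proposal(state, proposal, fraction = k / nsub)
    ev <- cpp_ev_violations(
      rbind(midstate$coords[[1L]], midstate$coords[[2L]]),
      state$specs[[1L]]$n, state$specs[[2L]]$n,
      state$specs[[1L]]$topology == "circular",
      state$specs[[2L]]$topology == "circular", r)
    if (length(ev$i) > 0L) return(FALSE)
  }
  TRUE
}

#' Topological audit of a system state
#'
#' Asserts that circular chains are unknotted (`|Delta(-1)| = 1`) and, for
#' circular-circular systems, that the two rings are uncatenated (linking
#' number 0). Linear-linear systems pass trivially.
#'
#' @param state A `system_state`.
#' @param projection_seed Passed to [knot_check()].
#' @return A list with `pass` and the computed invariant values.
#' @export
audit_topology <- function(state, projection_seed = 1L) {
  circ <- vapply(state$specs, function(s) s$topology == "circular", TRUE)
  lk <- NA_integer_
  dets <- rep(NA_real_, 2L)
  pass <- TRUE
  if (all(circ)) {
    lk <- linking_number(state$coords[[1L]], state$coords[[2L]])
    if (lk != 0L) pass <- FALSE
  }
  for (k in which(circ)) {
    kc <- knot_check(state$coords[[k]], projection_seed = projection_seed)
    dets[k] <- kc$determinant
    if (!isTRUE(kc$unknot_compatible)) pass <- FALSE
  }
  list(pass = pass, linking_number = lk, determinants = dets)
}

# ---- canonical fixtures ----------------------------------------------------

#' Canonical topology fixtures
#'
#' Vertex lists for test curves with known invariants: an unlinked pair and a
#' Hopf link (linking number 0 and 1), a hexagonal trefoil and a polygonal
#' figure-eight knot (knot determinants 3 and 5). The same curves ship as
#' plain-text CSV coordinate files under `system.file("extdata",
#' package = "ringmix")`.
#'
#' @param name One of `"unlinked"`, `"hopf"`, `"trefoil"`, `"figure_eight"`.
#' @return For links, a list of two vertex matrices; for knots, one matrix.
#' @export
topology_fixture <- function(name = c("unlinked", "hopf", "trefoil",
                                      "figure_eight")) {
  name <- match.arg(name)
  circle <- function(n = 40L) {
    th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
    cbind(cos(th), sin(th), 0)
  }
  switch(name,
    unlinked = {
      a <- circle()
      b <- circle(); b[, 1L] <- b[, 1L] + 10
      list(a, b)
    },
    hopf = {
      a <- circle()
      th <- seq(0, 2 * pi, length.out = 41L)[-41L]
      b <- cbind(1 + cos(th), 0, sin(th))
      list(a, b)
    },
    trefoil = {
      # minimal 6-stick trefoil: hexagon vertices visited in a star order
      # with a three-level height pattern
      phi <- c(0, 3, 1, 4, 2, 5) * pi / 3
      cbind(cos(phi), sin(phi), c(1, 0, -1, 1, 0, -1))
    },
    figure_eight = {
      t <- seq(0, 2 * pi, length.out = 33L)[-33L]
      cbind((2 + cos(2 * t)) * cos(3 * t),
            (2 + cos(2 * t)) * sin(3 * t),
            sin(4 * t))
    })
}
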