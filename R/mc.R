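#' Monte Carlo run configuration
#'
#' Bookkeeping for the Metropolis schedule. One iteration is one attempted
#' crankshaft move. Defaults follow the standard schedule for these systems:
#' discard the first `2000 N` iterations, then measure every `20 N`
#' iterations, where `N` is the per-chain bead count.
#'
#' @param n Per-chain bead count `N` used for the `20N` / `2000N` defaults.
#' @param total_iterations Total attempted moves. Default
#'   `discard_iterations + 25000 n`.
#' @param discard_iterations Equilibration moves discarded before sampling
#'   (default `2000 n`).
#' @param sample_interval Iterations between measurements (default `20 n`).
#' @param s_max Maximum crankshaft segment length in bonds (default
#'   `min(floor(n/2), 60)`).
#' @param theta_max Maximum rotation angle in radians (default `pi`,
#'   i.e. unrestricted).
#' @param seed Master seed; every random draw of the run flows from it.
#' @param audit_interval Samples between topological audits (default 50).
#' @param check_crossing Run the swept-path non-crossing test on every move
#'   (default TRUE; required whenever a circular chain is present).
#' @param snapshot_stride Record a coordinate snapshot every this many
#'   samples (0 = none).
#' @return An object of class `mc_config`.
#' @export
mc_config <- function(n,
                      total_iterations = NULL,
                      discard_iterations = 2000 * n,
                      sample_interval = 20 * n,
                      s_max = min(floor(n / 2), 60L),
                      theta_max = pi,
                      seed = 1L,
                      audit_interval = 50L,
                      check_crossing = TRUE,
                      snapshot_stride = 0L) {
  if (is.null(total_iterations))
    total_iterations <- discard_iterations + 25000 * n
  stopifnot(s_max >= 1L, s_max <= n / 2, theta_max > 0, theta_max <= pi,
            sample_interval >= 1L, discard_iterations >= 0L,
            total_iterations >= discard_iterations)
  structure(list(n = as.integer(n),
                 total_iterations = as.double(total_iterations),
                 discard_iterations = as.double(discard_iterations),
                 sample_interval = as.integer(sample_interval),
                 s_max = as.integer(s_max),
                 theta_max = theta_max,
                 seed = as.integer(seed),
                 audit_interval = as.integer(audit_interval),
                 check_crossing = isTRUE(check_crossing),
                 snapshot_stride = as.integer(snapshot_stride)),
            class = "mc_config")
}

#' Propose one crankshaft move
#'
#' Draws a move from the symmetric proposal distribution: a chain uniformly,
#' a pivot bead `i` uniformly, a segment length `s` uniform in `[1, s_max]`
#' and (for linear chains) a direction; beads strictly between the pivots
#' rotate rigidly about the pivot axis by `theta ~ Uniform(-theta_max,
#' theta_max)`. If the segment of a linear chain runs past an end, the move
#' becomes a terminal rotation of all beads beyond the single interior pivot
#' (the reflection of the out-of-range pivot at the end) about a uniformly
#' random axis through that pivot. Bead indices are 1-based.
#'
#' @param state A `system_state`.
#' @param config An [mc_config()].
#' @return A list of class `crankshaft_proposal` with fields `chain`, `pivots`
#'   (bead indices on the chain, one for terminal moves), `moved`, `origin`,
#'   `axis`, `theta`, `terminal`.
#' @export
propose_crankshaft <- function(state, config) {
  chain <- if (stats::runif(1L) < 0.5) 1L else 2L
  spec <- state$specs[[chain]]
  N <- spec$n
  smax <- min(config$s_max, N %/% 2L)
  smax <- max(smax, 1L)
  i <- sample.int(N, 1L)
  s <- sample.int(smax, 1L)
  xyz <- state$coords[[chain]]
  terminal <- FALSE
  if (spec$topology == "circular") {
    j <- (i - 1L + s) %% N + 1L
    moved <- if (s >= 2L) ((i - 1L + seq_len(s - 1L)) %% N) + 1L else integer(0)
    pivots <- c(i, j)
    origin <- xyz[i, ]
    axis <- xyz[j, ] - origin
  } else {
    dir <- if (stats::runif(1L) < 0.5) 1L else -1L
    j <- i + dir * s
    if (j >= 1L && j <= N) {
      lo <- min(i, j); hi <- max(i, j)
      moved <- if (hi - lo >= 2L) seq.int(lo + 1L, hi - 1L) else integer(0)
      pivots <- c(lo, hi)
      origin <- xyz[lo, ]
      axis <- xyz[hi, ] - origin
    } else {
      terminal <- TRUE
      p <- if (j > N) 2L * N - j else 2L - j   # reflect at the end bead
      p <- min(max(p, 1L), N)
      moved <- if (j > N) {
        if (p < N) seq.int(p + 1L, N) else integer(0)
      } else {
        if (p > 1L) seq.int(1L, p - 1L) else integer(0)
      }
      pivots <- p
      origin <- xyz[p, ]
      axis <- runit3()
    }
  }
  theta <- stats::runif(1L, -config$theta_max, config$theta_max)
  nrm <- sqrt(sum(axis^2))
  if (nrm > 0) axis <- axis / nrm
  structure(list(chain = chain, pivots = pivots, moved = moved,
                 origin = origin, axis = axis, theta = theta,
                 terminal = terminal),
            class = "crankshaft_proposal")
}

#' Apply a crankshaft proposal (unconditionally)
#'
#' Rotates the proposal's moved beads by `fraction * theta`; used both to
#' realise accepted moves and to generate the intermediate configurations of
#' the swept-path test.
#'
#' @param state A `system_state`.
#' @param proposal A `crankshaft_proposal`.
#' @param fraction Fraction of the full rotation angle to apply.
#' @return The rotated `system_state` (iteration count unchanged).
#' @export
apply_proposal <- function(state, proposal, fraction = 1) {
  if (length(proposal$moved) == 0L) return(state)
  R <- rotation_matrix(proposal$axis, proposal$theta * fraction)
  xyz <- state$coords[[proposal$chain]]
  rel <- sweep(xyz[proposal$moved, , drop = FALSE], 2L, proposal$origin)
  xyz[proposal$moved, ] <- sweep(rel %*% t(R), 2L, proposal$origin, `+`)
  state$coords[[proposal$chain]] <- xyz
  state
}

#' Attempt one Metropolis move under hard constraints
#'
#' The potential is athermal (all energies 0 or infinite), so acceptance is a
#' pure constraint test: the rotated beads must stay inside the container,
#' violate no excluded-volume pair, and pass the swept-path non-crossing test.
#' The move is applied atomically; the iteration counter increments whether
#' or not the move is accepted.
#'
#' @param state A `system_state`.
#' @param proposal A `crankshaft_proposal`.
#' @param check_crossing Run [crossing_free()] (default TRUE).
#' @return A list with `accepted` and the (possibly updated) `state`.
#' @export
attempt_move <- function(state, proposal, check_crossing = TRUE) {
  new <- apply_proposal(state, proposal)
  new$iteration_count <- state$iteration_count + 1
  if (length(proposal$moved) == 0L)
    return(list(accepted = TRUE, state = new))
  r <- state$specs[[proposal$chain]]$r
  prop_xyz <- new$coords[[proposal$chain]][proposal$moved, , drop = FALSE]
  if (!all(contains_bead(state$geometry, prop_xyz, r))) {
    state$iteration_count <- new$iteration_count
    return(list(accepted = FALSE, state = state))
  }
  ev <- cpp_ev_violations(
    rbind(new$coords[[1L]], new$coords[[2L]]),
    state$specs[[1L]]$n, state$specs[[2L]]$n,
    state$specs[[1L]]$topology == "circular",
    state$specs[[2L]]$topology == "circular", r)
  ok <- length(ev$i) == 0L
  if (ok && check_crossing) ok <- crossing_free(state, proposal)
  if (!ok) {
    state$iteration_count <- new$iteration_count
    return(list(accepted = FALSE, state = state))
  }
  list(accepted = TRUE, state = new)
}

#' Run the Metropolis Monte Carlo simulation
#'
#' Executes `total_iterations` attempted crankshaft moves through the
#' compiled engine, measuring the standard observables (overlap length and
#' the contact probabilities, see [observe_state()]) every `sample_interval`
#' iterations after the discard phase, and auditing the topological
#' invariants every `audit_interval` samples. An audit failure aborts with a
#' diagnostic state dump.
#'
#' @param state A valid `system_state` (see [build_initial_segregated()]).
#' @param config An [mc_config()]; its `seed` drives every random draw.
#' @param observers Optional named list of functions `f(state)` returning a
#'   single numeric, evaluated at every sample and appended as columns.
#' @return An object of class `mc_series`: list with `samples` (data frame),
#'   `acceptance` (rates and rejection breakdown), `audits`, `snapshots`,
#'   `final_state`, `config`.
#' @export
run_mc <- function(state, config, observers = NULL) {
  stopifnot(inherits(state, "system_state"), inherits(config, "mc_config"))
  set.seed(config$seed)
  n1 <- state$specs[[1L]]$n; n2 <- state$specs[[2L]]$n
  circ1 <- state$specs[[1L]]$topology == "circular"
  circ2 <- state$specs[[2L]]$topology == "circular"
  r <- state$specs[[1L]]$r
  geom <- state$geometry
  coords <- rbind(state$coords[[1L]], state$coords[[2L]])

  counters <- c(attempted = 0, accepted = 0, rejected_wall = 0,
                rejected_overlap = 0, rejected_sweep = 0)
  step <- function(n_iter) {
    res <- cpp_mc_chunk(coords, n1, n2, circ1, circ2, r, geom$D, geom$L,
                        as.integer(n_iter), config$s_max, config$theta_max,
                        config$check_crossing)
    coords <<- res$coords
    for (nm in names(counters)) counters[nm] <<- counters[nm] + res[[nm]]
  }
  as_state <- function(it) {
    new_system_state(geom, state$specs,
                     list(coords[seq_len(n1), , drop = FALSE],
                          coords[n1 + seq_len(n2), , drop = FALSE]),
                     iteration_count = it)
  }

  # discard phase in large chunks
  left <- config$discard_iterations
  while (left > 0) {
    chunk <- min(left, 200000)
    step(chunk)
    left <- left - chunk
  }

  n_samples <- floor((config$total_iterations - config$discard_iterations) /
                     config$sample_interval)
  rows <- vector("list", n_samples)
  snapshots <- list()
  audit_rows <- list()
  for (k in seq_len(n_samples)) {
    step(config$sample_interval)
    it <- config$discard_iterations + k * config$sample_interval
    st <- as_state(it)
    row <- observe_state(st)
    if (!is.null(observers))
      for (nm in names(observers)) row[[nm]] <- observers[[nm]](st)
    rows[[k]] <- row
    if (config$snapshot_stride > 0L && k %% config$snapshot_stride == 0L)
      snapshots[[length(snapshots) + 1L]] <- st
    if (config$audit_interval > 0L && k %% config$audit_interval == 0L &&
        (circ1 || circ2)) {
      aud <- audit_topology(st)
      audit_rows[[length(audit_rows) + 1L]] <- data.frame(
        sample = k, iteration = it, pass = aud$pass,
        linking_number = as.integer(aud$linking_number),
        det1 = aud$determinants[1L], det2 = aud$determinants[2L])
      if (!aud$pass) {
        dump <- tempfile("ringmix_audit_failure_", fileext = ".json")
        write_state_json(st, dump)
        stop(sprintf(paste0("topology audit failed at iteration %g ",
                            "(Lk = %s, determinants = %s); state dumped to %s"),
                     it, format(aud$linking_number),
                     paste(format(aud$determinants), collapse = ", "), dump))
      }
    }
  }
  samples <- if (n_samples > 0L) do.call(rbind, rows) else NULL
  acceptance <- as.list(counters)
  acceptance$rate <- if (counters[["attempted"]] > 0)
    counters[["accepted"]] / counters[["attempted"]] else NA_real_
  structure(list(samples = samples,
                 acceptance = acceptance,
                 audits = if (length(audit_rows)) do.call(rbind, audit_rows)
                          else NULL,
                 snapshots = snapshots,
                 final_state = as_state(config$total_iterations),
                 config = config),
            class = "mc_series")
}

#' @export
print.mc_series <- function(x, ...) {
  cat("mc_series: Metropolis Monte Carlo sample series\n")
  cat(sprintf("  iterations: %g (discarded %g), samples: %d\n",
              x$config$total_iterations, x$config$discard_iterations,
              if (is.null(x$samples)) 0L else nrow(x$samples)))
  cat(sprintf("  acceptance rate: %.3f\n", x$acceptance$rate))
  if (!is.null(x$audits))
    cat(sprintf("  topology audits: %d, all passed: %s\n", nrow(x$audits),
                all(x$audits$pass)))
  invisible(x)
}
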