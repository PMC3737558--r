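#' Axial overlap length of the two chains
#'
#' The overlap length `lambda` is the length of the zone over which the two
#' chains overlap along the container axis, computed from the bead-centre
#' z-coordinates: `min(zmax1, zmax2) - max(zmin1, zmin2)`. It is negative
#' when an empty axial zone separates the chains, zero when their extents
#' just touch, and up to the container length when they mix completely.
#'
#' @param state A `system_state`.
#' @return `lambda` (reduced length). Divide by `state$geometry$L` for the
#'   normalised overlap fraction.
#' @export
overlap_length <- function(state) {
  z1 <- range(state$coords[[1L]][, 3L])
  z2 <- range(state$coords[[2L]][, 3L])
  min(z1[2L], z2[2L]) - max(z1[1L], z2[1L])
}

contact_counts <- function(state) {
  cpp_contact_counts(rbind(state$coords[[1L]], state$coords[[2L]]),
                     state$specs[[1L]]$n, state$specs[[2L]]$n,
                     state$specs[[1L]]$topology == "circular",
                     state$specs[[2L]]$topology == "circular",
                     state$specs[[1L]]$r,
                     state$geometry$D, state$geometry$L)
}

#' Average inter-chain contact probability
#'
#' Two beads are in contact when their centre distance is strictly below
#' `3r`. The inter-chain contact probability is the number of contacting
#' pairs with one bead in each chain divided by all `N1 N2` such pairs.
#'
#' @param state A `system_state`.
#' @return A probability in `[0, 1]`.
#' @export
inter_contact_probability <- function(state) {
  cc <- contact_counts(state)
  cc$inter / (state$specs[[1L]]$n * state$specs[[2L]]$n)
}

#' Average intra-chain contact probability
#'
#' Counted over all non-consecutive same-chain bead pairs (for circular
#' chains the wrap-around pair is consecutive too), with the `< 3r` contact
#' criterion: `N(N-3)/2` eligible pairs for a circular chain of `N` beads,
#' `(N-1)(N-2)/2` for a linear one.
#'
#' @param state A `system_state`.
#' @param chain Chain index (1 or 2), or `NULL` (default) for the mean of
#'   both chains.
#' @return A probability in `[0, 1]`.
#' @export
intra_contact_probability <- function(state, chain = NULL) {
  cc <- contact_counts(state)
  one <- function(k) {
    spec <- state$specs[[k]]
    denom <- if (spec$topology == "circular") spec$n * (spec$n - 3) / 2
             else (spec$n - 1) * (spec$n - 2) / 2
    (if (k == 1L) cc$intra1 else cc$intra2) / denom
  }
  if (is.null(chain)) mean(c(one(1L), one(2L))) else one(chain)
}

#' End-bead contact probabilities of linear chains
#'
#' For each end bead of a linear chain: the inter-chain probability counts
#' contacts with any bead of the other chain (per-end denominator = the other
#' chain's length); the intra-chain probability counts contacts with internal
#' beads of the same chain (both terminal beads excluded) that are
#' non-consecutive to the probed end (per-end denominator `N - 3`). Both ends
#' contribute and are averaged; if both chains are linear, all four ends are
#' averaged.
#'
#' @param state A `system_state` with at least one linear chain.
#' @param chain Restrict to the ends of this chain index (1 or 2); default
#'   averages over all linear chains.
#' @return Named vector `c(p_end_inter, p_end_intra)`.
#' @export
end_contact_probabilities <- function(state, chain = NULL) {
  linear <- which(vapply(state$specs, function(s) s$topology == "linear", TRUE))
  if (length(linear) == 0L)
    stop("end_contact_probabilities requires at least one linear chain")
  if (!is.null(chain)) {
    if (!chain %in% linear) stop("chain ", chain, " is not linear")
    linear <- chain
  }
  cc <- contact_counts(state)
  p_int <- p_ina <- numeric(0)
  for (k in linear) {
    n_self <- state$specs[[k]]$n
    n_other <- state$specs[[3L - k]]$n
    p_int <- c(p_int, cc$end_inter[k, ] / n_other)
    p_ina <- c(p_ina, cc$end_intra[k, ] / (n_self - 3))
  }
  c(p_end_inter = mean(p_int), p_end_intra = mean(p_ina))
}

#' Fold boost of the end-bead contact ratio
#'
#' The factor by which the inter/intra contact ratio of the terminal beads of
#' a linear chain (system A) exceeds the inter/intra contact ratio of an
#' average bead (system B, typically the circular-circular reference):
#' `(p_end_inter / p_end_intra)_A / (p_inter / p_intra)_B`.
#'
#' @param end_ratio End-bead inter/intra contact ratio of system A.
#' @param avg_ratio Average-bead inter/intra contact ratio of system B.
#' @return The fold increase, or `NA` (with a warning) if a ratio is not a
#'   finite positive number.
#' @export
fold_boost <- function(end_ratio, avg_ratio) {
  if (!is.finite(end_ratio) || !is.finite(avg_ratio) ||
      end_ratio <= 0 || avg_ratio <= 0) {
    warning("fold boost not computable: ratios must be finite and positive")
    return(NA_real_)
  }
  end_ratio / avg_ratio
}

#' Measure all standard observables on one state
#'
#' One measurement record: overlap length (absolute and normalised by the
#' container length), the inter- and intra-chain contact probabilities (the
#' latter per chain and averaged), and — when a linear chain is present —
#' the end-bead contact probabilities.
#'
#' @param state A `system_state`.
#' @return A one-row data frame.
#' @export
observe_state <- function(state) {
  cc <- contact_counts(state)
  s1 <- state$specs[[1L]]; s2 <- state$specs[[2L]]
  lam <- overlap_length(state)
  intra_d <- function(spec)
    if (spec$topology == "circular") spec$n * (spec$n - 3) / 2
    else (spec$n - 1) * (spec$n - 2) / 2
  p1 <- cc$intra1 / intra_d(s1)
  p2 <- cc$intra2 / intra_d(s2)
  row <- data.frame(
    iteration = state$iteration_count,
    lambda = lam,
    lambda_over_L = lam / state$geometry$L,
    p_inter = cc$inter / (s1$n * s2$n),
    p_intra = (p1 + p2) / 2,
    p_intra1 = p1,
    p_intra2 = p2)
  linear <- which(c(s1$topology, s2$topology) == "linear")
  if (length(linear) > 0L) {
    ep <- end_contact_probabilities(state)
    row$p_end_inter <- ep[["p_end_inter"]]
    row$p_end_intra <- ep[["p_end_intra"]]
  } else {
    row$p_end_inter <- NA_real_
    row$p_end_intra <- NA_real_
  }
  row
}
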