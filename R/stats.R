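#' Blocking-method error bar for a correlated series
#'
#' Iterated pairwise block averaging (Flyvbjerg-Petersen): at each level
#' consecutive pairs of values are averaged, halving the series, and the
#' naive standard error of the block means is recorded. For a correlated
#' series the estimate grows with block size until blocks are effectively
#' independent and the curve plateaus; the plateau value is the error bar.
#'
#' The plateau is selected automatically as the first level whose estimate
#' agrees with the next level's to within its own statistical uncertainty
#' (`se / sqrt(2 (nblocks - 1))`), among levels retaining at least 32 blocks.
#' If no plateau is found the larger of the last eligible and the final
#' level's estimate is reported and flagged.
#'
#' @param series Numeric vector, length >= 32.
#' @return An object of class `blocking_result`: `mean`, `stderr`,
#'   `block_curve` (data frame of block_size, stderr_estimate,
#'   stderr_uncertainty, nblocks), `plateau_block_size`, `plateau_found`.
#' @examples
#' x <- rnorm(4096)
#' blocking_error(x)$stderr   # close to 1/64
#' @export
blocking_error <- function(series) {
  series <- as.numeric(series)
  if (anyNA(series) || any(!is.finite(series)))
    stop("series contains non-finite values")
  n <- length(series)
  if (n < 32L) stop("blocking needs at least 32 values")
  x <- series
  bs <- 1L
  curve <- list()
  while (length(x) >= 2L) {
    nb <- length(x)
    se <- sqrt(stats::var(x) / nb)
    curve[[length(curve) + 1L]] <- data.frame(
      block_size = bs, stderr_estimate = se,
      stderr_uncertainty = se / sqrt(2 * (nb - 1)), nblocks = nb)
    m <- nb %/% 2L
    x <- (x[2L * seq_len(m) - 1L] + x[2L * seq_len(m)]) / 2
    bs <- bs * 2L
  }
  curve <- do.call(rbind, curve)
  eligible <- which(curve$nblocks >= 32L)
  plateau <- NA_integer_
  for (l in eligible) {
    if (l == nrow(curve)) break
    if (abs(curve$stderr_estimate[l + 1L] - curve$stderr_estimate[l]) <=
        curve$stderr_uncertainty[l]) { plateau <- l; break }
  }
  if (!is.na(plateau)) {
    stderr <- curve$stderr_estimate[plateau]
    found <- TRUE
    pbs <- curve$block_size[plateau]
  } else {
    last_eligible <- if (length(eligible)) max(eligible) else 1L
    stderr <- max(curve$stderr_estimate[last_eligible],
                  curve$stderr_estimate[nrow(curve)])
    found <- FALSE
    pbs <- curve$block_size[last_eligible]
  }
  structure(list(mean = mean(series), stderr = stderr, block_curve = curve,
                 plateau_block_size = pbs, plateau_found = found),
            class = "blocking_result")
}

#' @export
print.blocking_result <- function(x, ...) {
  cat(sprintf("blocking_result: mean %.6g +/- %.3g (plateau block size %d%s)\n",
              x$mean, x$stderr, x$plateau_block_size,
              if (x$plateau_found) "" else ", no clear plateau"))
  invisible(x)
}

#' @export
plot.blocking_result <- function(x, ...) {
  graphics::plot(x$block_curve$block_size, x$block_curve$stderr_estimate,
                 log = "x", type = "b", xlab = "block size",
                 ylab = "stderr estimate",
                 main = "Blocking curve", ...)
  graphics::abline(h = x$stderr, lty = 2)
  invisible(x)
}

#' Integrated autocorrelation time
#'
#' `tau_int = 1/2 + sum_{t>=1} rho(t)`, summed with an automatic window: the
#' smallest lag `W` with `W >= c tau_int(W)`, `c = 6`. Under this convention
#' an iid series has `tau_int = 1/2`, and the effective number of independent
#' samples is `n / (2 tau_int)`.
#'
#' @param series Numeric vector (length >= 8).
#' @param c_window Window constant (default 6).
#' @return `tau_int` with attributes `window` (the lag used) and
#'   `convention` (`"iid = 0.5"`). Warns if the series is shorter than
#'   `100 tau_int` (estimate unreliable) or if no window closes.
#' @export
autocorrelation_time <- function(series, c_window = 6) {
  series <- as.numeric(series)
  if (anyNA(series) || any(!is.finite(series)))
    stop("series contains non-finite values")
  n <- length(series)
  if (n < 8L) stop("series too short for an autocorrelation time")
  x <- series - mean(series)
  v <- mean(x^2)
  if (v == 0) return(structure(0.5, window = 0L, convention = "iid = 0.5"))
  # autocovariance via FFT
  m <- 2L^ceiling(log2(2L * n))
  f <- stats::fft(c(x, rep(0, m - n)))
  ac <- Re(stats::fft(Mod(f)^2, inverse = TRUE))[seq_len(n)] / m
  rho <- ac / ac[1L]
  tau <- 0.5
  W <- 0L
  for (t in seq_len(n - 1L)) {
    tau <- tau + rho[t + 1L]
    W <- t
    if (W >= c_window * tau) break
  }
  if (W >= n - 1L)
    warning("no autocorrelation window closed; tau_int unreliable")
  if (n < 100 * tau)
    warning(sprintf("series length %d < 100 tau_int (%.1f); estimate unreliable",
                    n, tau))
  structure(max(tau, 0.5), window = W, convention = "iid = 0.5")
}
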