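#' Configuration for one simulated system
#'
#' Bundles the physical system (chain length, topology pair, volume fraction,
#' container aspect ratio) with the Monte Carlo schedule. Defaults are the
#' study conditions: volume fraction 5%, aspect ratio 4, the `2000N` discard /
#' `20N` sampling schedule and a segregated start.
#'
#' @param n Beads per chain.
#' @param topology Length-2 character vector, each `"circular"` or
#'   `"linear"` (e.g. `c("circular", "linear")` for one intact and one broken
#'   topological domain).
#' @param phi Total bead volume fraction of the container (default 0.05).
#' @param aspect Container length:diameter ratio (default 4).
#' @param initial `"segregated"` (default) or `"overlapping"` start.
#' @param seed Master seed for the run.
#' @param output_dir If non-NULL, the run writes a CSV sample series, a JSON
#'   manifest and XYZ snapshots there.
#' @param ... Further arguments passed to [mc_config()]
#'   (e.g. `total_iterations`, `s_max`, `snapshot_stride`).
#' @return An object of class `run_config`.
#' @export
run_config <- function(n = 200L,
                       topology = c("circular", "circular"),
                       phi = 0.05, aspect = 4,
                       initial = c("segregated", "overlapping"),
                       seed = 1L, output_dir = NULL, ...) {
  initial <- match.arg(initial)
  if (length(topology) != 2L ||
      !all(topology %in% c("circular", "linear")))
    stop("'topology' must be two of \"circular\"/\"linear\"")
  structure(list(n = as.integer(n), topology = topology, phi = phi,
                 aspect = aspect, initial = initial, seed = as.integer(seed),
                 output_dir = output_dir,
                 mc = mc_config(n = n, seed = seed, ...)),
            class = "run_config")
}

topology_label <- function(topology) {
  paste(substr(topology, 1L, 4L), collapse = "+")
}

#' Simulate one system and summarise its observables
#'
#' Builds the geometry (bead radius from the volume fraction), the initial
#' state and runs the Metropolis Monte Carlo schedule, returning means with
#' blocking-method error bars and integrated autocorrelation times for the
#' overlap length and all contact probabilities, together with the derived
#' inter/intra contact ratios, the `D/d` ratio, acceptance statistics and the
#' topology audit log.
#'
#' @param config A [run_config()].
#' @return An object of class `ringmix_run`; see [summary.ringmix_run()].
#' @examples
#' \donttest{
#' cfg <- run_config(n = 40, total_iterations = 2e5, seed = 7)
#' run <- run_system(cfg)
#' summary(run)
#' }
#' @export
run_system <- function(config) {
  stopifnot(inherits(config, "run_config"))
  geom <- spherocylinder(aspect = config$aspect)
  r <- solve_bead_radius(2 * config$n, config$phi, geom)
  specs <- lapply(config$topology, chain_spec, n = config$n, r = r)
  builder <- if (config$initial == "segregated") build_initial_segregated
             else build_initial_overlapping
  state <- builder(specs, geom, seed = config$seed)
  series <- run_mc(state, config$mc)
  smp <- series$samples
  obs_names <- c("lambda", "lambda_over_L", "p_inter", "p_intra",
                 "p_end_inter", "p_end_intra")
  stats_rows <- lapply(obs_names, function(nm) {
    v <- smp[[nm]]
    if (is.null(v) || all(is.na(v)))
      return(data.frame(observable = nm, mean = NA_real_, stderr = NA_real_,
                        tau_int = NA_real_))
    b <- blocking_error(v)
    tau <- suppressWarnings(autocorrelation_time(v))
    data.frame(observable = nm, mean = b$mean, stderr = b$stderr,
               tau_int = as.numeric(tau))
  })
  stats_tab <- do.call(rbind, stats_rows)
  get <- function(nm, col) stats_tab[stats_tab$observable == nm, col]
  ratio_se <- function(a, sa, b, sb) abs(a / b) * sqrt((sa / a)^2 + (sb / b)^2)
  intra_over_inter <- get("p_intra", "mean") / get("p_inter", "mean")
  intra_over_inter_se <- ratio_se(get("p_intra", "mean"), get("p_intra", "stderr"),
                                  get("p_inter", "mean"), get("p_inter", "stderr"))
  end_ratio <- get("p_end_inter", "mean") / get("p_end_intra", "mean")
  end_ratio_se <- if (is.na(end_ratio)) NA_real_ else
    ratio_se(get("p_end_inter", "mean"), get("p_end_inter", "stderr"),
             get("p_end_intra", "mean"), get("p_end_intra", "stderr"))
  out <- structure(list(
    config = config,
    geometry = geom,
    bead_radius = r,
    D_over_d = geom$D / (2 * r),
    stats = stats_tab,
    intra_over_inter = intra_over_inter,
    intra_over_inter_se = intra_over_inter_se,
    end_inter_over_intra = end_ratio,
    end_inter_over_intra_se = end_ratio_se,
    acceptance = series$acceptance,
    audits = series$audits,
    series = series),
    class = "ringmix_run")
  if (!is.null(config$output_dir)) write_run_outputs(out, config$output_dir)
  out
}

write_run_outputs <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  label <- topology_label(run$config$topology)
  base <- sprintf("%s_N%d_seed%d", gsub("\\+", "_", label),
                  run$config$n, run$config$seed)
  utils::write.csv(run$series$samples,
                   file.path(dir, paste0(base, "_series.csv")),
                   row.names = FALSE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("ringmix")),
    config = run$config[c("n", "topology", "phi", "aspect", "initial", "seed")],
    mc = unclass(run$config$mc),
    bead_radius = run$bead_radius,
    D_over_d = run$D_over_d,
    acceptance = run$acceptance)
  jsonlite::write_json(manifest, file.path(dir, paste0(base, "_manifest.json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (length(run$series$snapshots) > 0L) {
    path <- file.path(dir, paste0(base, "_trajectory.xyz"))
    for (q in seq_along(run$series$snapshots))
      write_xyz(run$series$snapshots[[q]], path, append = q > 1L)
  }
  invisible(dir)
}

#' @export
print.ringmix_run <- function(x, ...) {
  cat(sprintf("ringmix_run: %s, N = %d per chain, phi = %g, D/d = %.1f\n",
              topology_label(x$config$topology), x$config$n, x$config$phi,
              x$D_over_d))
  lam <- x$stats[x$stats$observable == "lambda_over_L", ]
  cat(sprintf("  lambda/L = %.4f +/- %.4f   acceptance %.3f\n",
              lam$mean, lam$stderr, x$acceptance$rate))
  cat(sprintf("  intra/inter contact ratio = %.3g\n", x$intra_over_inter))
  if (!is.na(x$end_inter_over_intra))
    cat(sprintf("  end-bead inter/intra ratio = %.3g\n", x$end_inter_over_intra))
  invisible(x)
}

#' Summary of a simulated system
#'
#' @param object A `ringmix_run`.
#' @param ... Unused.
#' @return A one-row data frame: system descriptors, `D/d`, mean and blocking
#'   error of `lambda/L`, the contact probabilities and derived ratios,
#'   acceptance rate and worst integrated autocorrelation time.
#' @export
summary.ringmix_run <- function(object, ...) {
  g <- function(nm, col) object$stats[object$stats$observable == nm, col]
  data.frame(
    topology = topology_label(object$config$topology),
    n = object$config$n,
    initial = object$config$initial,
    D_over_d = object$D_over_d,
    lambda_over_L = g("lambda_over_L", "mean"),
    lambda_over_L_se = g("lambda_over_L", "stderr"),
    p_inter = g("p_inter", "mean"),
    p_inter_se = g("p_inter", "stderr"),
    p_intra = g("p_intra", "mean"),
    p_intra_se = g("p_intra", "stderr"),
    intra_over_inter = object$intra_over_inter,
    intra_over_inter_se = object$intra_over_inter_se,
    p_end_inter = g("p_end_inter", "mean"),
    p_end_intra = g("p_end_intra", "mean"),
    end_inter_over_intra = object$end_inter_over_intra,
    end_inter_over_intra_se = object$end_inter_over_intra_se,
    acceptance = object$acceptance$rate,
    max_tau_int = max(object$stats$tau_int, na.rm = TRUE),
    audits_passed = is.null(object$audits) || all(object$audits$pass))
}

#' @export
plot.ringmix_run <- function(x, ...) {
  s <- x$series$samples
  graphics::plot(s$iteration, s$lambda_over_L, type = "l", col = "grey50",
                 xlab = "iteration", ylab = expression(lambda / L),
                 main = sprintf("%s, N = %d", topology_label(x$config$topology),
                                x$config$n), ...)
  graphics::lines(s$iteration, cumsum(s$lambda_over_L) / seq_along(s$lambda_over_L),
                  lwd = 2)
  graphics::legend("topleft", c("sample", "running mean"),
                   col = c("grey50", "black"), lwd = c(1, 2), bty = "n")
  invisible(x)
}

#' Catalogue of headline quantitative claims
#'
#' The package's machine-readable list of the benchmark observations it is
#' built to reproduce, with the system that produces each and whether it is
#' checked at desk scale (minutes on one CPU). The N = 1400 fold boosts
#' require far longer runs and are flagged `desk_scale = FALSE`; they are
#' only evaluated in extended runs (see [run_system()] with a custom
#' `total_iterations`).
#'
#' @return A data frame with columns `claim`, `system`, `n`, `quantity`,
#'   `expected`, `comparison`, `desk_scale`.
#' @export
reference_claims <- function() {
  data.frame(
    claim = c(
      "D/d rounds to 11 at 400 total beads, phi 0.05, aspect 4",
      "D/d rounds to 22 at 2800 total beads, phi 0.05, aspect 4",
      "circular+circular intra/inter contact ratio exceeds 100",
      "end-bead fold boost, circ+lin over circ+circ average bead, N = 200",
      "lambda/L ordering lin+lin > circ+lin > circ+circ at N = 200",
      "end-bead fold boost, circ+lin over circ+circ average bead, N = 1400",
      "end-bead fold boost, lin+lin over circ+circ average bead, N = 1400"),
    system = c("geometry", "geometry", "circ+circ", "circ+lin / circ+circ",
               "all three", "circ+lin / circ+circ", "lin+lin / circ+circ"),
    n = c(200L, 1400L, 200L, 200L, 200L, 1400L, 1400L),
    quantity = c("round(D/d)", "round(D/d)", "p_intra / p_inter",
                 "fold_boost", "lambda/L", "fold_boost", "fold_boost"),
    expected = c(11, 22, 100, 6, NA, 8, 10),
    comparison = c("eq", "eq", "ge", "approx", "order", "approx", "approx"),
    desk_scale = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE))
}

#' Run a sweep of systems and tabulate the results
#'
#' Runs each configuration independently (results do not depend on the
#' execution order; each run has its own seed) and aggregates one summary row
#' per system. Failures are recorded per row and do not stop the sweep.
#'
#' @param configs A list of [run_config()] objects.
#' @return A data frame with one row per configuration (class
#'   `ringmix_sweep`); failed runs carry the error message in `error`.
#' @export
run_sweep <- function(configs) {
  stopifnot(is.list(configs),
            all(vapply(configs, inherits, TRUE, "run_config")))
  rows <- lapply(configs, function(cfg) {
    res <- tryCatch(summary(run_system(cfg)), error = function(e) e)
    if (inherits(res, "error")) {
      data.frame(topology = topology_label(cfg$topology), n = cfg$n,
                 initial = cfg$initial, D_over_d = NA_real_,
                 lambda_over_L = NA_real_, lambda_over_L_se = NA_real_,
                 p_inter = NA_real_, p_inter_se = NA_real_,
                 p_intra = NA_real_, p_intra_se = NA_real_,
                 intra_over_inter = NA_real_, intra_over_inter_se = NA_real_,
                 p_end_inter = NA_real_, p_end_intra = NA_real_,
                 end_inter_over_intra = NA_real_,
                 end_inter_over_intra_se = NA_real_,
                 acceptance = NA_real_, max_tau_int = NA_real_,
                 audits_passed = NA, error = conditionMessage(res))
    } else {
      res$error <- NA_character_
      res
    }
  })
  out <- do.call(rbind, rows)
  class(out) <- c("ringmix_sweep", class(out))
  out
}
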