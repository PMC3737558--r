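# Shared production-length N = 200 runs for the acceptance checks; computed
# once per test session and reused across test blocks. Lengths give the
# slowest observable (the overlap length) tens to hundreds of integrated
# autocorrelation times of data after the 2000N-iteration discard.
.production <- new.env(parent = emptyenv())

production_runs <- function() {
  if (!is.null(.production$runs)) return(.production$runs)
  n <- 200L
  cfg <- function(topo, seed, prod)
    run_config(n = n, topology = topo, seed = seed,
               total_iterations = 2000 * n + prod)
  runs <- list(
    cc = run_system(cfg(c("circular", "circular"), 21L, 4.5e7)),
    cl = run_system(cfg(c("circular", "linear"), 22L, 2.5e7)),
    ll = run_system(cfg(c("linear", "linear"), 23L, 2.5e7)))
  .production$runs <- runs
  runs
}
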