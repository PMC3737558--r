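# ringmix

Monte Carlo simulation of two hard-core bead chains — circular and/or
linear — confined in a spherocylindrical container, modelling topological
domains of bacterial chromosomes. The package exists to study one question:
what changes when a closed topological domain acquires a double-strand break,
i.e. when one of two co-confined ring polymers becomes linear? Purely
entropic effects then switch the pair from a *segregated* to a *mixed*
state, which is how chromosome organisation can both keep intact domains
apart and let a broken domain reach its repair template on the sister
chromatid.

It is written for polymer/biophysics researchers who want a small,
self-contained, fully reproducible simulator with honest error bars.

## Model and observables

Each chain is a pearl necklace of `N` hard beads of radius `r` (bond length
`2r`, freely jointed, athermal). The container is a cylinder with
hemispherical caps, diameter `D = 1` (the length unit), tip-to-tip length
`L = 4D`. Bead size follows from fixing the total bead volume at a fraction
`phi = 0.05` of the container volume: `2N (4/3) pi r^3 = phi V`, so the
diameter ratio `D/d = D/2r` grows as `N^(1/3)` (11 at `N = 200` per chain,
22 at `N = 1400`).

Sampling is Metropolis Monte Carlo over crankshaft moves (rigid rotation of
a sub-chain about the axis through two pivot beads; terminal rotations at
linear chain ends) under hard constraints: excluded volume, the container
wall, and strict chain-crossing prevention by displacement-bounded swept-path
substeps, audited with exact topological invariants (Gauss linking number,
Alexander determinant `|Delta(-1)|`). Measured every `20N` iterations after a
`2000N` discard:

* overlap length `lambda = min(zmax1, zmax2) - max(zmin1, zmin2)` along the
  cylinder axis (negative when the chains are separated), reported as
  `lambda/L`;
* inter- and intra-chain contact probabilities at cutoff `3r`, and the
  end-bead variants for linear chains;
* derived ratios: the intra/inter contact ratio of a ring pair, and the
  fold boost `(p_end_inter/p_end_intra) / (p_inter/p_intra)` quantifying how
  much more a broken end mixes than an average ring bead.

Error bars use the Flyvbjerg–Petersen blocking method; integrated
autocorrelation times (`tau_int = 1/2` for iid data) are reported alongside.

## Worked example

A small mixed system (one ring, one broken domain, 60 beads per chain):

```r
library(ringmix)
cfg <- run_config(n = 60, topology = c("circular", "linear"),
                  total_iterations = 2000*60 + 1.2e6, seed = 42)
run <- run_system(cfg)
print(run)
#> ringmix_run: circ+line, N = 60 per chain, phi = 0.05, D/d = 7.6
#>   lambda/L = -0.0217 +/- 0.0186   acceptance 0.246
#>   intra/inter contact ratio = 71.9
#>   end-bead inter/intra ratio = 0.0611
```

Reading the numbers: at this short chain length (`D/d = 7.6`) the two chains
barely overlap on average (`lambda/L` near zero), an average bead is ~72
times more likely to touch its own chain than the other one, and the
terminal beads of the linear chain already show an inter/intra contact ratio
(0.061) several times the average-bead ratio of a ring pair.
`summary(run)` returns the full one-row table (means, blocking errors,
`tau_int`, audit status); `plot(run)` shows the `lambda/L` trace.

Production systems (`N = 200`, `D/d = 11`) behave as the model predicts:
two rings stay segregated (intra/inter contact ratio above 100), a
linear+ring pair mixes through the linear chain's ends (fold boost around
5–6), and mean `lambda/L` orders lin+lin > circ+lin > circ+circ outside
combined blocking errors.

A command-line front end is installed at `inst/cli/ringmix`
(`simulate`, `sweep`, `analyze`, `fixtures`), reading JSON configs and
writing CSV series, JSON manifests and XYZ snapshots.

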