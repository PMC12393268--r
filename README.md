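# fretstates

Single-molecule FRET lifetime analysis of two-state membrane-receptor
conformations, from raw photon streams to state occupancies and
donor-acceptor distances.

## The problem

A membrane receptor (the motivating case is full-length EGFR in lipid
nanodiscs) carries a donor dye on its intracellular C-terminal tail and an
acceptor in the bilayer or on a bound ATP analog. Surface-immobilized single
molecules are recorded by time-correlated single-photon counting until
photobleaching. Because energy transfer shortens the donor lifetime, the
donor microtime decay reports the tail-to-reference distance through

    E = 1 − τ_DA / τ_D          r = r₀ ((1 − E) / E)^(1/6)

with dye-pair Förster distances r₀ = 8.4 nm (SNAP-Surface 594/Cy5) or
7.5 nm (SNAP-Surface 594/Atto 647N). The intracellular domain populates a
*compact* (~8 nm) and an *open* (~12 nm) conformation, so per-bunch donor
lifetimes follow a two-component Gaussian mixture whose peak positions and
widths are shared across measurement conditions; only the open-state
amplitude a_c varies per condition:

    p_c(τ) = (1 − a_c) N(τ; μ₁, σ₁) + a_c N(τ; μ₂, σ₂),   μ₁ < μ₂

The package implements the full chain — 100-ms intensity binning, Poisson
change-point segmentation, single-bleach-step selection, FRET-level
assignment up to acceptor photobleach, 1000-photon-bunch lifetime MLE with
IRF convolution and measured background, global shared-parameter mixture
fitting, and distance conversion — plus the companion trajectory
observables (WHAM reweighting of umbrella-sampled collective variables, the
strict-16 Å lipid contact number of the ATP binding site, inter-residue
distances) and a synthetic-data generator that makes every stage testable
without any external data. It is aimed at single-molecule spectroscopists
and simulators who want a reproducible, seed-stable reference
implementation of this analysis.

## Worked example

The bundled demo simulates the physiological 30% anionic-lipid condition
without and with EGF (open-state amplitudes 0.74 and 0.96), pushes the
photon streams through the whole chain, and fits both conditions globally:

```r
library(fretstates)
report <- run_pipeline(demo_config())   # seed 1, 150 molecules/condition
report
#> Pipeline run 111734fc (seed 1, 4.8 s)
#>   POPS30_noEGF         traces 150  accepted 138  rejected  12  bunches  410
#>   POPS30_EGF           traces 150  accepted 132  rejected  18  bunches  387
#> Global two-state lifetime fit
#>   shared peaks: 1.1 ns (compact), 2.62 ns (open); widths 0.256 / 0.634 ns
#>   2 condition(s), 797 bunches, logLik -866.26
#>   open-state amplitude (%):
#>     POPS30_EGF               99
#>     POPS30_noEGF             76
#> Peak distances (nm):
#>     condition   state  peak_ns distance_nm distance_round_nm
#>  POPS30_noEGF compact 1.095767         7.7                 8
#>  POPS30_noEGF    open 2.615112        11.6                12
#>    POPS30_EGF compact 1.095767         7.7                 8
#>    POPS30_EGF    open 2.615112        11.6                12
```

Reading the output: of 150 simulated molecules per condition, those without
a clean single donor and acceptor photobleaching step are rejected (reason
codes in `report$conditions`); the survivors contribute ~400 bunch
lifetimes per condition. The global fit recovers the generating open-state
amplitudes (76% vs 0.74 generated; 99% vs 0.96) and the two shared peaks,
which convert to distances rounding to the canonical 8 nm (compact) and
12 nm (open). The EGF-induced occupancy change for a condition pair comes
from `open_amplitude_change(report$fit, "POPS30_noEGF", "POPS30_EGF")`, and
`plot(report$fit)` overlays the fitted mixture on square-root-rule
histograms.

Individual stages are plain functions (`bin_trace`, `detect_change_points`,
`filter_single_bleach`, `assign_fret_levels`, `bunch_photons`,
`fit_bunch_mle`, `fret_global_fit`, `lifetime_to_distance`, `wham_solve`,
`reweighted_average`, `contact_number`, `residue_distance`) and the fitted
object supports `print`, `summary`, `coef`, `logLik`, `predict`, `plot`,
`simulate` and `residuals`. See the vignette
`vignettes/two-state-lifetime-analysis.Rmd` for the model, parameter
defaults, generator assumptions and numerical choices.

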