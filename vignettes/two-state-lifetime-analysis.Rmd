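---
title: "Two-state conformational analysis of single-molecule FRET lifetime data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-state conformational analysis of single-molecule FRET lifetime data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fretstates)
```

## The measurement and the model

A membrane receptor reconstituted in a lipid nanodisc carries a donor dye on
its C-terminal tail and an acceptor either in the bilayer or on a bound ATP
analog. Immobilized single molecules are excited at 80 MHz and every detected
photon is recorded with its arrival time (macrotime, seconds) and its delay
after the excitation pulse (microtime, nanoseconds, TCSPC). Energy transfer
to the acceptor shortens the donor lifetime, so the donor microtime decay is
a ruler: with the donor-only reference lifetime $\tau_D$, the efficiency is

$$E = 1 - \tau_{DA}/\tau_D,$$

and the donor-acceptor distance follows from the Förster relation

$$r = r_0\left(\frac{1-E}{E}\right)^{1/6},$$

with $r_0 = 8.4$ nm for the SNAP-Surface 594/Cy5 pair and $7.5$ nm for
SNAP-Surface 594/Atto 647N.

The intracellular domain populates two conformations — a *compact* state
with the tail near the reference (~8 nm) and an *open* state (~12 nm) — so
per-molecule donor lifetimes are modelled as a two-component Gaussian
mixture. Across measurement conditions (lipid composition, ±EGF, dye pair)
the peak positions and widths are physical properties of the two states and
are therefore **shared**; only each condition's open-state amplitude $a_c$
varies:

$$p_c(\tau) = (1-a_c)\,\mathcal N(\tau;\mu_1,\sigma_1) +
              a_c\,\mathcal N(\tau;\mu_2,\sigma_2), \qquad \mu_1 < \mu_2 .$$

The analysis chain implemented here runs:

1. **Binning** (`bin_trace`): photon streams to 100-ms intensity traces,
   donor and acceptor channels.
2. **Change points** (`detect_change_points`): recursive binary segmentation
   with a Poisson likelihood-ratio statistic; a split is accepted when
   $2\,\Delta\log L$ exceeds a BIC-type penalty, $2\ln n_{\text{bins}}$ by
   default.
3. **Selection** (`filter_single_bleach`): only traces with a single
   photobleaching step in each channel survive; "bleached" means the
   terminal segment sits at or below 3× the expected background counts per
   bin.
4. **FRET levels** (`assign_fret_levels`): donor segments count as FRET
   levels until acceptor photobleaching.
5. **Lifetimes** (`bunch_photons`, `fit_bunch_mle`): consecutive bunches of
   1000 donor photons are fitted by unbinned maximum likelihood with a
   mono-exponential decay convolved with the instrument response function
   (IRF) plus a separately measured uniform background fraction.
6. **Global fit** (`fret_global_fit`): all conditions' bunch lifetimes enter
   one likelihood with shared $(\mu_1,\mu_2,\sigma_1,\sigma_2)$ and
   per-condition $a_c$; fitted peaks convert to distances through the
   relations above.

The companion trajectory observables — WHAM reweighting of umbrella-sampled
collective variables (`wham_solve`, `reweighted_average`), the 16 Å
lipid-contact number of the ATP binding site (`contact_number`) and the
residue 721 to residue 1186 distance (`residue_distance`) — share the
package's containers and are validated against analytic and brute-force
oracles.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| intensity bin width | 0.1 | s | standard binning for immobilized-molecule intensity traces |
| change-point penalty | $2\ln n_{\text{bins}}$ | — | BIC for the two parameters a split adds; ~5% trace-level false-split rate at 100 bins |
| background threshold | 3× background | counts/bin | "photobleached" is not defined numerically by the measurement; 3× separates the background band from signal levels at the default rates |
| bunch size | 1000 | photons | per-bunch lifetime precision $\approx \tau/\sqrt{1000}$, small versus the state separation |
| lifetime fit bounds | [0.05, 10] | ns | physically sensible for these dyes; estimates pinned at a bound are flagged and excluded |
| background fraction | measured | — | fixed during the fit, estimated per level from the post-donor-bleach segment rate |
| $r_0$ | 8.4 / 7.5 | nm | dye-pair Förster distances |
| $\tau_D$ | 3.0 | ns | donor-only reference; recoverable from the printed peak/distance pairs via `derive_donor_reference` (3.04 and 3.02 ns, mean 3.03, reported at the 0.1 ns precision of the inputs) |
| contact cutoff | 16 (strict `<`) | Å | just below the ATP-analog radius; counts coarse-grained bead pairs |
| ANOVA significance | 0.001 | — | condition-comparison threshold |

## The decay model and its numerics

Photon microtimes of a state with lifetime $\tau$ are an exponential decay
convolved with the IRF and folded into the $W = 12.5$ ns window (80 MHz
excitation makes wrap-around physically present; for a memoryless decay
folding and truncation-with-renormalization coincide). For a Gaussian IRF
the convolution is the exponentially modified Gaussian, evaluated in log
space through the scaled complementary error function, plus its geometric
wrap tail; tabulated IRFs are convolved numerically on a 4-ps midpoint grid.
Both routes agree to better than $10^{-3}$ ns on matched inputs (tested).
The likelihood is maximized over $\tau$ by bounded scalar search to a
$10^{-6}$ ns tolerance; the histogram representation (`build_decay_histogram`)
is for display and goodness-of-fit only.

At the reference operating point (1000 photons, $\tau = 3$ ns, IRF FWHM
0.3 ns, 5% background) the estimator is unbiased and its RMSE matches the
Cramér–Rao bound of the *actual* model, 0.126 ns — about 30% above the naive
$\tau/\sqrt{n} = 0.095$ ns because window truncation and the background both
remove information. This matters when judging per-bunch precision: no
unbiased estimator can do better under these conditions.

## The global fit

Fitting is multi-start expectation–maximization (10 seeded starts; the first
from data quantiles, the rest jittered) followed by direct BFGS maximization
of the positivity-truncated likelihood (components renormalized on
$\tau > 0$; the correction is $<10^{-3}$ for these parameter scales but keeps
the density proper). The EM log-likelihood trace is stored and asserted
non-decreasing. Identifiability is enforced by relabelling so $\mu_1 <
\mu_2$; the open amplitude is the weight of the long-lifetime component.
Standard errors come from the observed information matrix on the natural
scale. Each bunch contributes one likelihood term regardless of its parent
molecule — matching per-bunch histogramming — with per-molecule weighting
available (`weight_by = "molecule"`) but off by default.

Two caveats discovered while validating the fit are worth recording. First,
a two-component Gaussian mixture fitted to data drawn from a *single*
Gaussian does not park one amplitude at zero: the maximum-likelihood
solution splits the component or grabs a tail cluster, so a pure one-state
condition is only assigned an amplitude near one when another condition in
the global fit anchors the second peak (this is exactly what sharing peaks
across conditions is for, and is how the package tests that limit). Second,
at 500 bunches per condition the observed-information standard error of the
compact width is 4–6% of its value, so recovered widths scatter at that
scale; amplitudes, the quantity of interest, are recovered an order of
magnitude more tightly.

Display histograms use the square-root rule: `sqrt_rule_bins(n)` bins for
`n` bunches, floor 5. The fit never sees binned data.

## What the generator emulates — and what it does not

`simulate_condition` draws each molecule's state from the condition's open
fraction, its expected lifetime from the corresponding Gaussian peak
(truncated at a 0.05 ns physical floor), and simulates the photon stream as
a piecewise-constant-rate Poisson process with single-step acceptor and then
donor photobleaching, IRF-convolved folded microtimes, and uniform
background in both channels. Defaults are 2000 detected signal photons/s and
200 background photons/s per channel — plausible for a confocal setup at a
few µW but not values the measurement fixes.

Three deliberate generator choices:

* **Equalized bunch yield.** The acceptor bleach time defaults to (target
  donor photons) / (donor rate), so every molecule contributes the same
  expected number of 1000-photon bunches before acceptor bleaching. Brighter
  (open) molecules would otherwise be over-represented among bunches and the
  condition's amplitude would differ between the molecule and bunch levels;
  equalizing makes the generated amplitude the estimand of the fit at both
  levels.
* **Acceptor intensity floor.** The open-state peak (2.7 ns) lies close to
  $\tau_D$ (3.0 ns), where the true efficiency — and with it the acceptor
  count rate — approaches zero. For intensity bookkeeping the efficiency is
  floored at 0.25 so that every molecule's acceptor level clears the
  3×-background threshold and its bleach step is resolvable; microtime
  decays always use the drawn lifetime exactly.
* **Intensity-only acceptor.** Acceptor photons carry uniform microtimes;
  the analysis uses donor microtimes only, and the acceptor channel exists
  to locate its bleach step.

Not emulated: dye blinking, acceptor direct excitation, spectral crosstalk,
multi-state kinetic switching within a molecule, and diffusing-molecule
bursts (the molecules are immobilized). Passing the recovery suites
therefore shows the chain is correct and calibrated for traces with these
properties; real traces with heavy blinking or crosstalk would need the
selection stage extended, and per-molecule lifetime heterogeneity beyond
the two-state model would show up as excess width, not as a third peak.

For the MD-side observables, `simulate_umbrella_windows` draws exact samples
from $\exp(-U(x) - \tfrac{k}{2}(x-c_i)^2)$ by rejection, so WHAM output can
be checked against analytic surfaces (a $5(x^2-1)^2$ double well is
recovered to within 0.15 kT of its 5 kT barrier with 12 windows of 5000
samples); `simulate_bead_frames` places labelled beads uniformly for exact
oracle comparison of the contact count. Reproducing the measurement's
trajectory-derived contact numbers would require the original 400 µs
coarse-grained trajectories, which are out of desk scope; the module is
validated on these synthetic fixtures instead.

## Degenerate inputs and tie-breaks

* Half-open bins, segments and photon ranges everywhere; photon indices are
  0-based. Ties in the split statistic break toward the earliest bin.
* Single-bin "transitional" segments — a boundary bin containing a mid-bin
  rate change, with a rate monotonically between its neighbours' — are
  absorbed into the following segment before bleach-step classification;
  the flagged partial last bin is excluded from segmentation.
* An all-zero intensity trace segments to a single zero-rate segment; an
  empty photon trace bins to an empty intensity trace.
* Zero-variance microtime bunches pin at the lower fit bound and are
  flagged; estimates converging onto either bound are likewise flagged and
  excluded from the global fit.
* WHAM with a single unbiased window reduces exactly to the log-histogram
  free energy with uniform weights; non-overlapping adjacent windows are
  reported unconverged rather than silently reweighted.
* The 16 Å contact cutoff is strict (`<`); at exactly 16 Å a pair does not
  count. Residue distances use bead centroids, with the minimum-image
  convention applied to the centroid difference when a box is present.

## Reproducibility

Every stochastic function takes an explicit integer seed and restores the
caller's RNG state. The pipeline splits its master seed deterministically
per stage and per molecule (`child_seed`), so any single molecule can be
regenerated in isolation and a rerun with the same configuration is
bit-identical. Problem sizes used by the validation suites — 200 molecules
per condition for photon-level recovery, 500 bunches per condition for
mixture recovery, 500 replicates for estimator calibration, 12×5000 samples
for the WHAM oracle — were chosen so that statistical error sits well below
the tolerances being asserted while a full run stays interactive.

## Known limitations

* The change-point penalty is calibrated for the 100-ms binning; very short
  traces (tens of bins) have reduced step sensitivity.
* The background fraction is estimated per level from the post-bleach
  segment; for levels much brighter than background the induced error is
  negligible, but traces with background comparable to signal will blur the
  lifetime estimates.
* Peak widths are reported in nanoseconds only. A first-order propagation of
  the width through the Förster relation does not reproduce conventional
  nanometre width statements, and rather than guess an unstated mapping the
  package leaves width conversion to the user.
* 2-D WHAM is provided on a product grid; finer-structured 2-D surfaces may
  need more bins per axis than the 1-D default.
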