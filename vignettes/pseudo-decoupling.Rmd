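---
title: "Scan-weighted pseudo-decoupling: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scan-weighted pseudo-decoupling: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(srnmr)
```

## The problem

In triple-resonance experiments such as the HNCA, the usable evolution time
of the indirect ^13^C^α^ dimension is limited not by relaxation but by the
one-bond ^1^J~CαCβ~ scalar coupling (about 35 Hz): the accumulated signal of
a coupled carbon is modulated by cos(πJt), which reaches zero near 14 ms and
would fold the doublet splitting into the line if sampled further. The
practical consequence is a carbon resolution of roughly 1/8 ms ≈ 120 Hz,
too coarse to separate the C^α^ shifts that sequential backbone assignment
depends on.

## The scan-weighting model

The super-resolution (SR) trick is to cancel the cosine *experimentally*:
the number of scans accumulated at evolution time $t_1$ is made proportional
to $1/\lvert\cos(\pi J\,t_\mathrm{eff})\rvert$, where
$t_\mathrm{eff} = t_1 + 2\delta$ is the time during which the coupling is
active ($\delta$ is a fixed pulse-sequence delay; the chemical shift evolves
during $t_1$ only, so peak positions are untouched). The accumulated,
noise-free signal of the coupled spin then follows the bare exponential
$e^{-t_1/T_2}$, i.e. the doublet collapses to a singlet whose width is set
by the (much longer) sampled $t_{1,\max}$.

Two complications define the schedule:

* **The zero crossing.** At $t_\mathrm{eff} = 1/(2J)$ the required scan
  count diverges. A window of half-width `switch_margin_s` (2 ms by
  default, as in both published parameter sets) is never sampled in
  effective time: from
  $t_1^{\mathrm{switch}} = 1/(2J) - 2\delta_A - m$ onward the short delay
  $\delta_A$ is replaced by the long delay $\delta_B$, which jumps
  $t_\mathrm{eff}$ across the crossing while the $t_1$ grid itself stays
  uniform. No grid points are removed.
* **The sign change.** Past the crossing the cosine is negative; the pulse
  phase is flipped by π at the same increment, so the accumulated signal
  keeps its sign. In the schedule this is the `phase_sign` column, always
  equal to the sign of $\cos(\pi J\,t_\mathrm{eff})$.

On the far side of the switch, $t_\mathrm{eff}$ clears the crossing by
$2(\delta_B-\delta_A) - m$. For the HSQC parameters (1 ms/3 ms) this equals
the 2 ms margin; for the HNCA parameters (10 µs/2 ms) it is 1.98 ms —
20 µs less, which is the geometry the delays actually permit. The schedule
constructor verifies both clearances on every row.

## Where the boost stops

Three conventions are implemented for the high-$t_1$ tail (`boost_cap`):

* `"after-zero-crossing"` (**default**): scans are not increased once
  $t_\mathrm{eff}$ has passed $1/(2J)$; the signal then decays naturally.
  Under this convention the HNCA preset (base 4 scans, 200 increments)
  costs a mean of 4.82 scans per increment — the package's scan-budget
  report, in line with the ~4.9 average cost the method is known for.
* `"after-1/J"`: boosting continues through the inverted lobe until
  $t_\mathrm{eff} = 1/J$, where the cosine magnitude recovers to 1. This
  keeps the corrected envelope exactly exponential over the whole range
  $t_\mathrm{eff} \le 1/J$ (mean cost 5.61 for the same preset), and is the
  mode used by the oracle-equivalence tests for precisely that reason.
* `"no-cap"`: the textbook weighting applied everywhere (mean cost 7.2);
  only truly singular rows (a later cosine zero on the grid) are rejected.

The choice is a genuine convention gap — the published description scales
scans "for all $t_1$" while the schedule figure states the count is not
increased after the zero crossing — so all three are exposed; only the
default changes the budget report.

## Integer scans and the residual correction

Scan counts must be integers. The default rounding is
`max(base, round(base × weight))`; a phase-cycle-compatible mode rounds the
weight first and multiplies by the base, so counts stay multiples of a full
cycle. The per-increment mismatch is recorded as
`residual = base × weight / n_scans` and satisfies the exact bookkeeping
identity `base × weight = n_scans × residual` on every row (it stays within
(0.5, 2) by construction). Multiplying the accumulated signal by the
residual vector in the time domain — before apodization — removes the
staircase distortion of integer sampling; this residual-ratio correction is
the package's interpretation of the indirect-dimension smoothing step used
in processing pipelines, not a reimplementation of any external smoother.

```{r schedule}
p <- sr_preset("hnca-sr")
sched <- build_schedule(p)
sched
head(sched$rows[sched$rows$delta_used == "B", ], 3)
```

## What the simulator does and does not model

`simulate_interferogram()` accumulates, per increment,
$n\,s\,\sum_k a_k e^{2\pi i\Omega_k t_1}\prod_J\cos(\pi J t_\mathrm{eff})\,
e^{-t_1/T_{2,k}}$ plus complex Gaussian noise of standard deviation
$\sigma\sqrt{n}$ per component (statistically identical to summing $n$
per-scan draws; a literal per-scan mode exists for testing). Modelling
choices, all of which keep peak positions identical between conventional
and SR acquisitions:

* quadrature detection is ideal (no echo/anti-echo bookkeeping); gradient
  selection, TROSY line selection and pulse imperfections are abstracted
  away;
* the chemical shift is refocused during the 2δ element — only couplings
  evolve there;
* multiple passive couplings multiply as independent cosines (weak-coupling
  limit); strong coupling, relaxation interference and deuterium decoupling
  are out of scope.

The windowed reference (`simulate_windowed_reference()`) acquires with a
constant scan count on the same skip-aware grid and divides by
$\cos(\pi J t_\mathrm{eff})$ afterwards. Noiselessly it coincides with the
residual-corrected SR signal wherever the boost is active; with noise its
pointwise standard deviation is worse by $\sqrt{\mathrm{weight}}$, which is
the quantitative sense in which post hoc windowing loses twice the
sensitivity where the weight reaches 4.

## Processing and resolution measurement

`process_interferogram()` applies, in order: residual correction (SR data
only), optional truncation to an effective point count, the squared-cosine
window $\cos^2(\pi k/2N)$ (the SSB = 2 convention), scaling of the first
point by 0.5 (baseline-offset suppression), zero filling to
$2 \times \mathrm{zero\_fill\_factor} \times N$ complex points (default
factor 2), and a centred DFT; the real part is returned with an axis in Hz
and ppm (default carrier 176.05 MHz, ^13^C at a 700 MHz field). The
spectral integral is invariant under zero filling, which the tests use as a
normalization check.

FWHM is measured by linear interpolation of the half-maximum crossings
around the tallest peak in a window, so its resolution is one frequency
bin; component counting uses interior local maxima above a relative
threshold. The doublet-splitting estimator takes the two tallest
components; with linear peak positions the documented accuracy is one
digital-resolution bin, and on 42 ms conventional acquisitions it recovers
a 35 or 38 Hz coupling within that bin (partially overlapping doublet
components bias the apparent splitting by a few Hz, well inside the bin at
the default processing).

```{r fwhm}
spn <- spin_group(0, couplings_hz = 35, t2_s = 0.1)
conv <- build_schedule(sr_preset("hnca-conv"), "conventional")
f_conv <- measure_fwhm(process_interferogram(
  simulate_interferogram(spn, conv)), c(-250, 250))
sr <- build_schedule(sched$params)
f_sr <- measure_fwhm(process_interferogram(
  simulate_interferogram(spn, sr)), c(-250, 250))
c(conventional_hz = f_conv, sr_hz = f_sr, ratio = f_conv / f_sr)
```

The ratio above (about 4.4 for the HNCA geometry, about 4.1 for the methyl
HSQC geometry) is the four-to-fivefold resolution gain: essentially
$t_{1,\max}^{SR}/t_{1,\max}^{conv}$, with the conventional line further
broadened by its unresolved 35 Hz doublet.

A spin *without* the scheduled coupling — a glycine C^α^, which has no
C^β^ — inherits the schedule envelope instead: the phase flip and scan
boost imprint a sign change and growth the signal never compensates, and
the processed line is a doublet with sinc wiggles. The simulator reproduces
this artifact (two or more components where the conventional spectrum shows
one), with both residual-corrected and uncorrected outputs available since
the processing of the measured artifact is not uniquely defined.

## The synthetic shift generator

`generate_shift_table()` draws per-residue shifts as a built-in
random-coil mean (literature-typical values, hard-coded and documented)
plus Gaussian dispersion, default standard deviations 4.0 (N), 0.5 (H^N),
1.5 (C^α^), 1.5 (C^β^) ppm. These emulate the spread of folded-protein
shifts well enough to pose a realistic linking problem; what they do *not*
model is secondary-structure correlation along the chain, residue-type
multimodality, or any real protein's shift list, so benchmark accuracies
characterise the method's relative behaviour, not absolute performance on
real data. Glycine rows carry no C^β^, proline rows no amide entries, and
multidomain constructs are built by joining member sequences with
10-residue glycine linkers.

Peak lists follow the standard generation rules (intra + sequential C^α^
per observable amide for HNCA, sequential only for HNcoCA, C^α^/C^β^ of
the predecessor for CBCAcoNH; the N-terminal amide is unobserved). The
carbon width model is $0.66/t_{1,\max}$ plus the 35 Hz splitting for
standard experiments, i.e. about 118 Hz standard versus 17 Hz SR; the
intra:sequential HNCA intensity ratio defaults to 1:0.5 (a modelling
choice, configurable).

## The linking benchmark

`benchmark_linking()` runs the full pipeline per replicate: shifts →
peak lists → coordinate jitter with per-dimension standard deviation
FWHM/2 in ppm (peak-centre precision scales with linewidth) → strip
building by (H, N) clustering → global strip linking → truth scoring.
Linking is a linear assignment problem (maximal cardinality, then minimal
total |Δppm|, matches beyond tolerance forbidden), solved globally so
results are deterministic and order-independent; a greedy solver exists
for comparison, and an exhaustive-search oracle cross-checks the solver on
small instances in the tests. Accuracy is the percentage of strips whose
predecessor (or the absence of one) is correct — deliberately a
linking-level metric: amino-acid-type inference and full sequence
anchoring belong to the deep-learning assignment systems this benchmark
deliberately stands apart from, so its numbers are not comparable to
published automated-assignment accuracies and no such comparison is made.

The default matching tolerance is 1.5 × the condition's carbon FWHM in
ppm (≈ 2.1 standard deviations of the jitter difference), so the true
match is admitted equally often (~97%) in both conditions; the conditions
then differ only through what the method actually changes — linewidth,
hence candidate density and coordinate precision. On 100-residue chains
this yields SR accuracy well above standard in essentially every paired
replicate, and accuracy decreases from 200- to 500-residue multidomain
systems for both conditions (glycine linkers are intentionally
pathological: ten near-identical C^α^ shifts in a row).

## Problem sizes and numerical choices

Simulations throughout use the preset increment counts (200 for the HNCA
schedule, 256 for the HSQC schedule, matched-dwell conventional
references), 20 paired replicates of a 100-residue chain for the headline
benchmark and 5 replicates for each multidomain size — sizes chosen so the
entire suite runs comfortably on a laptop core while keeping Monte-Carlo
standard errors far below the effects being measured (the noise-ratio
check uses 10^4 replicates at a single increment, for a ~1% standard
error against a 5% tolerance). Degenerate inputs are defined, not
rejected: a grid that never reaches the zero crossing yields a legal
switchless schedule with monotone weights; zero matching tolerance links
nothing; an all-alanine zero-dispersion chain sends both benchmark
conditions to near-random accuracy.

## Known limitations

* The spin model is kinematic (cosine modulation × exponential decay);
  there is no density-matrix evolution, so constant-time ^15^N details,
  strong coupling and cross-correlated relaxation are invisible.
* The glycine-artifact lineshape depends on how the measured data are
  residual-corrected, which is not uniquely defined; only the qualitative
  doublet-plus-wiggles behaviour is asserted.
* The benchmark's accuracy metric is linking-level and its shift generator
  is uncorrelated Gaussian; both choices favour transparency over realism.
* File formats are documented subsets (a single NMR-STAR atom-shift loop;
  Sparky-style w1/w2/w3 lists), not full-standard parsers.
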