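# srnmr

Scan-weighted pseudo-decoupling ("super-resolution", SR) for the indirect
¹³C dimension of protein NMR experiments: schedule generation, acquisition
simulation, spectral analysis, and a sequential-assignment benchmark.

## The problem

Sequential backbone assignment leans on the HNCA experiment, which
correlates each amide ¹H–¹⁵N pair with its own and its predecessor's
¹³Cα. The usable Cα evolution time is capped near 8 ms by the one-bond
¹J<sub>CαCβ</sub> coupling (~35 Hz): the accumulated signal evolves as
cos(πJt)·e^(−t/T₂), and past the cosine's first zero the doublet
splitting corrupts the line. The resulting ~120 Hz carbon linewidth makes
Cα-based strip linking ambiguous for anything but small proteins.

## The method

SR pseudo-decoupling cancels the cosine experimentally. The number of
scans accumulated at evolution time t₁ is set to the integer nearest

&nbsp;&nbsp;&nbsp;&nbsp;NS(t₁) = NS₀ / |cos(π J t_eff)|,&nbsp;&nbsp;
t_eff = t₁ + 2δ,

where δ is a fixed pulse-sequence delay during which the coupling (but not
the chemical shift) also evolves. Near the singularity at
t_eff = 1/(2J), a 2 ms window is skipped in *effective* time: from
t₁ = 1/(2J) − 2δ_A − 2 ms onward the short delay δ_A is replaced by the
long delay δ_B, jumping t_eff across the zero crossing while the t₁ grid
stays uniform, and the pulse phase is flipped by π to absorb the cosine's
sign change. The accumulated signal then follows the bare e^(−t₁/T₂), so
the doublet collapses and the carbon dimension can be sampled 4–5× longer
(33–38 ms instead of 8 ms) for a matching gain in resolution. A
per-increment residual factor NS₀·w/NS corrects the integer-rounding
staircase during processing.

The package implements the schedule algebra, a coupled-spin interferogram
simulator (conventional, SR, and 1/cos-windowed acquisitions, with
per-scan noise accumulation), spectrum processing (squared-cosine
apodization, zero filling, FWHM/multiplet analysis), a synthetic
backbone-shift and peak-list generator, and a transparent strip-linking
benchmark that quantifies how the narrower SR lines improve sequential
assignment.

## Worked example

```r
library(srnmr)

p <- sr_preset("hnca-sr")        # J = 35 Hz, dA = 10 us, dB = 2 ms, 38 ms
switch_time(p) * 1e3
#> [1] 12.26571

sched <- build_schedule(p)
sched
#> <sr_schedule> sr, J = 35 Hz, 200 increments, t1max = 38 ms
#>   scans: total 963, mean 4.82/increment, 1.20x conventional

spn  <- spin_group(offset_hz = 0, couplings_hz = 35, t2_s = 0.1)
conv <- build_schedule(sr_preset("hnca-conv"), "conventional")
f_conv <- measure_fwhm(process_interferogram(
            simulate_interferogram(spn, conv)), c(-250, 250))
f_sr   <- measure_fwhm(process_interferogram(
            simulate_interferogram(spn, sched)), c(-250, 250))
c(conventional = f_conv, sr = f_sr, ratio = f_conv / f_sr)
#> conventional           sr        ratio
#>    129.53764     29.61140      4.37458
```

The switch at 12.27 ms (printed as 12.3 in the source parameter sets) is
where δ_A gives way to δ_B; the schedule costs a mean of 4.82 scans per
increment against the 4-scan conventional reference; and the same coupled
spin that appears as a ~130 Hz unresolved doublet after an 8 ms
conventional acquisition becomes a ~30 Hz singlet under the SR schedule —
a 4.4-fold resolution gain. The linking benchmark runs the full
shifts → peaks → jitter → strips → assignment pipeline:

```r
b <- benchmark_linking(random_protein_sequence(100, 1),
                       n_replicates = 5, seed = 1)
b$summary
#>   condition mean_accuracy sd_accuracy
#> 1  standard      11.59197   0.9888344
#> 2        sr      35.83315   4.0585824
```

SR peak lists link substantially better than standard ones on every
paired replicate; the absolute numbers are a property of the synthetic
generator and the deliberately simple linking metric (see the methods
vignette), not of any published assignment software.

A command-line wrapper with `schedule`, `simulate-fid`, `process`,
`simulate-peaks`, `benchmark` and `demo` subcommands is installed at
`system.file("cli", "srnmr.R", package = "srnmr")`.

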