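---
title: "Targeted QC screening of LC-HRMS measurement sequences"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Targeted QC screening of LC-HRMS measurement sequences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hrmsqc)
```

## The problem

LC-HRMS metabolomics campaigns routinely span hundreds of injections
over days or weeks, split into measurement sequences. Over that time
the instrument drifts: retention times shift as the column ages,
detector sensitivity changes between (and within) sequences, and the
mass calibration wanders by a few ppm. Before any biological analysis
it must be established that the data are internally consistent — or
where they are not, which files, compounds or sequences need manual
inspection or normalisation.

`hrmsqc` screens centroided mzXML runs for a user-defined list of
target features (typically a QC standard mix plus pooled-matrix QC
features) and reports, per feature and file, four basic quality
parameters: retention time, measured m/z and its mass accuracy in ppm,
integrated feature area, and optionally the carbon isotopolog ratio.
Each parameter is classified into one of four colour zones and the
whole campaign is condensed into a features-by-files overview matrix,
in the spirit of conventional univariate QC control charts — no
multivariate modelling, no batch correction, just transparent
descriptive screening.

## From raw scans to parameters

**Input.** Files are listed in sequence CSVs (`file`, optional
`sequence`, optional `acquisition_time`), one row per injection in
measurement order. Sample-type categories (blank, standard QC, matrix
QC, sample, ...) are derived from the filename prefix up to a
separator character (default `_`). Target features need at least a
name, an ion species, an expected retention time (minutes) and either
a molecular formula or an explicit target m/z.

**Theoretical m/z.** Formulas are parsed to element counts and summed
over a built-in table of most-abundant-isotope masses (¹²C = 12
exactly, ¹H = 1.0078250319, ...). Adduct m/z is
\((M + \Delta m)/|z|\) with electron-mass-correct deltas; for
\([M+H]^+\) the delta is the proton mass 1.00727646 Da. Using the
hydrogen-atom mass here is a classic half-millimass error (211.1334
instead of 211.1329 for protonated C₁₂H₁₈O₃); a regression test guards
against it.

**EIC.** For every scan the intensities of all centroids with
\(|m/z - m/z_\mathrm{target}| / m/z_\mathrm{target} \cdot 10^6 \le
\mathrm{ppm}\) are summed (closed, symmetric window). The
intensity-weighted mean of the matched centroid m/z values is kept per
scan. A binary search over the sorted centroid arrays only pre-filters
candidates; membership is decided by the ppm inequality itself, so the
extraction is exactly equivalent to a brute-force linear filter (a
property the test suite asserts bit-for-bit on random runs).

**Peak picking.** The target peak is found by the
continuous-wavelet-transform ridge approach standard for MS traces:
the EIC is convolved with Ricker (Mexican-hat) wavelets on a geometric
scale grid (default 2–32 scans, 10 steps), positive local CWT maxima
are linked across scales into ridge lines, and ridges shorter than
`min_ridge` (3) or with SNR below `min_snr` (3) are discarded. SNR is
the apex CWT coefficient over the 95th percentile of the absolute
smallest-scale coefficients, a robust noise proxy that is insensitive
to the peak itself. Among surviving candidates, the apex nearest the
expected retention time within ±`rt_tol` wins; ties go to the higher
apex. No candidate in the window is a regular *not-found* result, not
an error — it propagates into the report as a missing (red) cell.

**Boundaries and area.** Peak boundaries are placed at the minimum of
the lightly smoothed trace nearest the apex on each side, within a
window capped at ±3 best-scale scan spacings. On a clean Gaussian
flank the minimum sits at the cap (≈ ±3–5 σ, capturing > 99.5 % of the
analytic area); between co-eluting peaks it sits in the valley. We
deliberately use the *nearest minimal point* rather than the first
local minimum encountered: with a noise floor, tiny fluctuations next
to the apex otherwise truncate the peak on one side. The area is the
trapezoidal integral of the raw (not wavelet-reconstructed) intensity
between the boundaries, in counts·seconds.

**Isotopolog ratio.** When enabled, the M+1 EIC at
\(m/z + 1.00336\) Da (the ¹³C–¹²C spacing) is integrated over the same
boundaries and reported as RIA = area(M+1)/area(M). We define RIA with
M+1 in the numerator — the conventional orientation, matching
\(\mathrm{RIA} \approx n_C \cdot a_{13}/a_{12}\) (≈ 0.1298 for 12
carbons) so that it scales linearly with carbon number. The
carbon-only approximation ignores ¹⁵N, ¹⁷O and ³³S contributions to
M+1 and is therefore biased for high-heteroatom formulas; it is meant for
carbon-number plausibility checks, not formula assignment. Resolution
effects (unresolved isotopic fine structure) are likewise out of
scope.

## References, zones and summaries

Each parameter is compared against a reference:

* retention time and m/z default to the *fixed* values from the target
  list (expected tR, theoretical m/z), switchable to the data-based
  arithmetic mean of the found values;
* feature area has no theoretical value and always uses the data-based
  mean, by default **per measurement sequence** — so a between-sequence
  sensitivity step shows up in the per-sequence reference levels and
  the summary table, while within-sequence instability shows up in the
  per-file bias.

The absolute deviation is classified by three ascending limits
\((g, y, o)\): green \(\le g\), yellow \((g, y]\), orange \((y, o]\),
red \(> o\) — boundaries inclusive on the greener side. Mass accuracy
defaults to (3, 5, 8) ppm, the scheme appropriate for a well-calibrated
Orbitrap-class instrument. Retention time defaults to (6, 12, 30) s and
area bias to (20, 30, 50) %; both are ordinary working tolerances for
reversed-phase gradients and electrospray detectors and are expected
to be adjusted per assay. Summary statistics (mean, sample SD with
n−1, RSD) are computed per (feature, sequence) and per (feature,
sample category) over the found results only; not-found results are
counted separately and never enter references or means — including a
missing target as zero would corrupt the reference of every other
file.

## The synthetic campaign generator

Real raw data are bulky and instrument-specific, so validation rests
on a generator that emulates the phenomena the screener must detect,
with exact ground truth. A campaign spec defines sequences, files per
category, a feature list and the defects to inject. Each file is a
centroided MS1 run: every feature contributes a Gaussian elution
profile (default σ 5 s, apex ≈ 10⁵ counts) with an M+1 companion
centroid at the theoretical carbon isotopolog ratio; analyte centroids
carry the file's injected ppm deviation plus per-scan Gaussian jitter
(default 0.5 ppm, sub-ppm scan-to-scan precision typical of a modern
HRMS); a Poisson number of noise centroids per scan (default mean 15)
with exponential intensities exercises SNR filtering. Injectable
defects: a per-sequence detector sensitivity factor, linear tR drift
per file, and a linear ppm ramp across each sequence — the drift,
offset and sensitivity-step patterns one actually observes across
multi-week campaigns. Blank-category files contain only noise.

The defaults describe the validation conditions used throughout the
tests: two sequences of 12 standard-QC injections (plus two blanks and
two matrix QCs), 240 s runs at 1 Hz with three mid-polarity
standard-like analytes. The generator does **not** attempt realistic
chemistry: no tailing by default (an exponential tailing knob exists
for robustness experiments), no ion suppression, no matrix background,
no correlated drift between parameters. Passing the recovery tests
therefore demonstrates that the *measurement machinery* is unbiased
and precise under controlled conditions — it does not certify
performance on heavily tailing or co-eluting real-world peaks.

Determinism is part of the contract: the spec seed fixes every random
draw via per-file derived seeds, so identical specs produce
byte-identical mzXML files, and the screening pipeline itself has no
randomness.

## Numerical choices and edge cases

* The ppm window is closed; a centroid exactly on the boundary is
  included.
* All-zero EICs, flat traces, and targets outside the acquired time
  range produce not-found results that stay visible (grey/red) in
  every table.
* Unreadable files are logged and flagged missing for all targets;
  the run continues.
* A degenerate integration interval (left = right) warns and returns
  area 0.
* Zone limits must be strictly ascending and positive; configuration
  errors fail fast before any file is read.
* Retention times are seconds internally and minutes in all
  user-facing output, matching chromatographic convention.

## Problem sizes

The bundled tests and the acceptance script run on scaled-down
campaigns chosen to exercise every mechanism at desk scale: 50 seeded
Gaussian peaks for apex/area recovery, 100 random runs for the
EIC-equivalence property, and a 2 × 12-injection QC campaign (240 s
runs, three features) for defect recovery. These sizes were chosen as
the smallest that give stable recovery statistics; the pipeline itself
is linear in scans × files and handles full-length runs the same way.

## Known limitations

Untargeted feature finding, deconvolution of co-eluting isomers,
profile-mode centroiding, mzML/vendor formats, automated drift
*correction* (as opposed to detection), and multivariate QC statistics
are all out of scope. The screener answers one question quickly: are
the targeted features where they should be, at the mass, abundance and
isotope ratio they should have — and if not, where exactly does it go
wrong.
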