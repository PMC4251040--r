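---
title: "Mass-bin fingerprinting and differential profiling: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mass-bin fingerprinting and differential profiling: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of its method: the model behind
mass binning, the statistical chain, the numerical conventions, the design
choices that were genuinely open, and what the synthetic-data tests do and
do not demonstrate.

## The data model

A full-scan LC-MS run is an ordered sequence of MS1 scans; each scan is a
retention time (stored in seconds, reported in minutes at every interface)
plus parallel m/z and intensity vectors. Profile and centroid acquisitions
are treated identically as (m/z, intensity) point lists: every operation in
the package is a pure sum over points, which is valid for both, so no
centroiding is performed and none is needed. MSn scans carry fragmentation
spectra that would contaminate intensity totals; the reader drops them and
reports the count. mzML and mzXML are parsed through `mzR`'s proteowizard
backend and ANDI-MS netCDF through `ncdf4`; mzData is rejected as obsolete
rather than half-supported.

## Chromatograms and spectra

TIC (per-scan intensity sum), BPC (per-scan maximum) and EIC (per-scan sum
restricted to a mass window) all emit one point per scan on the run's own
time axis; empty scans contribute zeros rather than being skipped so any
two series from one run are directly comparable. Three conventions matter:

* **EIC windows are closed intervals** `[lo, hi]`. A practitioner asking
  for 608–610 means "the window containing the ion at 609", and quoted
  ranges like 743–744 include both endpoints. Whether such windows should
  include their endpoints is genuinely ambiguous; we adopt the closed
  reading and document that it deliberately differs from bin membership
  (below), so a window boundary placed exactly on a point mass behaves
  predictably in each context.
* **Averaged mass spectra are per-scan means**: pooled intensities over the
  RT window are divided by the number of scans in the window, so a 2-minute
  and a 10-second window around the same peak give comparable spectra.
  Points are grouped by m/z rounded to `mz_decimals` (default 2, matching
  ion-trap mass resolution; raise it for high-resolution data).
* Series report retention times in minutes; internal storage is seconds
  (the convention of the raw formats).

## Mass binning

The grid over `[mass_lo, mass_hi]` with width `s` has
`N = ceiling((mass_hi - mass_lo) / s)` bins — for an exact division simply
range/size, e.g. 700 bins for m/z 100–1500 at size 2. Membership is
half-open `[lo, hi)` with the last bin closed at `mass_hi`, so every point
belongs to exactly one bin; a bin's value is the total intensity of all
member points across all scans. Three choices deserve justification:

* **Edges are anchored at the user's `mass_lo`**, not at the instrument
  scan range: the even-numbered bin labels users quote (608_610, 706_708)
  arise from edges at `mass_lo + k*s` with `mass_lo = 100`. Anchoring at
  the user range keeps the labels predictable whatever range is requested.
* **Out-of-grid points are discarded and counted**, never clipped into the
  end bins. This keeps the conservation law auditable:
  `sum(bin values) + discarded intensity = total ion current`, a property
  the test suite checks to 1e-9 relative tolerance.
* **Per-bin EIC export uses bin membership** (half-open), not the closed
  user-EIC convention, so the exported per-bin series decompose the bin
  totals exactly. The divergence is deliberate and documented on both
  functions.

Bin size trades resolution against redundancy: below size 2 on ion-trap
data there is little resolution gain while the variable count and the
number of per-bin EIC files balloon (the export warns beyond 1000 bins).
Size 2 is therefore the default throughout; `rebin_vector()` aggregates a
fine fingerprint exactly onto any aligned coarser grid, so multi-size
comparisons need only one pass over the raw data.

## The statistics chain

Preprocessing is strictly ordered — IQR filter, sum normalization, log2,
autoscaling — and the `feature_table` carries provenance flags so that a
step applied twice or out of order is an error rather than a silent
mistake. Fold changes and significance intentionally live on different
scales:

* **Fold change** is the group-mean ratio on the *sum-normalized, pre-log*
  table, where a ratio of concentrations is meaningful.
* **p-values** are two-sided Welch t-tests on the *log2/autoscaled* table,
  where the normality and variance assumptions are closest to holding. The
  t statistic is invariant to the per-column affine map of autoscaling, so
  this equals the test on the log2 scale. Welch rather than pooled-variance
  was chosen because autoscaling equalizes total, not within-group,
  variance; with near-equal group sizes the two tests differ little, and
  Welch is the safer default. No multiple-testing correction is applied by
  default — the operating point is a raw p < 1e-10 with a 4-fold change
  requirement, which is already far more conservative than an FDR at
  conventional levels; `stats::p.adjust` can always be applied to the
  returned p-values.
* The **log2 pseudocount** is half the smallest positive value in the
  table. Binned intensities are virtually never zero on real data, but
  filtered or synthetic tables can contain zeros; the half-minimum rule is
  scale-free and preserves every row's ordering.
* The **IQR filter schedule** (5/10/25/40% by feature count, removal count
  `floor(f*N)`) mirrors common chemometrics practice of pruning harder the
  larger the table. At 700 features it removes `floor(175)` = 175
  variables; published analyses of this design sometimes quote 176 of 700,
  an off-by-one whose origin (likely one near-constant variable removed
  separately) cannot be recovered from descriptions; we implement the
  floor rule and note the discrepancy.
* **PCA** is the SVD of the column-centered matrix; explained variance is
  the squared singular values over their total, and each component's sign
  is fixed by making its largest-|loading| entry positive, so results are
  deterministic across platforms. An eigendecomposition of the covariance
  matrix serves as the independent oracle in tests (1e-8).
* **HCA** uses `1 - Pearson correlation` between item profiles with the
  Ward criterion applied to the unsquared dissimilarities (`hclust`
  `"ward.D"`). Applying Ward to squared distances (`ward.D2`) is equally
  defensible; we fix the unsquared variant so dendrogram heights are
  reproducible, and report heights exactly as computed. Items with zero
  variance have no defined correlation and raise an error naming the item.

`run_group_analysis()` chains all stages, writes five CSVs and three PNGs,
and returns the intermediate objects, so the one-call route and the manual
stage-by-stage route are interchangeable (a property the tests assert).

## The synthetic generator

The generator emulates what the method needs from real data, not the data
itself. Each ion is a Gaussian chromatographic peak: intensity
`A * exp(-(t - t0)^2 / (2 * sigma^2))` at its m/z in every scan (a 7-point
Gaussian profile in the mass dimension when `mz_sigma > 0`, weights
normalized to conserve total intensity). Baseline noise is exponential —
non-negative and heavier-tailed than Gaussian, as ion-trap baselines are —
scattered uniformly in m/z.

The default two-group study fixes the conditions the quantitative tests
run under: 12 vs 11 samples (an unbalanced design after losing one
replicate, common in practice), 61 scans at 10 s spacing, 30 shared ions
with apex amplitudes drawn log-uniformly from 1e4–1e5 and retention widths
of 8 s, 10 spiked ions of amplitude 4e3 placed at centers of otherwise
unused bins and multiplied 8-fold in group A, log-normal per-peak replicate
variation at 15% CV, and 150 baseline points per scan with mean set so a
scan's baseline totals ~1% of the largest apex. Two of these choices are
load-bearing and worth making explicit:

* The spiked ions carry only ~5% of the total ion current, so after sum
  normalization the 8-fold spike appears as a fold change near 6 in the
  spiked bins and a mild global depression (FC ≈ 0.7) in every null bin.
  This is exactly the compositional side effect sum normalization has on
  real one-sided designs, and the volcano thresholds must (and do) tolerate
  it.
* All randomness is drawn before the effect fold is applied, so studies
  differing only in effect size share every other number — which is what
  makes the effect-monotonicity property testable on a fixed seed.

Problem sizes in the test suite (20 replicates of the 23-sample study for
the recovery and null suites, single runs for conservation and refinement)
keep the full suite under half a minute while leaving the recovery margins
wide; they are not near any statistical edge.

**What passing these tests shows** — that the implementation is correct:
intensities are conserved, grids refine exactly, the statistics match
independent oracles, and under the stated generative model the chain
recovers a known 8-fold effect with perfect group separation and no false
positives. **What it does not show** — performance on real data, where
peaks tail, retention drifts, baselines wander, ion suppression couples
features, and isotopes/adducts/dimers make bins of one metabolite strongly
correlated. The generator deliberately omits all of these (RT drift is
irrelevant by construction, since binning discards the time axis; the
others are limitations shared with any binning approach).

## Known limitations

* Bins are coarse: co-eluting isobars and ions < `bin_size` apart merge,
  and one metabolite's isotopes/adducts occupy several correlated bins.
  Binning finds discriminating *mass ranges*; identifying the metabolite
  behind one still requires inspecting the bin's EIC and spectra.
* Sum normalization shifts null features in the presence of a strong
  one-sided signal (above); fold changes are best read as relative to the
  sample's total signal.
* The IQR filter's schedule is a heuristic; with very few samples the IQR
  itself is noisy.
* `ward.D` heights are not comparable to `ward.D2` heights; compare
  dendrograms only within one convention.
* Vendor raw formats and mzData are not read; convert to mzML first.
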