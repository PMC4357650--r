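---
title: "Methods behind glycoMSI: from glycan masses to DIPPS maps"
author: "glycoMSI maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind glycoMSI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glycoMSI)
```

# The experiment this package models

Formalin fixation cross-links the tissue proteome, so N-linked glycans can
be released in place by printing PNGase F onto an FFPE section without the
analytes delocalising. MALDI-TOF spectra acquired over PNGase F-treated and
buffer-control regions then differ in exactly the peaks contributed by the
released glycans. `glycoMSI` covers the downstream data analysis: deciding
which peak groups are glycan candidates, how confidently their masses match
glycan compositions, and where in the tissue they occur.

# Glycan mass arithmetic

A composition is a count vector over five monosaccharide classes — hexose,
N-acetylhexosamine, deoxyhexose (fucose), NeuAc and NeuGc — with monoisotopic
dehydrated residue masses 162.052824, 203.079373, 146.057909, 291.095417 and
307.090331 Da. A free glycan carries one extra water (18.010565 Da), so the
all-zero composition legitimately weighs one water. Ion forms are derived
increments:

* `[M+Na]+`: + sodium − one electron (22.9892214 Da). The electron mass
  (0.0005486 Da) matters at the 4-decimal agreement the mass tables are
  quoted to.
* glycosylamine `[M+Na]+`: −0.984016 Da (OH → NH2 at the reducing-end
  HexNAc); released glycans initially retain the amine, which produces the
  characteristic ~1 Da doublets between fresh and hydrolysed forms.
* reduced alditols (borohydride-opened ring, +2.015650 Da) as `[M−H]−` and
  `[M−2H]2−` for negative-mode LC-MS cross-referencing.

Constants are CODATA/IUPAC monoisotopic values to six decimals. Annotation
(`annotateMass`) scans every (library record, ion form) pair, keeps matches
inside a signed ppm tolerance, and sorts by absolute error; averages of ppm
errors over mass sets use the mean of absolute values. The bundled
`kidney_glycans.csv` library holds the murine-kidney compositions
reconstructed from the published composition names and the mass arithmetic
itself; one reported m/z value (2067.747) admits no composition over the
five classes within ~400 ppm and is therefore not in the library. Note that
recomputing the mean absolute ppm error of the nine published imaging AWM
masses against their computed sodiated masses gives 34.6 ppm; the
originally reported figure (38.7 ppm) is not recoverable from the printed
masses under any rounding or sign convention we tried, and the package
reports what it computes.

# Preprocessing

**TopHat baseline.** The baseline estimate is the grayscale opening
(erosion, then dilation, flat window) of the profile; subtracting it leaves
nonnegative residuals and preserves any peak narrower than the window. The
window is expressed in points (default 101) because sampling density, not
m/z, sets the scale of baseline structure; it should stay wider than an
isotope envelope so envelopes are not flattened.

**Normalisation.** TIC divides by the intensity sum (output sums to 1), RMS
by the root mean square (output RMS 1). Both are idempotent; an all-zero
spectrum has no defined normalisation and errors.

**Profile reduction.** Vendor tools reduce raw profiles to a fixed point
count before display; the reduction method is unspecified, so `glycoMSI`
uses interval-maximum resampling, chosen because max-pooling can never lose
a peak apex (at the cost of slightly inflating noise plateaus).

**Recalibration.** External calibration is refined by a quadratic
least-squares fit mapping observed calibrant masses to the three-component
standard's sodiated masses (matched within 500 ppm). Three pairs
interpolate exactly; the fitted curve must be monotone over the acquisition
range (checked via its derivative at the range ends) so peak order is
preserved. When several calibrant spots are available the fit with the
smallest maximum absolute residual is the natural "best" choice.

**Binning.** Half-open `[lo, hi)` bins of fixed width (default 0.5 Da, the
conventional interval for TOF imaging summaries) with intensity summed per
spot; total in-range intensity is conserved. The result is a
`SummarizedExperiment` (bins × spots) so spot metadata travels with the
matrix. Grid conventions, stated once and used everywhere: 0-based
coordinates, x rightward, y downward; the acquisition range (default
800–4500 m/z, mirroring matrix suppression below 800) is enforced on read.

# Peak grouping and candidate filters

Pooled peaks are sorted by m/z and cut at gaps larger than the linkage
distance (default 0.1 Da). In one dimension this gap-cut is exactly
single-linkage agglomerative clustering with the dendrogram cut at the
linkage height — the only linkage interpretation with a unique 1-D result —
and the suite verifies the equivalence against `stats::hclust` on a
thousand random instances. Each group's mass is the abundance-weighted mean
(AWM) of member m/z with S/N as weights; AWM is invariant to peak order and
to rescaling all weights, and a group whose S/N values are all zero falls
back to the unweighted mean and is flagged. Occurrence counts spots, not
peaks (a spot's duplicate peaks count once), so proportions are bounded by
one.

Candidate filters follow the published thresholds with inclusive
comparisons: profiling candidates need ≥2 treated spots, ≤1 control spot
and AWM > 1000 m/z (the conservative variant raises the treated minimum to
4); imaging analytes need ≥100 spectra in total. Spot counting (rather than
section counting) is used because a 16-spot condition matches the published
15/16 worked example.

# DIPPS

For group g, `DIPPS(g) = p̂_t(g) − p̂_c(g)`, the difference between the
proportions of treated and control spectra exhibiting g. It is bounded in
[−1, 1], zero for treatment-indifferent analytes, and antisymmetric under
label swap. Ranking is by descending DIPPS with ties broken by ascending
AWM for determinism. Two selection modes exist, mirroring the published
use of both a user-selected count and a data-dependent rule:

* **top-N** — the N highest-ranked groups;
* **heuristic cutoff** — every observed DIPPS value is tried as cutoff c;
  the DIPPS map of the selected set is scored by its per-group-normalised
  occupancy contrast (mean count in treated spots minus mean count in
  control spots, divided by the selection size) and the maximising c wins,
  larger c on ties. The originally referenced heuristic is unpublished;
  this occupancy-contrast rule is one admissible data-dependent choice,
  not a reproduction.

DIPPS maps count, per spot, how many selected groups have a peak there; log
ion-intensity maps use `log1p` so absent spots stay at exactly zero.
No multiple-testing calibration is attached to DIPPS — it is a ranking
statistic, not a test.

# Multivariate summaries

**Segmentation.** Bisecting k-means under correlation distance
(1 − Pearson): starting from one segment, the leaf with the highest inertia
(summed correlation distance to the leaf mean spectrum) is split by 2-means
until the requested number of leaves. Each split runs `stats::kmeans` with
5 restarts on row-standardised spectra, where squared Euclidean distance is
proportional to correlation distance. Zero-variance spots have no
correlation geometry and are excluded with a message. Every cut of the tree
is a partition, and splits refine previous cuts. Commercial MSI software
couples segmentation with proprietary "strong smoothing"; the optional 3×3
median filter on maps (`medianFilterMap`) is a deliberately simple,
non-equivalent substitute.

**pLSA.** The binned matrix is factorised as the multinomial aspect model
p(spot, bin) = Σ_z p(z) p(spot|z) p(bin|z), fit by EM from a random
initialisation (seeded), stopping when the log-likelihood gain falls below
1e-8 per unit of total intensity or at 500 iterations. The likelihood is
nondecreasing by construction and the trace is stored. Numerical choices:
mixture probabilities are floored at 1e-300 before forming E-step ratios so
that components vanishing on a cell contribute exactly zero rather than
NaN; spots with zero total intensity are excluded from the fit and shown as
missing in maps; all-zero bins get zero probability. With k = 1 the model
collapses to the row/column marginals, a closed form the tests check.
Component maps show the per-spot posterior p(z|spot), which sums to one
across components.

# The phantom generator

The generator exists so every stage has ground truth. The default phantom
is a 60 × 40 grid holding an elliptical "kidney" section — a cortex annulus
around a medulla core, all PNGase F-treated (650 tissue spots) — a 24 × 24
buffer-control rectangle (576 spots) and four calibrant spots carrying the
calibration standard. The nine murine-kidney glycans are planted at their
sodiated masses with zone prevalences chosen to echo the published
spatial findings: the fucosylated complex glycans are cortex-restricted
(prevalence 0.85–0.90 in cortex, ≤0.05 in medulla), two oligomannose
species are medulla-enriched (0.90 vs 0.10), three species are shared
(0.80/0.80), and the control region carries no glycans. Presence is an
independent Bernoulli draw per spot; present glycans emit one peak at the
true mass plus Normal(0, 0.02 Da) jitter — well under a quarter of the
0.1 Da linkage, so planted clusters cannot fragment — with log-normal
intensity (meanlog log 50, sdlog 0.6) and S/N of 3 plus an Exponential(mean
12) excess, the truncation at 3 mirroring an S/N > 3 picking threshold.
Every non-calibrant spot receives Poisson(5) noise peaks uniform over the
acquisition range with weaker intensity and S/N (mean excess 2) — the
simplest noise model that stresses the occurrence filters, since uniform
noise forms many small groups that the ≥100-spectra filter must remove.
An optional fraction of planted peaks can be emitted as glycosylamine
satellites 0.984 Da low, to exercise the ~1 Da doublet discussion.

Ground truth records each glycan's sodiated mass, its area-weighted treated
prevalence, control prevalence, and expected DIPPS (their difference). At
these problem sizes (~2,400 spots, ~15,000 peaks, 7,400 bins) the full
pipeline — grouping, filtering, DIPPS, binning, segmentation and a k = 2
pLSA on the ~650 tissue spots — runs in well under a minute, which is the
scale the test suite and the acceptance script use.

What passing phantom tests shows — and what it does not: the generator
draws independent spots with single centroided peaks per analyte. It has no
isotope envelopes, no matrix clusters, no detector saturation, no spatially
correlated intensity drift, and its noise is uniform rather than
chemically structured. Recovery on the phantom therefore validates the
statistical machinery (grouping resolution, occurrence accounting, DIPPS
calibration, segmentation separability), not robustness to every artefact
of real acquisitions.

# Design decisions that were genuinely open

* **Linkage interpretation** — "grouping at a linkage distance" is read as
  single linkage (gap cut); complete linkage would make 1-D results
  order-dependent and non-unique.
* **Heuristic cutoff** — defined as occupancy-contrast maximisation (above)
  because the referenced rule is unpublished; the user-selected top-N mode
  is always available and is what the headline 13-value selection used.
* **Best-of-several calibrations** — smallest maximum |residual|, an
  explicit criterion where the original description gives none.
* **Reduction by interval maxima** — peak-apex preservation was judged more
  important than amplitude fidelity for a display/alignment step.
* **Electron-mass correction** — included in `[M+Na]+`; at 4-decimal
  precision the 0.0005 Da matters, and the bundled standard's reference
  masses agree with the computed values to well under 0.001 Da either way.
* **Binning mode** — plain interval summation; whether the commercial
  "maximum processing mode" alters binning is undocumented, so the
  conservative conserving choice is used and noted as an approximation.

# Known limitations

* Table-level composition assignments for the published kidney list were
  reconstructed from composition names in the text and mass arithmetic;
  one reported mass (2067.747) could not be assigned and is omitted.
* The heuristic DIPPS cutoff is one admissible rule, not the original.
* Segmentation/pLSA equivalence to commercial software is qualitative
  (region discrimination), never bitwise; smoothing differs by design.
* The phantom's realism limits are listed above; conclusions about real
  FFPE acquisitions require real data.
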