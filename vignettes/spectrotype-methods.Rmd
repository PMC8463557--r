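---
title: "Methods: species discrimination from MALDI-ToF protein spectra"
author: "spectrotype"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: species discrimination from MALDI-ToF protein spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spectrotype)
```

## The problem

Linear-mode MALDI-ToF mass spectrometry of whole-organism protein extracts
produces, for each specimen, a spectrum of protein masses in roughly the
1.5–20 kDa range. Closely related species — for example congeneric
siphonophores, whose diagnostic morphology is fragile and often damaged in
net samples — carry reproducible species-specific peak fingerprints in this
range. The biotyping question is therefore statistical: given a few to a few
dozen spectra per putative species, do the spectra cluster by species, which
peaks drive the separation, and how strongly is each cluster supported?

`spectrotype` implements the full chain from raw two-column ASCII spectra to
those answers: preprocessing, peak detection, peak binning into a feature
matrix, Hellinger transformation, Ward clustering with multiscale-bootstrap
edge support (AU/BP), diagonal-discriminant t-score feature ranking,
non-metric multidimensional scaling (NMDS), a homogeneity-of-dispersion test,
and PERMANOVA. A Kimura 2-parameter (K2P) distance module supports the
companion molecular comparison. Because raw biotyping spectra are rarely
deposited, the package also ships a synthetic-spectrum generator so every
stage is testable end to end without instrument data.

## Preprocessing model

Each spectrum is an ascending m/z grid $m_1 < \dots < m_n$ with intensities
$y_i \ge 0$. The fixed preprocessing order is

1. **trim** to the mass range of interest (default 1500–20000 Da, closed
   interval);
2. **square-root transform**, the standard variance stabilization for
   count-like detector intensities;
3. **Savitzky–Golay smoothing**: local least-squares polynomial fit (default
   half-window 10 points, order 3). Edge points are smoothed with the
   first/last full window's fit evaluated at their own offset, so
   polynomials up to the configured order pass through exactly;
4. **SNIP baseline removal**: iterative peak clipping
   $b(i) \leftarrow \min\{b(i), (b(i-k) + b(i+k))/2\}$ with the clipping
   half-window $k$ running from `snip_iterations` (default 100) down to 1.
   Only points whose full window fits inside the spectrum are clipped: the
   $k$ edge points pass through unchanged in each pass. This makes linear
   trends exact fixed points of the operator; the index-clamping alternative
   erodes the spectrum edges cumulatively and was rejected for that reason.
   Negative residuals after subtraction are clipped to 0;
5. **TIC normalization**: intensities scaled to a fixed total ion current
   (default 1), making spectra of different absolute yield comparable.

The method names and their order follow the established R biotyping
workflow; the smoothing window and SNIP iteration count are not fixed by
that workflow's description and are exposed in `processing_params()`.

## Peaks, binning, and the feature matrix

The noise level is the scaled median absolute deviation
$\hat\sigma = 1.4826\,\mathrm{med}|y - \mathrm{med}(y)|$, a single robust
constant per spectrum (consistent for Gaussian noise; the workflow reference
names only "SNR", so the estimator is a documented default). A peak is a
strict local maximum over a window of $2h+1$ points (default half-window
$h = 7$) with intensity $\ge$ SNR threshold $\times \hat\sigma$ (default 6).

Peaks from all spectra are pooled and binned at a relative mass tolerance
(default 0.001, i.e. $\Delta m / m$, matching linear-mode mass accuracy): the
sorted pooled masses are split recursively at the largest gap until every bin
satisfies (a) $(\max - \min)/\mathrm{mean} \le$ tolerance and (b) no two
peaks from the same spectrum. Each peak's mass becomes its bin mean. On
fingerprint-like data — tight mass clusters separated by gaps much wider than
the tolerance — this recursive split provably coincides with the minimal
contiguous partition, and the test suite checks that equivalence against an
exhaustive dynamic-programming search. When distinct true peaks lie only one
or two tolerances apart the recursive split can use more bins than the
minimum; this is a property of the recursive heuristic itself (shared with
the reference workflow) and is documented rather than patched.

The feature matrix has one row per spectrum and one column per bin; absent
peaks are 0 (not re-interpolated from the raw spectrum, so the matrix is
reproducible without retaining raw data). Columns occupied in fewer than
`min_frequency` of spectra (default 0.05, closed boundary: exactly 5%
occupancy is kept) are dropped. The **Hellinger transform**
$x_{ij} \leftarrow \sqrt{x_{ij} / \sum_j x_{ij}}$ then gives every row unit
sum of squares, so Euclidean distances between rows are Hellinger distances —
an abundance-robust geometry that is the recommended input for
community-style ordination of biotyping matrices.

## Cluster support: multiscale bootstrap

Spectra are clustered by Ward's criterion on Euclidean distances
(`ward.D2` convention: Lance–Williams on squared distances, square-root
heights, so two singletons at distance $d$ merge at height $d$). Edge
support uses the multiscale bootstrap: for scales $r \in \{0.5, \dots,
1.4\}$ the feature columns are resampled with replacement to size
$\lceil pr \rfloor$ and the spectra reclustered ($B$ replicates per scale;
published setting 10,000, tests use 100–1000). Columns, not rows, are
resampled by default: support concerns the grouping of spectra under
perturbation of the peak complement (a `resample = "rows"` flag exists).
With per-scale recovery proportions $\mathrm{BP}_r$ of an original edge, the
probit values $z_r = \Phi^{-1}(1 - \mathrm{BP}_r)$ (counts clamped to
$[0.5, B - 0.5]$) are fitted by weighted least squares to

$$z(r) = v\sqrt{r} + c/\sqrt{r},$$

with binomial weights, and the approximately unbiased support is
$\mathrm{AU} = 100\,(1 - \Phi(v - c))$; BP is the raw proportion at $r = 1$.
Two boundary cases are handled explicitly: an edge recovered in *every*
replicate at every scale gets AU = 100 directly (the probit of a clamped
constant cannot be represented by the two-term model), and an edge never
recovered gets AU = 0 with a degenerate-fit flag.

## Feature ranking, ordination, tests

**DDA t-scores.** For species $g$ and feature $j$,
$$\tau_{gj} = \frac{\bar x_{gj} - \bar x_j}{m_g\,(s_j + s_0)},
\qquad m_g = \sqrt{1/n_g - 1/n},$$
with pooled within-group sd $s_j$ and offset $s_0 = \mathrm{med}_j\, s_j$;
features are ranked by $\sum_g \tau_{gj}^2$. This is diagonal
(feature-independent) discriminant scoring; the additive $s_0$ floor stands
in for the original James–Stein variance shrinkage, an adequate
approximation since only the ranking is consumed. By default scores are
computed on the Hellinger matrix (a flag switches to the raw binned matrix;
the source description does not fix this).

**NMDS** minimizes Kruskal stress-1,
$\sqrt{\sum_{i<j}(\delta_{ij} - \hat d_{ij})^2 / \sum_{i<j}\delta_{ij}^2}$,
with configuration distances $\delta$ and monotone disparities $\hat d$ from
isotonic regression (primary tie treatment — tied dissimilarities may
untie). The descent alternates isotonic fits with a Guttman transform; each
step is accepted only if stress-1 decreases, with step halving otherwise, so
the logged stress trace is non-increasing by construction. Starts: metric
MDS plus random restarts, best stress reported. Default input is Bray–Curtis
on the Hellinger matrix with $k = 2$ — an unusual but deliberately retained
combination (both parts are explicit in the source workflow);
Euclidean-on-Hellinger is available behind a flag.

**Dispersion homogeneity** embeds the dissimilarity matrix by principal
coordinates, keeping negative eigenvalues as imaginary axes; each sample's
distance to its group centroid is
$\sqrt{\max(0,\, d^2_{\mathrm{real}} - d^2_{\mathrm{imag}})}$, and a one-way
ANOVA F on these distances is reported with its parametric p (a permutation
p over the distances is optional). **PERMANOVA** is one-way:
$SS_\mathrm{total} = \frac1n \sum_{i<j} d^2_{ij}$,
$SS_\mathrm{within} = \sum_g \frac{1}{n_g}\sum_{i<j \in g} d^2_{ij}$,
pseudo-$F = \frac{SS_B/(g-1)}{SS_W/(n-g)}$, and
$p = (1 + \#\{F_\pi \ge F\})/(1 + n_\pi)$ with 999 permutations by default,
so the attainable minimum is $1/(n_\pi + 1)$.

## K2P distances

Alignment columns containing a gap, `N`, or any IUPAC ambiguity code in any
sequence are removed once (complete deletion; `U` is read as `T`). For each
pair, with transition proportion $P$ (A↔G, C↔T) and transversion proportion
$Q$ over the retained sites,
$$d = -\tfrac12 \ln\!\big((1 - 2P - Q)\sqrt{1 - 2Q}\big).$$
Saturated pairs (non-positive log argument) raise an error reporting $P$ and
$Q$ rather than returning a fabricated value.

## The synthetic-spectrum generator

The generator states the world the analysis assumes and nothing more. Each
species is a fingerprint: peak masses, mean intensities, and per-peak
occurrence probabilities. A simulated spectrum is

$$y(m) = a\,e^{-\lambda (m - m_\mathrm{low})}
  + \sum_{j\,\mathrm{present}} h_j\, e^{-(m - \mu_j)^2 / 2\sigma^2}
  + \varepsilon(m), \qquad \varepsilon \sim N(0, \sigma_\varepsilon^2)
  \text{ truncated at } 0.$$

Defaults, with the reasoning for each (none of these is tuned to test
outcomes; they were fixed once from what linear-mode biotyping data look
like):

| parameter | default | rationale |
|---|---|---|
| mass range, grid | 1500–20000 Da, 1 Da | published range of interest; ~1 Da digitization typical of linear mode |
| peak width σ | 5 Da | linear-mode resolution $m/\Delta m \sim 10^3$ at mid-range |
| baseline | $20\,e^{-(m-1500)/2500}$ | the low-mass matrix hump SNIP must remove |
| noise sd | 1 | peak means (log-normal around 80) then give raw-scale SNR far above threshold, as in quality-screened spectra |
| mass jitter | 2×10⁻⁴ relative (sd) | linear-mode mass accuracy ~0.02%; keeps within-species peaks inside the 0.001 binning tolerance |
| intensity CV | 0.3 | "slight differences depending on individual": moderate biological + preparation variability |
| occurrence probabilities | uniform 0.7–1 | reproducible species peaks that are not perfectly penetrant |
| peaks per species | 5–30, ≥ 8σ apart | observed fingerprint richness; separation keeps peaks resolvable by the half-window-7 detector |

Fingerprints are redrawn until no species pair shares more than a capped
fraction (default 0.2) of peaks within the binning tolerance. Peak-recovery
statements are made against the peaks *realized* in each spectrum (recorded
in `meta$true_peaks`): with occurrence probabilities below 1 a fingerprint
peak can be legitimately absent, so "recovery" is only well defined for
injected peaks.

The default world draws species peak masses independently, so distinct
species are essentially disjoint in peak space and all between-species
Hellinger distances sit near $\sqrt 2$. That is the right world for
species-recovery questions but makes "a species with many exclusive peaks"
indistinguishable from any other species. The outlier-skew scenario
therefore adds structure real congeners have: nine core species share a
family-conserved peak set (shared peaks are exactly the ones the t-score
ranking pushes strongly negative) plus species-specific peaks, while the
outlier carries three times as many exclusive, high-intensity peaks. In that
world the outlier is the outermost cluster and compresses the remaining NMDS
point cloud, as observed for the real skewed species.

**What the generator does not model:** matrix-cluster chemistry, isotope
envelopes, detector saturation, mass-dependent peak width, spectral warping
beyond per-individual jitter, and fixation (formalin) effects. A green test
therefore establishes that the *statistical chain* behaves as specified on
data satisfying its assumptions — not that any particular instrument or
preservation protocol satisfies them.

## Numerical choices and degenerate inputs

* Ties everywhere break toward the lowest index (first largest gap in
  binning, `hclust`'s deterministic ordering, first matching bin).
* One pipeline seed deterministically derives per-stage seeds
  (`derive_seed`), so stages can be rerun in isolation and full reruns are
  byte-identical.
* All-zero rows (Hellinger, Bray–Curtis, TIC) raise errors naming the
  offending spectrum; empty peak lists are legal; a single species label
  aborts the statistics stages but still writes preprocessing outputs.
* Frequency filters use closed boundaries (kept at exactly the threshold).
* Saturation in K2P and window/length mismatches raise informative errors.

## Known limitations

* The recursive binning heuristic is minimal only on well-separated mass
  clusters (see above).
* The AU model is asymptotic in $B$ and the scale grid; at test-scale
  $B \le 1000$ AU values for borderline edges carry a few percent of
  Monte-Carlo noise.
* The dispersion test reports the parametric ANOVA p by default; for tiny
  groups the permutation option is preferable.
* NMDS with few points and $k = 2$ can terminate at local minima; restarts
  mitigate but do not eliminate this.
* `bray_curtis()` and `k2p_matrix()` are $O(n^2)$ R loops — fine for the
  hundreds of spectra this design targets, not for thousands.
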