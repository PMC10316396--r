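---
title: "Spanning-tree mapping of hyperspectral coherent Raman images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spanning-tree mapping of hyperspectral coherent Raman images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spectree)
```

## The problem

Broadband coherent anti-Stokes Raman scattering (BCARS) microscopy
acquires a full vibrational spectrum at every pixel of an image —
hundreds of chemically informative channels over the fingerprint region
(500–1800 cm⁻¹, one value every 2 cm⁻¹, 651 channels). In an ordered
tissue such as the *C. elegans* gonad, whose cells progress from
proliferating germ cells through meiosis to maturing oocytes along a
single anatomical axis, these spectra encode a chemical progression.
`spectree` implements a pipeline that

1. converts raw CARS intensities into calibrated Raman-like spectra
   (Kramers–Kronig retrieval against a nonresonant-background reference),
2. summarizes the pixel cloud in 651-dimensional spectral space as a
   minimum-spanning tree over cluster centroids (SPADE-style), with every
   pixel assigned to exactly one tree node,
3. counts, for each of S ordered tissue sections, the fraction of the
   section's pixels falling on each node, and
4. correlates those per-section node frequencies with spatial
   gene-expression profiles measured over the same sections.

Because the original microscope data and transcriptome cannot be bundled,
the package ships a synthetic-data generator with known ground truth that
emulates both, so that every stage is testable end to end and parameter
recovery can be quantified.

## The forward model behind the generator

A tissue pixel is a mixture of P spectral components (defaults: nucleus,
cytoplasm, yolk, ecm, fluid). Each component contributes a resonant
susceptibility that is a sum of Lorentzian resonances,

$$\chi_R(\omega) = \sum_j \frac{A_j}{\Omega_j - \omega - i\,\Gamma_j},$$

plus a nonresonant (electronic) amplitude $\chi_{NR}$. The measured CARS
intensity at a pixel with component abundances $a_p$ is the coherent sum

$$I(\omega) = \Bigl|\chi_{NR}^{\mathrm{pix}} + \sum_p a_p\,
\chi_{R,p}(\omega)\Bigr|^2 + \varepsilon(\omega),$$

with $\chi_{NR}^{\mathrm{pix}}$ the abundance-weighted mix of component
nonresonant amplitudes and $\varepsilon$ additive Gaussian noise whose
standard deviation scales with $\sqrt{I}$ (shot-noise-like; default
`sd_scale = 0.01`, i.e. ~1 % at the background level). Background pixels
carry the pure nonresonant background, whose noise-free spectrum is
emitted as the NRB reference. Peak positions in the default library
follow standard fingerprint assignments (785/811/1340 cm⁻¹ nucleic
acids, 936/1004/1230/1655 cm⁻¹ proteins, 877/1300/1450/1740 cm⁻¹
lipids); amplitudes are free parameters chosen weak relative to
$\chi_{NR}$ so retrieval operates in its near-linear regime. They are
deliberately *not* calibrated to any real tissue — no quantitative
composition of the gonad's tissue classes is available to calibrate
against.

### Phantom geometry and the planted progression

The phantom is a straight band of S equal-width section strips (default
S = 10, 200 × 60 px) framed by background rows — the analysis only ever
consumes the label raster, so the U-shape of the real gonad is
immaterial. Each tissue pixel gets one dominant class (abundance 0.65)
drawn from section-dependent class probabilities; every component also
contributes a minor abundance (0.25 × its class probability), so
per-pixel abundances always sum below 1. Class probabilities follow
logistic transitions along the section axis with one sharp changeover at
section 6.5 (emulating the gonad loop), so sections fall into two blocks
of mutually similar composition — the recoverable analogue of the two
highly correlated section blocks seen in real node-frequency data. Each
component uses a distinct logistic centre and width; this matters
because two profiles that are affine images of one another would
correlate at exactly ±1 with each other's anchor genes and make
gene-to-component attribution unidentifiable.

Class *counts* per section are deterministic quotas (monotone rounding
for the sharply rising "yolk" class, largest remainder for the rest);
only pixel placement and an optional multiplicative abundance jitter
(default s.d. 5 %) are random. This makes section-mean abundances follow
the planted profiles exactly, so construction-level properties (e.g.
monotone growth of the post-changeover component) hold by design rather
than on average.

### The synthetic gene table

Anchor genes track a linked component's per-section mean abundance,
$g(s) = a + b\,\bar a_p(s) + \epsilon$ (defaults a = 2, b = 40,
noise s.d. 0.5 — a high signal-to-noise coupling, as for strongly
expressed marker genes); one flat control gene is exactly constant
(mirroring a uniformly expressed control whose downstream metabolites
show no spatial pattern); random genes draw i.i.d. lognormal section
values. Expression values are continuous non-negative floats, not
counts: all comparisons operate on normalized profiles, so count noise
models would add realism nowhere it is consumed. Note one deliberate
consequence of the defaults: the fluid class varies mildly across
sections, so its anchor gene's fold change (~1.4) falls below the 2-fold
"dynamic gene" threshold and is correctly filtered out — a built-in
reminder that the dynamic filter and the correlation machinery answer
different questions.

## Retrieval

The Kramers–Kronig step treats the ratio $R(\omega) =
I(\omega)/I_{NRB}(\omega)$ as the squared modulus of a minimum-phase
response, so its phase is the Hilbert transform of $\tfrac12 \log R$ and

$$S(\omega) = \sqrt{R(\omega)}\,\sin\varphi(\omega) \approx
\frac{\operatorname{Im}\chi_R(\omega)}{\chi_{NR}},$$

a Raman-like spectrum standardized by the NRB ("the NRB as internal
reference"): multiplying raw and reference by a common factor leaves the
result unchanged, which is what makes retrieved amplitudes comparable
across pixels, days and instruments. Implementation choices (the exact
retrieval variant is a free design decision):

* **Edge handling.** The Hilbert transform is computed by FFT after
  periodic-mirror padding of 2 × the axis length at each edge, which
  keeps the extension continuous at every joint and suppresses
  wraparound error; validated against closed-form Im χ oracles — peak
  positions are recovered to 0 channels across a 600–1700 cm⁻¹ sweep,
  and 2:1 amplitude ratios to 0.03 %.
* **Residual baseline.** The slowly varying part of the phase that the
  reference does not remove is taken out per pixel by iterative
  asymmetric least squares (Whittaker smoother with second-difference
  penalty, λ = 10⁵ channel units, asymmetry p = 0.01, 10 reweighting
  iterations; a banded LDLᵀ solve in C++). λ is chosen so that trends
  varying on scales of hundreds of channels are absorbed while peaks a
  few channels wide are preserved (≤ 5 % height change in tests). A
  consequence worth knowing: very broad bands (the Γ = 40 cm⁻¹ water
  band spans ~40 channels) are *partially* absorbed too. Validation
  against ground truth therefore applies the same baseline functional to
  the true Im χ mixture before comparing — with that like-for-like
  comparison, per-pixel peak positions match for 100 % of tissue pixels
  (threshold 99 %).
* **Negatives.** Values that go slightly negative after baseline
  correction are kept by default; clustering tolerates small negatives
  and clipping would bias difference spectra.
* **Floors.** Raw and reference intensities are floored at 10⁻¹² of the
  NRB maximum before logs; a reference that is nonpositive after
  flooring is a hard error naming the channel.

## Tree construction

The SPADE-style stages and their fixed conventions (the source method
leaves all of these unstated, so they are package design decisions,
surfaced in the configuration):

* **Metric** — L1 by default (the flow-cytometry SPADE lineage
  convention), L2 available everywhere.
* **Density radius** — `radius_alpha = 5` × the median nearest-neighbour
  distance of a seeded 2000-point subsample.
* **Density** — exact neighbour counts within the radius (blocked
  pairwise distances with early abandoning in C++), not an approximation;
  the point itself counts, so the minimum density is 1.
* **Downsampling** — points below the 1st percentile of densities are
  removed as outliers; points between the 1st and 3rd percentiles are
  kept; denser points are kept with probability target/density; a hard
  cap of 2 × 10⁵ kept points applies. One uniform draw per point makes
  the rule exactly replayable from the seed.
* **Clustering** — k-means (default k = 300 for microscope-scale images;
  the synthetic reference condition uses k = 50 for its 10⁴-pixel
  phantom) with seeded k-means++ initialization, 10 restarts keeping the
  lowest within-cluster sum of squares, and empty clusters reseeded at
  the point farthest from its centroid. Ward-linkage agglomerative
  clustering is the alternative.
* **MST** — Prim's algorithm over centroid distances with deterministic
  lexicographic tie-breaking; verified against exhaustive enumeration of
  all labeled spanning trees at small k.
* **Layout** — seeded Fruchterman–Reingold with 500 iterations; the
  coordinates carry no information beyond connectivity.
* **Assignment** — *every* in-mask pixel, including density outliers
  dropped before clustering, is assigned to its nearest centroid (ties
  to the lowest node id), so node pixel sets partition the mask.

One behaviour of the reference synthetic condition is worth stating
plainly: because the phantom's five classes are tight clusters whose
within-class spread is noise-dominated, the median nearest-neighbour
distance is of the same order as the cloud diameter, and 5 × it covers
everything — densities come out uniform and downsampling degenerates to
keep-all (which is also the rule's documented degenerate case). The
non-degenerate downsampling path — outlier removal, probabilistic
thinning, density flattening — is exercised by planted dense/sparse blob
tests where densities genuinely vary. Real microscope data, with its
continuum of mixed spectra, sits between these extremes.

## Sections and correlation

Per-section node frequencies are raw fractions: counts of a node's
pixels inside a section divided by the section's pixel count, so each
non-empty section column sums to 1. Empty sections (e.g. a section
outside the imaged field) are flagged and dropped from all correlation
computations. All correlations are Pearson. The node–node clustermap
correlates node fraction profiles across sections, orders nodes by
average-linkage hierarchical clustering on Euclidean distances between
correlation-matrix rows (the conventional clustermap default), and
reports per-node standardized fractions in that order. Two conventions
deserve a note:

* **z-score divisor.** The operative description of the standardization
  ("subtract mean, divide by variance") is ambiguous between s.d. and
  variance; the default divides by the standard deviation — that is what
  "z-score" means and it yields unit-variance rows — and a
  `zscore_divisor = "var"` switch honours the literal reading.
* **Undefined correlations.** Zero-variance inputs (a constant gene, a
  node present in every section at identical frequency) yield
  *undefined* markers (`NA`), never a silent 0. Undefined values cannot
  enter top-node selections; a gene whose every correlation is undefined
  yields an empty selection with a warning.

Gene–node correlation operates on raw fractions (not z-scores); the
top-10 nodes per gene are the defined r values sorted descending with
ties broken by ascending node id, and their pixels form the highlight
mask for overlaying on the image.

## What the tests do and do not show

The reference condition for validation is the default phantom (200 × 60
px, S = 10, five components, k = 50, seed 1; chosen so the full pipeline
runs in minutes on one CPU — the vector-space dimensionality, 651, is
never reduced). Under it the suite verifies: closed-form retrieval
fidelity; exact oracle equivalence of the SPADE core (densities vs
O(N²) brute force, MST vs exhaustive enumeration, assignment vs direct
scan, downsampling vs seeded replay); structural invariants
(normalization, partition, spanning-tree shape, z-score identities,
zero-sum difference spectra); and parameter recovery — the planted
two-block section structure reappears in the node-frequency
section–section correlations with a within-minus-between contrast ≈ 1.3
(well above the 0.3 floor), every anchor gene's top-10 nodes contain a
node with ≥ 50 % of its pixels in the linked component's region, and the
flat control yields no defined correlations.

What passing these tests does *not* show: the phantom has no optical
point-spread function, no spectrograph response or wavenumber
calibration error, no cosmic rays, no spatial correlation of noise, and
tissue classes far more discrete than real cytology; section geometry is
an input, never inferred from the image. Results on real BCARS data
depend on all of those. The package's claim is narrower and testable:
given spectra generated by the stated forward model, the pipeline
recovers the planted spatial-chemical structure and its gene couplings
exactly or within the stated tolerances.

## Numerical and degenerate-input conventions

* Identical seeds give bit-identical phantoms, cubes, tables, trees and
  assignments; every stage draws from a named substream of the root
  seed, so changing k cannot perturb the phantom.
* k-means ties in assignment go to the lowest node id; `max.col` with
  `ties.method = "first"` and the strict-improvement rule in C++ agree.
* Empty tree nodes are flagged and filled with their centroid in node
  mean spectra.
* An all-coincident radius subsample falls back to the smallest nonzero
  pairwise distance in the full data; if none exists the radius is a
  hard error.
* Node ids are 1-based everywhere in the R API and in files; 0 marks
  "outside mask" in integer rasters.
* Cube bundles store float32 (JSON metadata + flat little-endian
  binary + TIFF rasters + CSV tables); trees serialize to JSON with
  exact integer edges. FCS export is list-mode float32 FCS 3.1 with one
  event per pixel, one parameter per wavenumber plus X and Y.

## A worked miniature

```{r mini, eval = FALSE}
cfg <- pipeline_config(seed = 1,
                       phantom = list(height = 40, width = 120, S = 10),
                       k = 30)
run <- run_pipeline(cfg)
dim(run$freq$fractions)            # 30 nodes x 10 sections
run$section_corr[1, 10]            # distal vs proximal: strongly negative
run$gene_reports$anchor_yolk$top_nodes
```

The full reference condition is `synthetic_study_config(seed = 1)`;
`scripts/acceptance.R` reruns it from scratch and prints every headline
quantity.
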