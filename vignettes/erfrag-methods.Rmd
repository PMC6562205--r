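---
title: "Models and methods behind erfrag"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind erfrag}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(erfrag)
```

`erfrag` quantifies four consequences of α1-antitrypsin (Z variant)
polymerisation in hepatocyte models: loss of ER luminal connectivity
(FLIP), reduced luminal protein mobility (FRAP), the population structure of
ER inclusions (morphometry), and the partition of newly synthesised protein
among degradation, secretion and intracellular retention (pulse-chase),
together with the transcriptome–proteome integration used to derive disease
signatures. Every analysis stage has a matching seeded generator with known
ground truth, so the estimators are testable end to end without any external
data. This vignette records the models, the tunable parameters and their
defaults, the numerical choices, and what the synthetic worlds do and do not
establish.

## The ER lattice and the photobleaching simulator

The ER lumen is a 2D lattice graph: sites are (row, col) cells (0-based),
and sites at Manhattan distance 1 share an undirected edge. A healthy
reticulum is one connected component (`make_reticular_geometry()`);
fragmented ER is a set of square blocks separated by at least one empty
lattice row (`make_fragmented_geometry()`), optionally plus a residual
reticulum strip, so each inclusion is its own component and no edge joins
two components. A 2D lattice was chosen over 3D because the assayed images
are single confocal sections and none of the tested contracts depend on
dimensionality.

Fluorophores are discrete particles. A fraction `immobile_fraction` never
moves; mobile particles perform a lazy symmetric random walk: with
probability `diffusion` per frame a particle hops to a uniformly chosen
lattice neighbour, otherwise it stays. Discrete particles were chosen over a
finite-difference PDE because conservation is then exact — bleached plus
unbleached counts equal the initial total at every frame, an invariant the
test suite asserts directly — and because the isolated-compartment contract
(no particle ever crosses between components) is structural rather than
approximate.

Two numerical choices deserve attention:

* **`diffusion` defaults to 0.8, deliberately below 1.** At exactly 1 the
  per-particle chain on the bipartite 4-neighbour lattice is periodic
  (particles alternate strictly between the two sublattices), and its
  long-run region occupancies deviate from the stationary distribution of
  the lazy walk. During development, Monte Carlo equilibria at `diffusion =
  1` were checked against an exact density-evolution oracle (the one-step
  transition matrix applied to expected occupancies) and showed a systematic
  recovery deficit that disappears for any hop probability below 1. The
  lazy walk's stationary distribution is proportional to site degree, so
  interior regions equilibrate slightly above the lattice-wide mean — a
  real property of random walks on bounded lattices, not an artifact.
* **Bleach pulses are instantaneous and probabilistic.** A pulse converts
  each particle inside the ROI to the dark state with probability
  `bleach_efficiency` (the assayed experiments do not state a bleach
  depth). The frame acquired at the pulse records the immediately
  post-pulse state.

Measurement noise is additive Gaussian on the per-frame ROI sums, with
standard deviation `noise_sd` times the ROI's expected pre-bleach signal;
detector noise is not characterised for the emulated experiments, so this is a
package choice. The acquisition defaults — frame interval 0.5 s, pulse at
5 s after 10 pre-bleach frames — are likewise package choices; no frame
rate, pulse duration or inter-pulse interval is stated for the original
experiments, and these values are never presented as theirs.

ROIs are half-open rectangles `[r0, r1) × [c0, c1)` in 0-based coordinates,
stated in all file headers. FRAP protocols have exactly one pulse; FLIP
protocols have two or more.

The simulator treats both the luminal marker (KDEL-GFP) and the
membrane-anchored probe (CytERM) as luminal particles. The two differ
photophysically in reality; the simplification is recorded here because
only connectivity and mobility contracts, which both probes share, are
exercised.

## FRAP estimation

`normalize_prebleach()` divides each ROI's trace by the mean of its
pre-bleach frames (all frames before the first bleach frame; at least 3
required, positive mean) and multiplies by 100. The operation is idempotent
and scale-invariant, both asserted as properties.

`fit_frap()` fits the single-exponential recovery

$$F(t) = F_0 + (\mathrm{plateau} - F_0)\,(1 - e^{-k t})$$

to the post-bleach frames by least squares, with *t* measured from the
first post-bleach frame. **F₀ is treated as a data quantity** — the
observed first post-bleach level — and only the plateau and rate are free
parameters. The rationale: a lattice-diffusion recovery is multi-exponential
(fast local refilling, then slow global dilution of the bleached
population), and a free three-parameter fit trades F₀ far upward to absorb
the early fast component, which biases the plateau low and breaks
mobile-fraction recovery. With F₀ pinned, the contract that the
estimator recovers the generator's mobile fraction within ±0.05 at 2% noise
holds across the tested immobile-fraction grid {0, 0.25, 0.5, 0.65, 0.9}.
A residual downward shape bias of order one percentage point remains in the
fitted plateau whenever the acquisition window is not long relative to the
lattice mixing time; the acceptance-scale FRAP world therefore simulates to
diffusion equilibrium (8,000 frames on the 40×40 lattice).

The mobile fraction is $(\mathrm{plateau} - F_0)/(F_\mathrm{pre} - F_0)$
with $F_\mathrm{pre} = 100$, clipped to [0, 1.05] with a `clipped` flag.
Because it is not stated whether published mobile fractions used the fitted
asymptote or the final intensity, both are reported
(`mobile_fraction`, `mobile_fraction_last`). The initial slope is estimated
model-free by ordinary linear regression over the first `window` (default 5)
post-bleach frames, so a rate-free mobility readout exists alongside the
model fit. Degenerate inputs are flagged, not thrown: a flat post-bleach
trace returns mobile fraction 0 with `k_identifiable = FALSE`; a
non-convergent fit returns the observed post-bleach mean as plateau with
`converged = FALSE`.

## FLIP and connectivity calls

`flip_depletion()` summarises a repeated-bleach experiment per ROI as the
depletion fraction (mean of the last three frames over the 100% pre-bleach
level) and the mean inter-pulse recovery (fractional intensity rebound
within each pulse gap relative to the drop at the preceding pulse — the
small, consistent rebound between bleaching events that signals rapid
luminal diffusion). `classify_connectivity()` maps depletion to three
levels: at or below `deplete_below` (default 0.25) is `connected`, at or
above `preserve_above` (default 0.75) is `isolated`, in between is
`indeterminate`. The thresholds are package choices — the published
calls are qualitative — and the defaults are validated only in the
sense that, on simulated geometries with known component structure, calls
match ground truth in ≥95% of non-indeterminate ROIs.

Group comparison (`compare_groups()`) is Student's pooled-variance t test —
the standard unpaired parametric t test of the figure legends in this
field; Welch's correction is available via `var_equal = FALSE`. Significance stars follow the figure
convention exactly: `****` p ≤ 0.0001, `***` p < 0.001, `**` p ≤ 0.01,
`*` p < 0.05, otherwise n.s.

## Morphometry

The image generator emulates sections of GFP-KDEL-transfected cells on a
128×128 16-bit canvas: a normal cell is background (mean 1000, σ 30) plus a
smooth sinusoidal reticular field filling roughly half the cytoplasm; an
inclusion-bearing cell carries 1–5 non-overlapping bright discs
(intensity ≈ 4000) with radii drawn from its size class — small 2–4 px,
medium 5–8 px, large 9–14 px, all configurable, since no pixel sizes are
published. Whether a cell bears inclusions is Bernoulli at
`inclusion_prevalence`; the truth table records class and disc count.

Segmentation is a global Otsu threshold followed by 8-connectivity
labelling, discarding regions under `min_area` (4 px²). One guard matters:
when the thresholded foreground exceeds `max_fill` (default 0.30) of the
image, the foreground is interpreted as reticular texture rather than
inclusions and zero regions are returned. This encodes the morphological
difference the classifier relies on — inclusions are compact and sparse,
reticular ER is large and connected — and keeps Otsu's scale invariance
(multiplying an image by a constant changes no labels).

Cells are classed by their **largest** inclusion (a rule published work does
not state; a cell with one large and one small inclusion is "large") using
half-open area bands (0, 80], (80, 300], (300, ∞) px². The bands are tied
to the generator's radius bands, with one documented seam: a rasterised
disc of radius 9 covers ≈ 255 px² < 300, so a large-class cell whose
biggest disc has radius 9 classes as medium. The class-agreement criterion
(≥90%) holds regardless, and prevalence — which only distinguishes normal
from inclusion-bearing — is unaffected. `population_summary()` reports
per-class percentages (summing to 100) and prevalence with an exact
binomial 95% CI.

## Omics simulation and integration

`generate_omics()` draws counts from a negative binomial with log-normal
baseline means, dispersion 0.1 by default, and planted |log2FC| ~
N(`log2fc_mean`, `log2fc_sd`) effects applied symmetrically (half up in
condition A, half down in B on the log scale) so library composition stays
comparable. Proteome presence is per batch (default 3 per genotype, the
published design) with detection probability `1 − exp(−μ/detection_scale)`,
increasing in expression; the configured genotype-exclusive proteins
(defaults 14 and 3) are imposed on top, and exclusivity patterns that arise
by chance are broken so the matrices contain exactly the configured sets.
The GMT annotation contains one term enriched among the planted
up-regulated genes (60% of its members), which the ORA stage should rank
first.

`differential_expression()` is the package's own pipeline — published studies often
name no engine — so this one is deliberately transparent: median-of-ratios size
factors, per-gene pooled t tests on `log2(normalized + 1)`,
Benjamini–Hochberg adjustment (`bh_adjust()`, step-up with monotonicity,
oracle-checked against both brute-force enumeration and the reference
implementation), and log2 fold changes from normalized means with a
pseudo-count of 1. All-zero genes are retained but flagged untestable;
zero-variance genes get p = 1 (equal means) or p = 0 (unequal). Direction
is `up`/`down` only at q < 0.05.

Exclusivity follows the strict published rule: present in **all** batches
of one genotype and absent from **all** of the other. Gene–protein
integration inner-joins on the shared identifier and keeps candidates whose
fold changes exceed ±2 (log2) at both levels; because it is ambiguous
whether the published pairing also required transcript-level significance,
`require_significant` exposes both modes. Expression tiers are within-subset
quartiles on ranked expression (descending, ties by gene id), sizes
differing by at most one; tiers are rank-based and thus invariant to
monotone transformations. Top-n lists rank by ascending raw p with
lexicographic tie-break. Reported percentages round half away from zero
(`percent_round()`: 5/17 → 29%). ORA is the one-sided upper hypergeometric
tail with BH across terms, verified against exhaustive combinatorial
enumeration for small universes. The cross-study comparison
(`top_n_by_pvalue()` + `cross_overlap()`) takes a precomputed ranking
deliberately: the published primary-tissue contrast had one sample per arm,
so no replicate test exists to reproduce, only the list operation.

## Pulse-chase kinetics

Label leaves the free intracellular pool by three competing first-order
fates with rates `k_deg`, `k_sec`, `k_ret` (h⁻¹). Closed forms: the free
pool decays as $L_0 e^{-\Sigma k\,t}$; each fate pool accumulates as
$(k_x/\Sigma k)\,L_0(1 - e^{-\Sigma k\,t})$. The observable **lysate** band
is free plus retained label — retained polymer is intracellular and treated
as non-decaying within the chase window — and the supernatant band is the
secreted pool, so mass balance lysate + supernatant + degraded = L₀ holds
identically (asserted to 1e-9 against an independent Runge–Kutta
integration). Band intensity is assumed linear in label (densitometry
linearity), with multiplicative Gaussian noise applied last; glycoform
maturation shifts are not modelled.

`fit_pulse_chase()` minimises the joint lysate + supernatant residual sum
of squares over (L₀, k_deg, k_sec, k_ret) with rates bounded at zero, via a
small multi-start L-BFGS-B grid plus a tight polishing pass (the polish uses
`factr = 1`, parameter-scaled, which is what achieves the 1e-6
fraction-recovery contract on noiseless data). Identifiability at the
0/1/2/4 h schedule: the lysate decay fixes Σk, the supernatant plateau fixes
f_sec, the lysate plateau fixes f_ret, and f_deg is the remainder. A lysate
that does not decay (final ≥ 95% of initial) is flagged non-identifiable
rather than rejected. The 70/15/15 partition is used as a canonical worked
example from prior literature on Z-variant fate, not as a measurement by
this package.

## Pipeline, configuration and seeds

`run_pipeline()` executes the four stages in order, validates every stage
block against its module's preconditions first (`validate_config()` reports
module/field paths, e.g. `generate_cell_population.inclusion_prevalence`),
and writes per-stage TSVs plus a combined `summary.json` containing the
seed, a configuration hash and per-stage provenance. One master seed spawns
deterministic per-stage substreams, so toggling a stage leaves the other
stages' draws unchanged and re-running a recorded configuration reproduces
every output byte-identically (asserted in the suite). Configuration is a
TOML subset — `[section]` headers and scalar/array `key = value` lines —
parsed in-package because no TOML reader is available in the supported R
stack; the same applies to the minimal uncompressed 16-bit multi-page TIFF
codec behind `write_tiff_stack()`/`read_tiff_stack()`.

## What the synthetic worlds do and do not establish

The generators reproduce the *structure* of the assayed experiments —
connectivity-dependent depletion, mobility-dependent recovery, prevalence
mixtures, planted differential signals, competing fates — with known truth
and realistic noise magnitudes (2% measurement noise, NB dispersion 0.1,
three batches per genotype). They do not reproduce optics (no PSF, no
photophysics, no 3D), real detection chemistry (peptide evidence is reduced
to a saturating detection probability), or real biological covariance
structure. A green suite therefore establishes that the estimators are
correct and calibrated on data generated under their own assumptions, and
that every bookkeeping operation matches its published worked example; it
does not establish anything about patient biology. Real-cell slope values
(e.g. 2.92 ± 0.75 vs. 1.23 ± 0.22 as published) are not reproduction
targets; only their ordering — connected faster than inclusion-bearing — is
asserted, and it holds on every seeded batch in the suite.
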