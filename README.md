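# erfrag

Quantitative analysis of endoplasmic-reticulum (ER) fragmentation in
hepatocyte models of α1-antitrypsin deficiency (A1ATD), with seeded
simulators for every input so each estimator can be audited against known
ground truth.

In PiZZ hepatocyte-like cells, misfolded Z-variant α1-antitrypsin polymerises
inside the ER and accumulates in dilated, walled-off inclusions. This changes
four measurable things, and `erfrag` implements the quantification of all
four:

1. **Photobleaching kinetics (FLIP/FRAP).** The ER lumen is modelled as a 2D
   4-neighbour lattice graph; fluorophores are discrete particles performing
   a lazy symmetric random walk (hop probability *D* per frame), a fraction
   of which is immobile. Bleach pulses convert in-ROI particles to a dark
   state. Particle counts are conserved exactly, and particles can never
   cross between connected components — the physical content of the
   "walled-off cisterna" phenotype. Estimators: normalization to 100%
   pre-bleach, single-exponential recovery fit
   *F(t) = F₀ + (plateau − F₀)(1 − e^(−kt))*, early-window initial slope,
   mobile fraction *(plateau − F₀)/(F_pre − F₀)*, FLIP depletion fractions,
   and three-level connectivity calls (connected / isolated / indeterminate).
2. **Inclusion morphometry.** A generator of synthetic single-cell images
   (diffuse reticular texture vs. 1–5 bright disc inclusions with
   small/medium/large radius classes), Otsu segmentation with 8-connectivity
   labelling, per-cell classification by largest inclusion area, and
   population summaries with an exact binomial CI on inclusion prevalence.
3. **Transcriptome–proteome integration.** Negative-binomial two-condition
   count simulation with planted fold changes; median-of-ratios
   normalization; per-gene t tests on log2 counts with Benjamini–Hochberg
   FDR; strict per-batch presence/absence exclusivity sets ("present in all
   three batches of one genotype, absent from all of the other");
   gene–protein integration at |log2FC| > 2; four-tier expression grouping;
   top-n / cross-study overlaps; hypergeometric over-representation analysis
   of GMT gene sets.
4. **Pulse-chase secretion kinetics.** A competing first-order fates model
   (degradation, secretion, polymer retention) with closed-form solutions,
   fate fractions *f_x = k_x / Σk*, and a constrained least-squares fitter
   for lysate/supernatant band intensities. At rates 0.70/0.15/0.15 h⁻¹ the
   partition is the canonical 70% degraded / 15% secreted / 15% retained.

Everything is tidyverse-shaped: data frames in, tibbles out, `tidy()` /
`glance()` methods on fitted objects, `autoplot()` for each result type, and
an end-to-end `run_pipeline()` driven by a TOML configuration with one
master seed.

## Worked example

```r
library(erfrag)

# A connected reticulum vs. two walled-off inclusions
geom <- make_reticular_geometry(24, 24)
geom
#> <er_geometry> 576 sites, 1104 edges, 1 component(s) on a 24 x 24 lattice
make_fragmented_geometry(2, c(5, 5))
#> <er_geometry> 50 sites, 80 edges, 2 component(s) on a 12 x 5 lattice

# FRAP on the connected reticulum with 35% immobile fluorophores
proto <- bleach_protocol(roi_rect(4, 8, 4, 8), "FRAP", pulse_times = 3,
                         frame_interval = 0.5)
traces <- simulate_photobleach(geom, proto, total_time = 500,
                               particles_per_site = 20,
                               immobile_fraction = 0.35, noise_sd = 0.02,
                               seed = 42)
fit_frap(normalize_prebleach(traces))
#> <frap_fit> roi 'bleach': F0 = -0.16%, plateau = 63.56%, k = 0.2104 1/s,
#>   initial slope = 15.546 %/s, mobile fraction = 0.636
```

The mobile fraction estimate (0.636) recovers the generating truth (0.65):
after a full bleach of the ROI, only mobile fluorophores re-enter, so the
recovery plateaus near the mobile share of the pre-bleach signal.

```r
# Pulse-chase at the canonical A1ATD partition, 2% densitometry noise
pc <- generate_pulse_chase(0.70, 0.15, 0.15, chase_times = c(0, 1, 2, 4),
                           noise_sd = 0.02, seed = 42)
fit_pulse_chase(pc)
#> <fate_fit> rates (1/h): deg 0.739, sec 0.153, ret 0.161
#>   fractions: degraded 70.2%, secreted 14.6%, retained 15.3%

# A 200-cell population generated at 40% inclusion prevalence, re-estimated
# by segmentation + classification
pop <- generate_cell_population(200, inclusion_prevalence = 0.40, seed = 7)
s <- population_summary(classify_population(pop$images))
s$class_summary
#>   size_class n_cells percent
#> 1 normal         125    62.5
#> 2 small           15     7.5
#> 3 medium          27    13.5
#> 4 large           33    16.5
round(100 * s$prevalence_ci, 1)
#> lower upper
#>  30.8  44.6
```

The estimated prevalence (37.5% here) sits inside the exact binomial 95%
interval around the generating 40%.

An end-to-end run (simulate → quantify → report, all four stages, one seed):

```r
summary <- run_pipeline(demo_config(), out_dir = "runs/demo")
# or from a shell:
#   Rscript scripts/run_pipeline.R --config inst/extdata/demo_config.toml --out runs/demo
```

## Acceptance script

`scripts/acceptance.R` recomputes the package's headline quantities from
scratch with the installed package — the long-time degraded fraction of the
competing-fates model at 0.70/0.15/0.15 h⁻¹; the mean fitted FRAP recovery
plateau over 10 seeded simulations of a connected 40×40 reticulum with
immobile fraction 0.10; and the inclusion prevalence re-estimated from a
200-cell population generated at 40% — and writes them as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

Runtime is a few minutes on one CPU; the FRAP stage dominates because each
trace is simulated to diffusion equilibrium (8,000 frames of 64,000
particles).
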