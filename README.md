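# skinmorph

Multiscale morphometry of intrinsic skin ageing in R: dermal
microstructure from two-channel nonlinear microscopy, surface texture
from skin replicas, and the cohort statistics that link the two.

## What it computes, and for whom

The package is aimed at quantitative dermatology / tissue-engineering
groups who need reproducible implementations of three measurements and
of the statistics connecting them:

* **Elastin-to-Collagen ratio** of the upper dermis,

  R_EC = N_elastin / N_collagen,

  counted over an entire two-channel 3-D stack. Collagen is read from
  the second-harmonic generation (SHG) channel, elastin from the
  autofluorescence (AF) channel. Grey-level thresholds are found
  automatically by 1-D k-means — k = 2 on SHG (background | collagen),
  k = 3 on AF (background | collagen bleed-through | elastin) — and each
  threshold is the centroid of the signal cluster. The k-means solver is
  an exact dynamic program on the grey-level histogram, so thresholds
  are deterministic global optima.

* **Arithmetic surface roughness** of a replica height profile,

  Ra = (1/l) ∫₀ˡ |z(x)| dx,

  after least-squares baseline removal and mean-centring; the replica
  index averages a longitudinal and a transversal profile.

* **Microrelief morphometry**: the replica image (basins dark, furrows
  bright) is segmented by marker-controlled watershed with markers from
  the extended regional minima of an H-minima transform; every polygon
  yields area A_i, perimeter P_i, major/minor axes, orientation and
  aspect ratio, summarised as the polygon density NP and the
  characteristic length

  Lc = (1/N) Σᵢ (√A_i + P_i / 4),

  a compact surface biomarker of dermal ageing.

* **Cohort statistics**: descriptives (mean ± sd, range), a median split
  on Lc into low/high groups, two-sided Mann-Whitney U comparisons
  (exact by enumeration up to a combined n of 20, tie-corrected normal
  approximation beyond), and the signed Pearson correlation matrix.

A synthetic-data module generates every input with known ground truth —
planted-fibre stacks, analytic roughness profiles, hard-core Voronoi
replica textures with exact tessellation truth, and cohorts with a
planted Lc–R_EC correlation — so the whole chain is validated by
parameter recovery. See the methods vignette
(`vignettes/skinmorph-methods.Rmd`) for the model details and design
choices.

## Worked example

```r
library(skinmorph)

## dermis: Elastin-to-Collagen ratio from a synthetic two-channel stack
st <- generate_stack(stack_spec(seed = 42))
compute_rec(st$stack)
#> R_EC = 0.01664  (576 elastin / 34606 collagen voxels)
#>   thresholds: collagen 180, elastin 219.9
sum(st$masks$elastin) / sum(st$masks$collagen)  # planted truth
#> [1] 0.0167

## surface: roughness of a longitudinal / transversal profile pair
lo <- generate_profile("sine", amplitude_um = 10, wavelength_um = 100)
tr <- generate_profile("sine", amplitude_um = 20, wavelength_um = 100)
ra_pair(lo, tr)
#> Ra = 9.546 um (longitudinal 6.364, transversal 12.73)

## surface: microrelief morphometry of a synthetic replica
rep <- generate_replica(replica_spec(n_seeds = 36, seed = 7))
lab <- segment_replica(rep$image, h = 10)
feats <- extract_features(lab, mm_per_pixel = 0.05)
summarize_morphometry(feats, analysed_area_mm2 = 15^2)
#> morphometry: NP 0.0889 /mm2, area 5.18 mm2, perimeter 9.55 mm,
#>   Lc 4.62 mm, aspect 1.46 (n = 20)

## cohort: median split on Lc and low/high group comparisons
res <- run_pipeline(run_config(seed = 7))
subset(res$table2, variable %in% c("r_ec", "lc_mm", "age_years"))
#>     variable  mean_low mean_high      p_value        label
#> 1       r_ec 0.0266454 0.0622819 2.357706e-04 p = 0.000236
#> 2      lc_mm 1.5759273 2.3084162 8.151536e-05 p = 8.15e-05
#> 10 age_years 84.762111 85.554879 4.701008e-01        N.S.D
res$correlation["lc_mm", "r_ec"]
#> [1] 0.958
```

Reading the output: the recovered R_EC (0.0166) matches the planted
mask-derived ratio (0.0167); the sine profiles return their closed-form
roughness 2A/π (6.366 and 12.732 µm); the replica summary reports the
interior polygons of the segmentation; and in the simulated cohort the
Elastin-to-Collagen ratio is significantly higher in the high-Lc group
while age is not ("N.S.D"), reflecting the planted latent structure
(r = 0.958 in this single cohort of 22).

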