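# nftburden

Clinicopathologic analysis of neurofibrillary tangle (NFT) burden on
digitized, p-tau immunostained hippocampal sections.

In primary age-related tauopathy (PART) and related conditions, the link
between tangle pathology and antemortem cognition is obscured by
semi-quantitative staging: Braak stage tracks the anatomical spread of
pathology, not its magnitude, and two slides with very different tangle
loads can share a stage. When a segmentation model supplies every tangle's
centroid and pixel area on a whole-slide image, the burden question becomes
quantitative. `nftburden` takes those segmentation outputs — per-slide NFT
object tables plus region annotations for the hippocampus proper and
entorhinal cortex — and computes:

- **Regional burden metrics.** NFT count density (counts/mm²), NFT
  positive-pixel density (Σ tangle area / region area), and a normalized
  0–1 positive-pixel burden from externally supplied immunoreactivity
  counts; regions are reported separately and pooled ("combined").
- **A spatial clustering statistic.** The NFT centroids of a slide are
  turned into a geometric graph: nodes are tangles, and an edge joins two
  tangles whose Euclidean distance is below a threshold *r*. The slide's
  summary is the mean local clustering coefficient

  C̄(r) = (1/n) Σᵢ 2Tᵢ / (kᵢ(kᵢ−1)),

  with Tᵢ the triangles through node *i* and kᵢ its degree (degree < 2
  contributes 0). Because no canonical inter-tangle distance exists, C̄ is
  evaluated over a sweep r = 100, 200, …, 5000 px (50.66–2533 µm at the
  default 0.5066 µm/px pitch). The total tangle count always accompanies
  this metric as a nuisance covariate, since the coefficient of a radius
  graph confounds arrangement with density.
- **The statistical battery.** Group descriptives with Yates/Pearson
  chi-squares and Welch t-tests; Cochran–Mantel–Haenszel age-stratified
  pooled odds ratios; per-SD logistic odds ratios of cognitive impairment
  for every burden measure, unadjusted and age-adjusted, with
  Benjamini–Hochberg FDR within each condition; an odds-ratio-versus-radius
  curve with Wald confidence bands; Spearman/Pearson correlations and
  two-way ANOVA for sub-measure analyses.
- **A synthetic cohort generator.** Truncated-normal ages (mean 85, range
  55–110), per-slide counts log-linear in age (count–age correlation
  calibrated to 0.3), Thomas-process (clustered) versus homogeneous Poisson
  (dispersed) spatial patterns, and a logistic outcome model with a per-SD
  burden odds ratio of 1.40 — so the whole pipeline is testable without any
  autopsy data.

Cognitive status is dichotomized by the standard rule: CDR ≥ 0.5 or
MMSE < 26 ⇒ impaired; with both scores on record the more recent decides
and same-date ties go to CDR; with neither, a chart-review flag decides.

## Worked example

```r
library(nftburden)

# a 50-subject synthetic cohort written in the package's on-disk formats
dir <- tempfile()
simulate_cohort(cohort_sim_params(n_subjects = 50, seed = 3), dir = dir)

cfg <- pipeline_config(
  cohort_path  = file.path(dir, "cohort.csv"),
  slide_dir    = file.path(dir, "nft_tables"),
  regions_path = file.path(dir, "regions.geojson"),
  out_dir      = file.path(dir, "out"))
report <- run_full_pipeline(cfg)
report$descriptives[4:5, 1:4]
#>      variable     test statistic    p_value
#> 4 braak_stage chi2_rxc  4.202132 0.52069620
#> 5 age_at_death welch_t  1.807758 0.07733068
```

The descriptives say: in this small cohort the Braak-stage distribution
does not differ between impaired and unimpaired subjects (p = 0.52), and
impaired subjects are older by a margin short of significance at n = 50
(Welch p = 0.077). The battery and curve live in `report$battery` (one
per-SD odds-ratio row per measure, unadjusted and age-adjusted, FDR within
condition) and `report$or_curve` (odds ratio per radius with its 95% band);
the same tables are written as CSV/JSON under `out_dir`. Single slides can
be analysed directly:

```r
regs  <- read_region_geojson(file.path(dir, "regions.geojson"))
nfts  <- assign_regions(read_nft_table(
           file.path(dir, "nft_tables", "s0001.csv")), regs)
slide <- slide_record("s0001", nfts, regs)
burden_metrics(slide)
#>   subject_id      region nft_count region_area_mm2 nft_count_density nft_pixel_density positive_pixel_burden
#> 1      s0001 hippocampus        37        32.21591          1.148501      0.0001754033                    NA
#> 2      s0001  entorhinal        83        50.01470          1.659512      0.0002748974                    NA
#> 3      s0001    combined       120        82.23061          1.459311      0.0002359181                    NA
clustering_sweep(nfts[, c("x", "y")], subject_id = "s0001")
#> <clustering_sweep> subject s0001: 120 NFTs, 50 radii (100..5000 px)
#>   mean_cc range 0.0250 .. 0.9602
```

A thin CLI wraps the same functions: `exec/nftburden simulate|validate|run
--config config.yaml`.

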