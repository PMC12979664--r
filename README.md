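# galidr

Screening and biophysical statistics for galectin intrinsically disordered
regions (IDRs).

Galectins are β-galactoside-binding lectins built around a folded
carbohydrate-recognition domain (CRD). In several vertebrate lineages the
CRD is tethered to a long, aromatic-rich disordered region whose repeated
"sticker" motifs drive self-association, phase separation, and the
agglutination of glycosylated particles. `galidr` is an R toolkit for
studying how such IDRs are detected, composed, and compared: it implements
the full proteome-screening funnel for CRD homologs with long disordered
regions, a transparent exact-repeat finder for aromatic sticker motifs, the
NMR relaxation and chemical-shift statistics used to quantify
self-association, and the supporting wet-lab assay computations — together
with seeded synthetic-data generators that plant known ground truth so
every stage is testable end to end.

It is aimed at structural biologists and sequence-evolution researchers who
want these analyses as composable, tidyverse-style functions: every
user-facing function takes a data frame and returns a tibble, fitted
objects have broom-style `tidy()`/`glance()` methods, and each result type
has a ggplot2 view.

## What it computes

**Screening funnel.** Candidate homologs are kept when a Smith–Waterman
local alignment against a reference CRD (BLOSUM62, affine gaps 11/1)
reaches ≥ 21% identity, where identity is counted over all alignment
columns including gaps. A protein enters the IDR set when its per-residue
disorder scores (from any external predictor) exceed 0.5 for at least 75
consecutive residues. The primary stretch is profiled by residue class, and
passes the composition filter when aromatic content (F+Y+W) > 8% and acidic
content (D+E) < 3% (both strict). Clade-level %W/%F/%Y distributions are
summarized as Tukey boxplot statistics (whiskers at 1.5 × IQR).

**Motif repetition.** `find_repeats()` enumerates every exactly repeated
k-mer (3 ≤ k ≤ 8, overlaps counted) and suppresses sub-motifs whose
occurrences are fully explained by a longer motif, giving a deterministic,
oracle-checkable measure of sticker-motif valence
(`aromatic_repeat_load()`). `nterm_conservation()` scores the best ungapped
placement of a conserved N-terminal reference fragment.

**NMR dynamics.** Relaxation series are fitted per residue as
`I(t) = I0·exp(−R·t)`, with standard errors from parametric Monte Carlo
refits (n = 500 by default). Residue-wise rates are aggregated per
condition with inverse-variance weighting,

    mean = Σ(x_i/se_i²) / Σ(1/se_i²),   se = sqrt(1 / Σ(1/se_i²)),

and conditions are compared through |ΔR2|, |ΔR1| and |Δ(R2/R1)| with
standard errors propagated in quadrature. Concentration-dependent rate
changes of two constructs are compared with an exact one-sided binomial
sign test on the per-residue difference-of-differences ΔΔR2. Chemical
shift perturbations combine 1H and 15N displacements as
`CSP = sqrt(ΔδH² + (0.14·ΔδN)²)` with a 0.01 ppm flagging threshold.

**Assays.** CD machine units convert to molar extinction differences via
`Δε = θ·0.1·MRW/(l·C·3298)`; Bradford assays are calibrated by ordinary
least squares of BSA concentrations on A594/A466 ratios; agglutination
strength is quantified as the supernatant-over-total protein fraction S/T
with replicate summaries.

## Worked example

```r
library(galidr)
library(tibble)

# a synthetic proteome with planted IDRs, screened at the default thresholds
spec   <- proteome_spec(n_homologs = 20, n_decoys = 20, seed = 1)
pop    <- sim_proteome(spec)
scores <- sim_disorder_scores(pop$records, pop$truth, noise_sd = 0.05, seed = 2)
scr    <- screen_proteome(pop$records, scores, reference = spec$crd_template)
scr$funnel
#> # A tibble: 4 × 2
#>   stage                n
#>   <chr>            <int>
#> 1 input               40
#> 2 identity_pass       40
#> 3 idr_pass            20
#> 4 composition_pass    20
```

All 40 records align to the CRD template above 21% identity (local
alignments of random sequences clear that bar easily — the discriminating
stages come later), but only the 20 homologs carry a ≥ 75-residue
disordered stretch, and all 20 pass the composition filter:

```r
scr$annotations[1:3, c("accession", "start", "end",
                       "pct_aromatic", "pct_negative", "pass_filter")]
#> # A tibble: 3 × 6
#>   accession start   end pct_aromatic pct_negative pass_filter
#>   <chr>     <int> <int>        <dbl>        <dbl> <lgl>
#> 1 HOM0001       1   154         11.0         1.95 TRUE
#> 2 HOM0002       1   114         10.5         2.63 TRUE
#> 3 HOM0003       1   151         11.3         1.99 TRUE
```

A two-condition relaxation comparison (the 40 vs 400 µM self-association
experiment in miniature): per-residue fits with Monte Carlo errors, then
inverse-variance weighted aggregation per condition:

```r
tr <- relax_truth(
  rates = tibble(
    condition = rep(c("40uM", "400uM"), each = 20),
    rate_type = "R2", residue = rep(1:20, 2),
    rate = c(runif(20, 16.5, 17.5), runif(20, 20.5, 21.5))
  ),
  noise_sigma = 0.01
)
est <- fit_rates(sim_relaxation(tr, seed = 3), n_mc = 500, seed = 4,
                 noise_sigma = 1)
dplyr::bind_rows(
  ivw_combine(est[est$condition == "40uM", ]),
  ivw_combine(est[est$condition == "400uM", ])
)
#> # A tibble: 2 × 3
#>    mean     se n_used
#>   <dbl>  <dbl>  <int>
#> 1  17.0 0.0689     20
#> 2  21.0 0.0888     20
```

The rate increase at the higher concentration (here planted: ~17 → ~21 1/s)
is the signature of concentration-dependent self-association; `condition_stats()`
and `condition_compare()` turn these aggregates into the full
|ΔR2| / |Δ(R2/R1)| comparison table, and `run_pipeline()` chains all stages
with one root seed and a manifest.

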