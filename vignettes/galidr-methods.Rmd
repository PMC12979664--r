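---
title: "Methods: screening, motif, NMR and assay statistics in galidr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: screening, motif, NMR and assay statistics in galidr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(galidr)
```

# Scope and model

`galidr` analyzes galectin-family proteins that combine a folded
carbohydrate-recognition domain (CRD) with a long intrinsically disordered
region (IDR). The package covers four connected analyses:

1. a proteome **screening funnel** that finds CRD homologs carrying long
   disordered regions of a particular amino-acid composition;
2. **motif-repetition** statistics inside those IDRs, because repeated
   aromatic "sticker" motifs are the multivalent units that drive
   self-association and phase separation;
3. **NMR observables** of self-association: concentration-dependent
   R1/R2 relaxation rates with Monte Carlo uncertainties, aggregated
   per condition and compared between conditions and constructs;
4. **assay computations** (CD unit conversion, Bradford calibration,
   agglutination supernatant fractions) supporting the wet-lab side.

A synthetic-data module generates every input the pipeline consumes, with
machine-readable ground truth, so each stage can be validated by parameter
recovery rather than by fixture files.

# The screening funnel

## Homolog detection

The funnel's first stage asks whether a sequence is a CRD homolog at all.
`align_identity()` computes an optimal local (Smith–Waterman) alignment,
by default under BLOSUM62 with affine gap penalties (opening 11,
extension 1), via `Biostrings::pairwiseAlignment()`. Percent identity is
defined BLAST-like as identical columns divided by **all** alignment
columns, gaps included; this denominator choice is recorded in every
result row. The default acceptance threshold is identity ≥ 21%.

Two points deserve emphasis:

* **E-values are passthrough metadata.** A database search quotes
  E-values against a database size; a pairwise stand-in has none, so
  `filter_hits()` thresholds identity (and optionally alignment length),
  and `read_hit_table()` lets externally produced tabular hit lists (the
  standard 12-column format) enter the funnel verbatim.
* **Nonstandard letters** (U/J/O, which BLOSUM62 lacks) are mapped to X
  before alignment and therefore score at mismatch level; the policy
  string travels with the result.

Whether the 21% criterion should be computed over the full query or only
the aligned region is ambiguous in general; the package reports the
aligned-region statistics (`aln_length`, `n_identical`) alongside the
percentage so either convention can be recovered.

## Disordered-stretch calling

`call_idr_stretches()` consumes per-residue disorder scores in [0, 1]
from any predictor and returns every **maximal run** of scores strictly
greater than the threshold (default 0.5) with length at least `min_len`
(default 75 residues). Comparisons are strict — a score of exactly 0.5
terminates a run, and a stretch of exactly 74 residues is discarded —
because the criteria are stated as strict inequalities. Runs are strictly
consecutive: no smoothing over sub-threshold interruptions is applied, so
a single low-scoring residue splits a stretch. All qualifying stretches
are reported; the longest per protein is tagged `primary` (ties going to
the most N-terminal), and the primary stretch is the one profiled by the
composition stage. This is lossless: nothing forces a protein to have only
one disordered region.

**Intervals are 1-based inclusive everywhere.** R indexes from 1, residue
numbering in structural biology starts at 1, and keeping a single
convention end to end removes a class of off-by-one translation errors
that a mixed half-open/closed scheme invites.

## Composition profiling and filtering

`composition_profile()` counts residues into a fixed partition: aromatic
(F+Y+W), negatively charged (D+E), positively charged (K+R), P, G, A,
`other` (remaining standard residues) and `nonstandard` (X/B/Z/U/J/O).
The eight classes partition the sequence, so their percentages sum to
100 exactly; nonstandard letters sit in their own class — they never
inflate a named class but always count in the length denominator. The
individual %F, %Y, %W are carried separately because the aromatic *type*
(not just the total) differs between vertebrate clades.

`composition_filter()` passes an IDR when aromatic > 8% **and**
negative < 3%, both strict. `clade_aromatic_stats()` summarizes %W/%F/%Y
per clade as Tukey boxplot statistics: median, quartiles under the
linear-interpolation convention (`stats::quantile()` type 7, the R
default), IQR, and whiskers at the most extreme observations within
1.5 × IQR of the quartiles.

# Motif repetition

`find_repeats()` replaces probabilistic motif discovery with an exact,
deterministic enumeration, because the scientific quantity of interest
here is *how often* an aromatic-containing unit is repeated, not a motif
model's significance. Its semantics:

* every k-mer with 3 ≤ k ≤ 8 occurring at least twice is a candidate;
* **overlapping occurrences count** (so `AAAA` contains `AAA` twice) —
  this makes counts deterministic and brute-force checkable, at the price
  of inflating counts in homopolymer runs, which is documented so counts
  are comparable across analyses;
* a candidate is **suppressed** when it is a substring of a longer
  reported motif with the identical occurrence multiset (positions shifted
  by the containment offset) — each repeat block is then reported once, at
  maximal extent;
* output is ordered by count (desc), then length (desc), then
  alphabetically.

One subtlety follows from the suppression rule: in a perfectly periodic
region, several distinct maximal motifs can legitimately coexist (e.g. a
tetrapeptide repeated three times and its one-residue-extended variant
also occurring three times at shifted positions). When a specific repeat
unit is the biological question — say, counting tetrapeptide stickers —
restrict the scan with `k_min = k_max = 4`; `aromatic_repeat_load()` then
sums the occurrences of aromatic-containing motifs, giving the sticker
valence. The packaged synthetic construct pair
(`inst/extdata/synthetic_zfgal_constructs.fasta`, a stand-in built for
this purpose and labelled synthetic) encodes a native-like W-rich IDR and
an augmented variant with each of its six tryptophan tetrapeptides
duplicated once; their load difference is exactly 6.

`nterm_conservation()` scores the best **ungapped** placement of a
reference fragment (default: the conserved fragment spanning residues
5–20 of human galectin-3) within the first 30 residues of a target,
maximizing identity with ties resolved toward the N-terminus. Targets
shorter than the fragment are scored over the available overlap and
flagged `truncated`. Gapless placement is intentional: the fragment is
short, and a gapped alignment would blur the offset information the
analysis needs.

# NMR relaxation statistics

## Per-residue fits

Each relaxation series is fitted as a two-parameter monoexponential
decay, I(t) = I0·exp(−R·t), by Levenberg–Marquardt least squares
(`minpack.lm::nlsLM`), initialized from a log-linear regression of the
positive intensities. Fits that fail to converge or return a negative
rate are flagged and excluded from all aggregation.

The standard error of R comes from **parametric Monte Carlo**: `n_mc`
(default 500) synthetic series are drawn from the best-fit curve plus
Gaussian noise and refitted; the SE is the standard deviation of the
refitted rates. The refits run through a vectorized Gauss–Newton solver
of the same least-squares objective (all `n_mc` replicates as columns of
one matrix), which the test suite cross-checks against `nlsLM` to 1e-5;
this keeps 500 refits per residue cheap enough to use everywhere.

The noise standard deviation can be **supplied** (the experimentalist's
spectral noise floor) or **estimated** from the fit residuals as
sqrt(SSE/(n−2)). Supplied noise is preferred whenever available: with
8-point series, residual-based variance estimates are themselves noisy,
and inverse-variance weights built from them are unstable — the
pipeline's synthetic runs pass the generator's known noise level to the
fitter for exactly this reason, and with it the planted condition
differences are recovered well within their 3-SE bands across seeds.

## Aggregation and condition comparison

Residue-wise estimates are combined by inverse-variance weighting (IVW):
mean = Σ(x_i/se_i²)/Σ(1/se_i²), se = sqrt(1/Σ(1/se_i²)). Aggregation can
be restricted to an explicit residue inclusion list (e.g. assigned CRD
residues only — IDR resonances are typically unassigned and
uninformative for CRD-site analysis). Per condition, `condition_stats()`
reports IVW R2 and R1 and their ratio with the propagated SE
r·sqrt((se_R2/R2)² + (se_R1/R1)²); `condition_compare()` forms
|ΔR2|, |ΔR1| and |Δ(R2/R1)| between conditions with SEs added in
quadrature. All arithmetic uses unrounded aggregates; printed-table
comparisons in the tests use one unit in the last printed digit as
tolerance.

## The ΔΔR2 sign test

To ask whether one construct's concentration-dependent R2 change exceeds
another's, `ddr2_sign_test()` forms the per-residue
difference-of-differences ΔΔR2 on the intersected residue set, drops
exact ties, and computes the exact binomial tail
p = P(X ≥ n_positive), X ~ Binomial(n_nonzero, ½). The default is
one-sided for a positive shift (the direction of increased
self-association); a two-sided variant is available by flag. The
implementation uses `stats::pbinom`; the tests verify it against direct
enumeration of binomial coefficients for every n ≤ 20.

## Chemical shift perturbations and intensity ratios

The combined 1H/15N perturbation is CSP = sqrt(ΔδH² + (α·ΔδN)²) with
α = 0.14, the community-standard 15N scaling that compensates the
nitrogen shift range. **The combination formula and weight are package
choices** — different labs use slightly different α — so both are
explicit arguments; α = 0 degenerates to |ΔδH|. Residues with
CSP > 0.01 ppm are flagged as perturbed (an intentionally simple
threshold for highlighting the strongest perturbations; configurable).
Peak lists are matched by assignment string, duplicate assignments are an
error, and unmatched peaks are reported in an attribute rather than
silently dropped. `intensity_ratio()` reports per-residue intensity
ratios, optionally median-normalized, with zero denominators flagged and
excluded; a scalar expected ratio (e.g. a molar ratio) can be supplied to
flag residues attenuated below it.

# Assay computations

* **CD conversion**: Δε = θ·0.1·MRW/(l·C·3298), with MRW the mean residue
  weight (Da), l the path length (cm), C the concentration (mg/ml);
  linear in θ and inversely proportional to l and C (property-tested).
  Secondary-structure deconvolution is out of scope; only the conversion
  feeding it is computed.
* **Bradford calibration**: unweighted ordinary least squares of known
  BSA standard concentrations on A594/A466 ratios (no weighting scheme is
  assumed because none is standard for this ratiometric variant).
  Predictions more than 10% outside the standards' ratio range are
  flagged as extrapolated — the assay is only trusted in its linear
  range.
* **Agglutination**: S/T = mean(supernatant)/total with sd/T; a lower
  fraction means stronger agglutination (more protein pelleted with the
  LPS micelles). Replicate means exceeding T by more than 5% are flagged
  as assay anomalies. OD600 turbidity replicates go through the same
  mean ± sd summarizer; no kinetic model is fitted.

# The synthetic-data generators

The generators emulate the *structure* of the real inputs, not their full
biology:

* **Proteomes** (`sim_proteome()`): homologs are built as a conserved
  N-terminal motif + disordered region + mutated CRD template. The IDR is
  a P/G/A/S/Q/T-rich filler (weights P .30, G .25, A .20, S .15, Q .05,
  T .05 — a chordate-like, proline/glycine/alanine-dominated composition)
  carrying 3–8 copies of a clade-specific aromatic tetrapeptide
  (tryptophan-based in fish, tyrosine-based in mammals, mirroring the
  clade-specific aromatic preferences of vertebrate galectin IDRs), with
  total aromatic content 12% (above the 8% filter) and acidic content 1%
  (below the 3% filter) by construction. Aromatic residue *types* are
  apportioned exactly (largest-remainder) to per-clade weights, so
  realized per-type content tracks the requested weights to well within
  2 percentage points for IDRs ≥ 100 residues. Decoys are uniform random
  sequences guaranteed not to contain any planted motif.
* **Disorder scores** are synthesized two-level signals (mean 0.8 inside
  the planted region, 0.2 outside, Gaussian noise, clipped to [0, 1]) —
  the package's contract is "scores in, stretches out", and predicting
  disorder is an external tool's job. Consequently, passing recovery
  tests shows the *caller* is correct, not that any predictor is.
* **Relaxation series** are exact monoexponentials plus i.i.d. Gaussian
  noise — no exchange contributions, no cross-correlated relaxation, one
  delay grid for both R1 and R2.
* **Peak lists** plant a fixed (ΔδH, ΔδN) on a residue subset plus
  positional jitter; no peak overlap or missing assignments are
  simulated (unmatched-peak handling is tested separately).
* **Assays** place standards exactly on a line and encode chosen S/T
  fractions, with optional relative noise.

What the generators deliberately do **not** model: phylogenetic
correlation between homologs, realistic disorder-predictor behavior,
spectral artifacts, or concentration-dependent exchange broadening.
Recovery tests on synthetic data therefore validate the statistical
machinery, not the upstream measurement processes.

All randomness flows from one root seed through named substreams (a
deterministic seed-mixing function keyed by stage name), so stages are
individually reproducible and the whole pipeline is byte-stable under a
fixed configuration.

# Orchestration and validation sizes

`pipeline_config()` holds every threshold with the defaults above
(disorder 0.5, length 75, aromatic 8, acidic 3, identity 21, CSP α 0.14
and flag 0.01 ppm, n_mc 500); `run_pipeline()` executes the stages in
dependency order, writes stage outputs and a manifest (package version,
seed, thresholds, timings, output digests) when a run directory is set,
and computes a recovery table against the generator truth.
`make_report()` assembles the funnel counts and a condition-comparison
table laid out with one column per concentration and rows R2, |ΔR2|, R1,
|ΔR1|, R2/R1, |Δ(R2/R1)|.

Validation sizes used by the test suite and the acceptance script were
chosen to make the checks statistically meaningful while keeping a full
run inside a few minutes on one core: 1,000 random score vectors and 500
random 200-mers for the oracle-equivalence properties, 200 records for
screening recall (≥ 95% boundary recovery within ±3 residues at noise
sd 0.05), 30 residues × 2 conditions at n_mc = 500 for the Table-style
condition comparison, 40 residues for the sign-test arm, and triplicate
assays at 1% noise.

# Known limitations

* The exact-repeat finder ignores degenerate motifs (one mismatch
  tolerance is reserved as an extension but off by default); it
  intentionally does not reproduce probabilistic motif-discovery output.
* The Monte Carlo error model resamples from the fitted curve with
  homoscedastic Gaussian noise; heteroscedastic or correlated spectral
  noise is not modeled.
* IVW aggregation with residual-estimated SEs from very short series is
  noisy (see above); supply a measured noise level when you have one.
* The identity stage is a pairwise stand-in: it ranks and filters
  sequences you give it, it does not search a database.
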