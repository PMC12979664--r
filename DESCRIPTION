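Package: galidr
Title: Screening and Biophysical Statistics for Galectin Intrinsically
    Disordered Regions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study how long intrinsically disordered regions (IDRs)
    tethered to galectin carbohydrate-recognition domains (CRDs) evolved and
    drive phase-separation-mediated agglutination.  Implements a proteome
    screening funnel (local-alignment identity filter, disordered-stretch
    calling from per-residue disorder scores, amino-acid composition
    profiling and filtering, clade-level aromatic statistics), an exact
    repeated-motif finder for IDR sticker motifs and N-terminal conservation
    scoring, NMR relaxation statistics (monoexponential R1/R2 fitting with
    Monte Carlo uncertainties, inverse-variance weighted aggregation,
    propagated condition comparisons, a paired sign test on rate changes,
    chemical shift perturbation and intensity-ratio mapping), wet-lab assay
    computations (circular dichroism molar extinction conversion, Bradford
    ratio calibration, agglutination supernatant fractions), and seeded
    synthetic-data generators with recorded ground truth for end-to-end
    validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
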