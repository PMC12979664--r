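# The generators must plant exactly what they claim to plant, and be
# deterministic under a fixed seed.

test_that("an empty proteome spec yields empty records and truth", {
  pop <- sim_proteome(proteome_spec(n_homologs = 0, n_decoys = 0, seed = 1))
  expect_equal(nrow(pop$records), 0)
  expect_equal(nrow(pop$truth), 0)
  expect_named(
    pop$records, c("accession", "sequence", "clade")
  )
})

test_that("proteome generation is deterministic and validates its spec", {
  spec <- proteome_spec(n_homologs = 4, n_decoys = 4, seed = 99)
  a <- sim_proteome(spec)
  b <- sim_proteome(spec)
  expect_identical(a, b)
  expect_error(proteome_spec(crd_template = ""), "non-empty")
  expect_error(
    proteome_spec(aromatic_weights = list(c(F = 0.5, Y = 0.4, W = 0.2))),
    "sum to 1"
  )
  expect_error(proteome_spec(repeat_motif = "PGA"), "aromatic")
})

test_that("planted repeats appear at least the planted number of times", {
  spec <- proteome_spec(
    n_homologs = 10, n_decoys = 0,
    n_repeats_range = c(3L, 3L), seed = 5
  )
  pop <- sim_proteome(spec)
  for (i in seq_len(nrow(pop$truth))) {
    tr <- pop$truth[i, ]
    seqs <- pop$records$sequence[pop$records$accession == tr$accession]
    idr <- substr(seqs, tr$idr_start, tr$idr_end)
    hits <- gregexpr(paste0("(?=", tr$repeat_motif, ")"), idr, perl = TRUE)[[1]]
    expect_gte(sum(hits > 0), 3)
  }
  # decoys never carry a planted motif
  spec2 <- proteome_spec(n_homologs = 0, n_decoys = 10, seed = 5)
  pop2 <- sim_proteome(spec2)
  for (m in unique(spec2$repeat_motif)) {
    expect_false(any(grepl(m, pop2$records$sequence, fixed = TRUE)))
  }
})

test_that("generated IDRs are P/G/A-enriched and track the aromatic weights", {
  spec <- proteome_spec(
    n_homologs = 25, n_decoys = 0,
    idr_length_range = c(120L, 160L), n_repeats_range = c(3L, 6L), seed = 11
  )
  pop <- sim_proteome(spec)
  nt <- nchar(spec$nterm_motif)
  for (i in seq_len(nrow(pop$truth))) {
    tr <- pop$truth[i, ]
    s <- pop$records$sequence[pop$records$accession == tr$accession]
    prof <- composition_profile(substr(s, nt + 1, tr$idr_end))
    # chordate-like filler: P+G+A well above the uniform expectation of 15%
    expect_gt(prof$pct_P + prof$pct_G + prof$pct_A, 30)
    w <- spec$aromatic_weights[[tr$clade]]
    requested <- 100 * spec$idr_aromatic_frac * w[c("F", "Y", "W")]
    realized <- c(prof$pct_F, prof$pct_Y, prof$pct_W)
    expect_lt(max(abs(realized - requested)), 2)
  }
})

test_that("noiseless disorder scores are exactly two-level", {
  spec <- proteome_spec(n_homologs = 3, n_decoys = 2, seed = 2)
  pop <- sim_proteome(spec)
  sc <- sim_disorder_scores(pop$records, pop$truth, noise_sd = 0, seed = 1)
  for (i in seq_len(nrow(pop$truth))) {
    tr <- pop$truth[i, ]
    s <- sc[sc$accession == tr$accession, ]
    if (tr$has_idr) {
      expect_true(all(s$score[seq(tr$idr_start, tr$idr_end)] == 0.8))
      expect_true(all(s$score[-seq(tr$idr_start, tr$idr_end)] == 0.2))
    } else {
      expect_true(all(s$score == 0.2))
    }
  }
  expect_error(
    sim_disorder_scores(pop$records[-1, ], pop$truth, noise_sd = 0, seed = 1),
    "different accessions"
  )
})

test_that("decoy-only score tables never contain a 75-residue stretch", {
  spec <- proteome_spec(n_homologs = 0, n_decoys = 20, seed = 3)
  pop <- sim_proteome(spec)
  sc <- sim_disorder_scores(pop$records, pop$truth, noise_sd = 0.05, seed = 4)
  for (acc in unique(sc$accession)) {
    runs <- oracle_runs(sc$score[sc$accession == acc], 0.5, 75)
    expect_equal(nrow(runs), 0)
  }
})

test_that("relaxation series follow the closed-form decay when noiseless", {
  tr <- relax_truth(
    rates = tibble::tibble(condition = "a", residue = 1L, rate = 2),
    i0 = 100, noise_sigma = 0, delays = c(0, 0.1, 0.5)
  )
  out <- sim_relaxation(tr, seed = 1)
  expect_equal(out$intensity, 100 * exp(-2 * c(0, 0.1, 0.5)))
  expect_identical(sim_relaxation(tr, seed = 7), sim_relaxation(tr, seed = 7))
  expect_error(
    relax_truth(
      rates = tibble::tibble(condition = "a", residue = 1L, rate = 2),
      i0 = -1
    ),
    "positive"
  )
  expect_error(
    relax_truth(
      rates = tibble::tibble(condition = "a", residue = 1L, rate = -2)
    ),
    "> 0"
  )
})

test_that("peak lists plant the requested shift and nothing else", {
  pk <- sim_peaklists(20,
    shifted_subset = 1:5, d_h = 0.02, d_n = 0.1,
    jitter_h = 0, jitter_n = 0, seed = 1
  )
  res <- csp(pk$reference, pk$perturbed, alpha = 0.14)
  # closed form: sqrt(0.02^2 + (0.14 * 0.1)^2)
  expected <- sqrt(0.02^2 + 0.014^2)
  expect_equal(res$csp[res$residue %in% 1:5], rep(expected, 5), tolerance = 1e-12)
  expect_equal(res$csp[!res$residue %in% 1:5], rep(0, 15))
  expect_true(all(res$flagged[res$residue %in% 1:5]))
  expect_false(any(res$flagged[!res$residue %in% 1:5]))
  # zero shift, zero jitter: identically zero CSP
  pk0 <- sim_peaklists(10, shifted_subset = integer(), seed = 2)
  expect_equal(csp(pk0$reference, pk0$perturbed)$csp, rep(0, 10))
})

test_that("noiseless assay tables encode the calibration and S/T exactly", {
  at <- sim_assays(
    slope = 20, intercept = -10, s_over_t = c(x = 0.25),
    noise = 0, seed = 1
  )
  cal <- bradford_fit(at$standards)
  expect_equal(cal$slope, 20, tolerance = 1e-9)
  expect_equal(cal$intercept, -10, tolerance = 1e-9)
  pred <- bradford_predict(cal, at$samples)
  ag <- agglutination_table(
    tibble::tibble(
      construct = pred$construct,
      s_conc = pred$conc / at$truth$ug_per_um
    ),
    total = at$truth$total_um
  )
  expect_equal(ag$fraction, 0.25, tolerance = 1e-9)
})
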