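# Screening funnel: stretch calling, composition, filtering, clade stats,
# and the alignment identity stage.

score_tbl <- function(score, acc = "p1") {
  tibble::tibble(accession = acc, position = seq_along(score), score = score)
}

test_that("stretch caller handles the simple cases", {
  expect_equal(nrow(call_idr_stretches(score_tbl(rep(0.2, 100)))), 0)

  one <- call_idr_stretches(score_tbl(rep(0.9, 100)))
  expect_equal(nrow(one), 1)
  expect_equal(one$start, 1L)
  expect_equal(one$end, 100L)
  expect_true(one$primary)

  # an 80-run and a 30-run split by a single sub-threshold score: only the
  # 80-run qualifies at min_len 75
  s <- c(rep(0.9, 80), 0.4, rep(0.9, 30))
  got <- call_idr_stretches(score_tbl(s))
  expect_equal(nrow(got), 1)
  expect_equal(c(got$start, got$end), c(1L, 80L))

  # threshold is strict: a run of exactly 0.5 does not count
  expect_equal(nrow(call_idr_stretches(score_tbl(rep(0.5, 100)))), 0)
})

test_that("stretch caller matches brute-force run enumeration", {
  set.seed(401)
  for (i in 1:200) {
    n <- sample(50:200, 1)
    score <- runif(n)
    min_len <- sample(2:20, 1)
    got <- call_idr_stretches(score_tbl(score), threshold = 0.5, min_len = min_len)
    want <- oracle_runs(score, 0.5, min_len)
    expect_equal(nrow(got), nrow(want))
    if (nrow(want) > 0) {
      expect_equal(got$start, want$start)
      expect_equal(got$end, want$end)
    }
  }
})

test_that("multiple qualifying stretches are all reported, longest primary", {
  s <- c(rep(0.9, 20), 0.1, rep(0.9, 40), 0.1, rep(0.9, 30))
  got <- call_idr_stretches(score_tbl(s), min_len = 20)
  expect_equal(nrow(got), 3)
  expect_equal(got$primary, c(FALSE, TRUE, FALSE))
})

test_that("composition counts by hand-checked examples", {
  p <- composition_profile("YYYYDAAAAA")
  expect_equal(p$pct_aromatic, 40)
  expect_equal(p$pct_negative, 10)

  g <- composition_profile(strrep("G", 50))
  expect_equal(g$pct_aromatic, 0)
  expect_equal(g$pct_negative, 0)

  s <- paste0(strrep("Y", 9), strrep("D", 2), strrep("A", 89))
  p2 <- composition_profile(s)
  expect_equal(p2$pct_Y, 9)
  expect_equal(p2$pct_negative, 2)

  # the class percentages partition the sequence
  part <- p2[, c(
    "pct_aromatic", "pct_negative", "pct_positive", "pct_P", "pct_G",
    "pct_A", "pct_other", "pct_nonstandard"
  )]
  expect_equal(sum(unlist(part)), 100, tolerance = 1e-9)

  # nonstandard letters count in the denominator but in no named class
  px <- composition_profile("YXXA")
  expect_equal(px$pct_aromatic, 25)
  expect_equal(px$pct_nonstandard, 50)
})

test_that("composition filter applies strict comparisons", {
  prof <- dplyr::bind_rows(
    composition_profile("YYYYDAAAAA"), # 40% aromatic, 10% negative
    composition_profile(paste0(strrep("Y", 9), strrep("D", 2), strrep("A", 89))),
    composition_profile(paste0(strrep("Y", 8), strrep("A", 92))) # exactly 8%
  )
  got <- composition_filter(prof)
  expect_equal(got$pass_filter, c(FALSE, TRUE, FALSE))
})

test_that("raising thresholds never enlarges the surviving set", {
  set.seed(77)
  spec <- proteome_spec(n_homologs = 15, n_decoys = 5, seed = 21)
  pop <- sim_proteome(spec)
  sc <- sim_disorder_scores(pop$records, pop$truth, noise_sd = 0.05, seed = 3)
  survivors <- function(min_len, aromatic_min) {
    res <- screen_proteome(
      pop$records, sc,
      reference = spec$crd_template,
      min_len = min_len, aromatic_min = aromatic_min
    )
    res$annotations$accession[res$annotations$pass_filter]
  }
  base <- survivors(75, 8)
  expect_true(all(survivors(100, 8) %in% base))
  expect_true(all(survivors(75, 10) %in% base))
})

test_that("clade stats match the quantile definition and whisker rule", {
  prof <- tibble::tibble(
    clade = "fish", pct_F = 1:9, pct_Y = 1:9, pct_W = 1:9
  )
  st <- clade_aromatic_stats(prof)
  expect_equal(unique(st$median), 5)
  expect_equal(unique(st$q1), 3)
  expect_equal(unique(st$q3), 7)
  expect_equal(unique(st$whisker_low), 1)
  expect_equal(unique(st$whisker_high), 9)

  # a single value: degenerate box
  one <- clade_aromatic_stats(
    tibble::tibble(clade = "m", pct_F = 4, pct_Y = 4, pct_W = 4)
  )
  expect_true(all(one$median == 4 & one$q1 == 4 & one$q3 == 4 & one$iqr == 0))
  expect_true(all(one$whisker_low == 4 & one$whisker_high == 4))

  # an outlier beyond 1.5 IQR does not drag the whisker
  out <- clade_aromatic_stats(
    tibble::tibble(clade = "x", pct_F = c(1:9, 100), pct_Y = 1, pct_W = 1)
  )
  fr <- out[out$metric == "pct_F", ]
  expect_equal(fr$whisker_high, 9)

  # quartiles equal the independently re-derived type-7 quantiles
  set.seed(5)
  vals <- runif(23, 0, 15)
  st2 <- clade_aromatic_stats(
    tibble::tibble(clade = "z", pct_F = vals, pct_Y = vals, pct_W = vals)
  )
  expect_equal(st2$q1[1], oracle_quantile7(vals, 0.25))
  expect_equal(st2$q3[1], oracle_quantile7(vals, 0.75))
})

test_that("identical sequences align at 100% identity over the full span", {
  s <- strrep("MKVLA", 10)
  hit <- align_identity(s, s)
  expect_equal(hit$percent_identity, 100)
  expect_equal(hit$target_start, 1L)
  expect_equal(hit$target_end, 50L)
})

test_that("simple-scoring alignment score equals the DP oracle", {
  # the classic textbook pair first
  got <- align_identity("HEAGAWGHEE", "PAWHEAE",
    scoring = "simple",
    match = 2, mismatch = -1, gap_opening = 0, gap_extension = 2
  )
  expect_equal(got$score, oracle_sw_score("HEAGAWGHEE", "PAWHEAE", 2, -1, 2))

  set.seed(303)
  for (i in 1:25) {
    a <- random_protein(sample(5:20, 1), alphabet = c("A", "C", "D", "E", "F", "G", "H"))
    b <- random_protein(sample(5:20, 1), alphabet = c("A", "C", "D", "E", "F", "G", "H"))
    got <- align_identity(a, b,
      scoring = "simple",
      match = 2, mismatch = -1, gap_opening = 0, gap_extension = 2
    )
    expect_equal(got$score, oracle_sw_score(a, b, 2, -1, 2))
  }
})

test_that("hit filtering keeps >= 21% identity and external hits import", {
  hits <- tibble::tibble(
    accession = c("a", "b", "c"),
    percent_identity = c(20.9, 21, 35),
    aln_length = c(100, 100, 10)
  )
  expect_equal(filter_hits(hits)$accession, c("b", "c"))
  expect_equal(filter_hits(hits, min_aln_length = 50)$accession, "b")

  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(
    "q1\thitA\t35.2\t120\t50\t3\t1\t120\t10\t129\t1e-30\t200", f
  )
  imp <- read_hit_table(f)
  expect_equal(imp$accession, "hitA")
  expect_equal(imp$percent_identity, 35.2)
  expect_equal(imp$evalue, 1e-30)
})

test_that("end-to-end screening recovers planted IDRs and rejects decoys", {
  spec <- proteome_spec(n_homologs = 25, n_decoys = 25, seed = 42)
  pop <- sim_proteome(spec)
  sc <- sim_disorder_scores(pop$records, pop$truth, noise_sd = 0.05, seed = 8)
  res <- screen_proteome(pop$records, sc, reference = spec$crd_template)
  truth <- pop$truth
  planted <- truth[truth$has_idr, ]
  found <- dplyr::inner_join(
    planted, res$annotations[, c("accession", "start", "end", "pass_filter")],
    by = "accession"
  )
  ok <- abs(found$start - found$idr_start) <= 3 &
    abs(found$end - found$idr_end) <= 3
  expect_gte(sum(ok) / nrow(planted), 0.95)
  decoy_pass <- res$annotations$pass_filter &
    res$annotations$accession %in% truth$accession[!truth$is_homolog]
  expect_equal(sum(decoy_pass), 0)
  expect_equal(res$funnel$n[res$funnel$stage == "input"], 50)
})
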