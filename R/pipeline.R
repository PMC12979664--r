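# Orchestration: a configuration object whose defaults are the screening
# and analysis thresholds used throughout, a runner that chains the stages
# on synthetic data (generate -> screen -> motifs -> relax -> csp ->
# assays), and a report assembler producing funnel counts and a
# condition-comparison table.

#' Pipeline configuration
#'
#' Collects every stage toggle and threshold.  The threshold defaults are
#' the screening and analysis criteria used throughout the package:
#' disorder score > 0.5 over >= 75 consecutive residues, > 8% aromatic and
#' < 3% acidic IDR composition, >= 21% alignment identity, CSP weight 0.14
#' and flagging threshold 0.01 ppm, 500 Monte Carlo refits.
#'
#' @param stages Character vector of stages to run, in dependency order;
#'   any subset of `c("generate", "screen", "motifs", "relax", "csp",
#'   "assays")`.  Stages other than `"generate"` require the generate stage
#'   (they consume its synthetic inputs).
#' @param seed Root seed; every stage derives a named substream from it.
#' @param disorder_threshold,min_len,aromatic_min,negative_max,identity_min
#'   Screening thresholds.
#' @param csp_alpha,csp_flag CSP combination weight and flagging threshold.
#' @param n_mc Monte Carlo refits per residue fit.
#' @param proteome A [proteome_spec()] for the generate stage (its `seed` is
#'   overridden by the root seed).
#' @param relax List of generator settings for the relaxation arm:
#'   `n_residues`, per-condition mean R2/R1 (`r2_low`, `r2_high`, `r1_low`,
#'   `r1_high`), residue-to-residue spread `spread`, `noise_sigma`,
#'   `delays`, condition labels.
#' @param assays List of generator settings for the assay arm: `slope`,
#'   `intercept`, named `s_over_t`, `noise`, `n_replicates`.
#' @param out_dir Optional run directory; when set, stage outputs and a
#'   manifest are written there.
#'
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(stages = c(
                              "generate", "screen", "motifs",
                              "relax", "csp", "assays"
                            ),
                            seed = 1L,
                            disorder_threshold = 0.5, min_len = 75,
                            aromatic_min = 8, negative_max = 3,
                            identity_min = 21,
                            csp_alpha = 0.14, csp_flag = 0.01,
                            n_mc = 500,
                            proteome = proteome_spec(
                              n_homologs = 30, n_decoys = 30, seed = seed
                            ),
                            relax = list(
                              n_residues = 24,
                              r2_low = 17, r2_high = 21,
                              r1_low = 0.82, r1_high = 0.72,
                              spread = 1, noise_sigma = 0.01,
                              delays = c(0, 0.01, 0.03, 0.05, 0.09, 0.13, 0.17, 0.25),
                              conditions = c("40uM", "400uM")
                            ),
                            assays = list(
                              slope = 20, intercept = -10,
                              s_over_t = c(hGal3 = 0.05, zfGalWY = 0.45, zfGal = 0.30),
                              noise = 0.01, n_replicates = 3
                            ),
                            out_dir = NULL) {
  allowed <- c("generate", "screen", "motifs", "relax", "csp", "assays")
  if (!all(stages %in% allowed)) {
    abort(sprintf(
      "unknown stage(s): %s", paste(setdiff(stages, allowed), collapse = ", ")
    ))
  }
  if (length(setdiff(stages, "generate")) > 0 && !"generate" %in% stages) {
    abort("downstream stages require the 'generate' stage.")
  }
  if ("motifs" %in% stages && !"screen" %in% stages) {
    abort("the 'motifs' stage consumes screening annotations; add 'screen'.")
  }
  proteome$seed <- as.integer(seed)
  structure(
    list(
      stages = stages, seed = as.integer(seed),
      thresholds = list(
        disorder_threshold = disorder_threshold, min_len = min_len,
        aromatic_min = aromatic_min, negative_max = negative_max,
        identity_min = identity_min, csp_alpha = csp_alpha,
        csp_flag = csp_flag, n_mc = n_mc
      ),
      proteome = proteome, relax = relax, assays = assays,
      out_dir = out_dir
    ),
    class = "pipeline_config"
  )
}

relax_truth_from_config <- function(cfg) {
  rl <- cfg$relax
  with_substream(cfg$seed, "relax_truth", {
    res <- seq_len(rl$n_residues)
    base_r2 <- runif(rl$n_residues, -rl$spread, rl$spread)
    base_r1 <- runif(rl$n_residues, -rl$spread, rl$spread) * 0.02
    rates <- dplyr::bind_rows(
      tibble::tibble(
        condition = rl$conditions[1], rate_type = "R2", residue = res,
        rate = rl$r2_low + base_r2
      ),
      tibble::tibble(
        condition = rl$conditions[2], rate_type = "R2", residue = res,
        rate = rl$r2_high + base_r2
      ),
      tibble::tibble(
        condition = rl$conditions[1], rate_type = "R1", residue = res,
        rate = rl$r1_low + base_r1
      ),
      tibble::tibble(
        condition = rl$conditions[2], rate_type = "R1", residue = res,
        rate = rl$r1_high + base_r1
      )
    )
    relax_truth(
      rates = rates, i0 = 100, noise_sigma = rl$noise_sigma,
      delays = rl$delays
    )
  })
}

#' Run the analysis pipeline on synthetic data
#'
#' Executes the configured stages in dependency order, records a manifest
#' (package version, seed, thresholds, stage timings, and md5 digests of
#' written outputs), and, when ground truth is available, a recovery table
#' scoring each stage against what was planted.  Re-running with the same
#' configuration reproduces identical outputs.
#'
#' @param config A [pipeline_config()].
#'
#' @return Object of class `galidr_run`: list with `config`, `results` (one
#'   element per executed stage), `recovery` (tibble of truth-recovery
#'   checks), and `manifest`.
#' @export
#' @examples
#' run <- run_pipeline(pipeline_config(
#'   stages = "generate", seed = 1,
#'   proteome = proteome_spec(n_homologs = 3, n_decoys = 3, seed = 1)
#' ))
#' names(run$results)
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  th <- config$thresholds
  results <- list()
  timings <- list()
  tick <- function(name, expr) {
    t0 <- Sys.time()
    out <- force(expr)
    timings[[name]] <<- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    out
  }

  if ("generate" %in% config$stages) {
    results$generate <- tick("generate", {
      pop <- sim_proteome(config$proteome)
      scores <- sim_disorder_scores(
        pop$records, pop$truth,
        noise_sd = 0.05, seed = substream_seed(config$seed, "scores")
      )
      truth_rx <- relax_truth_from_config(config)
      relax_data <- sim_relaxation(
        truth_rx,
        seed = substream_seed(config$seed, "relax_data")
      )
      n_res <- config$relax$n_residues
      peaks <- sim_peaklists(
        n_res,
        shifted_subset = seq_len(max(1, floor(n_res / 4))),
        d_h = 0.02, d_n = 0.1, jitter_h = 5e-4, jitter_n = 5e-3,
        seed = substream_seed(config$seed, "peaks")
      )
      assay_tabs <- rlang::exec(
        sim_assays,
        !!!config$assays,
        seed = substream_seed(config$seed, "assays")
      )
      list(
        population = pop, scores = scores,
        relax_truth = truth_rx, relax_data = relax_data,
        peaklists = peaks, assays = assay_tabs
      )
    })
  }

  gen <- results$generate
  if ("screen" %in% config$stages) {
    results$screen <- tick("screen", screen_proteome(
      gen$population$records, gen$scores,
      reference = config$proteome$crd_template,
      identity_min = th$identity_min,
      threshold = th$disorder_threshold, min_len = th$min_len,
      aromatic_min = th$aromatic_min, negative_max = th$negative_max
    ))
    results$screen$clade_stats <- clade_aromatic_stats(results$screen$annotations)
  }
  if ("motifs" %in% config$stages) {
    results$motifs <- tick("motifs", {
      ann <- results$screen$annotations
      list(
        repeats = find_repeats_all(ann),
        nterm = dplyr::bind_cols(
          tibble::tibble(accession = gen$population$records$accession),
          dplyr::bind_rows(purrr::map(
            gen$population$records$sequence, nterm_conservation
          ))
        )
      )
    })
  }
  if ("relax" %in% config$stages) {
    results$relax <- tick("relax", {
      # the generator's noise level plays the role of the spectral noise
      # floor an experimentalist would supply to the fitter; with it the
      # Monte Carlo SEs (and hence the IVW weights) are well calibrated
      known_sigma <- gen$relax_truth$noise_sigma * gen$relax_truth$i0
      est <- fit_rates(
        gen$relax_data,
        n_mc = th$n_mc, seed = substream_seed(config$seed, "fits"),
        noise_sigma = if (known_sigma > 0) known_sigma
      )
      stats <- condition_stats(est)
      comp <- condition_compare(
        stats,
        low = config$relax$conditions[1], high = config$relax$conditions[2]
      )
      list(estimates = est, condition_stats = stats, comparison = comp)
    })
  }
  if ("csp" %in% config$stages) {
    results$csp <- tick("csp", {
      pk <- gen$peaklists
      list(
        csp = csp(pk$reference, pk$perturbed,
          alpha = th$csp_alpha, flag_threshold = th$csp_flag
        ),
        intensity = intensity_ratio(pk$reference, pk$perturbed)
      )
    })
  }
  if ("assays" %in% config$stages) {
    results$assays <- tick("assays", {
      at <- gen$assays
      cal <- bradford_fit(at$standards)
      pred <- bradford_predict(cal, at$samples)
      s_tab <- dplyr::summarise(
        dplyr::group_by(pred, construct = .data$construct),
        s_conc = mean(.data$conc), .groups = "drop"
      )
      ag <- agglutination_table(
        dplyr::transmute(pred,
          construct = .data$construct,
          s_conc = .data$conc / at$truth$ug_per_um
        ),
        total = at$truth$total_um
      )
      list(calibration = cal, predictions = pred, agglutination = ag)
    })
  }

  recovery <- assemble_recovery(config, results)
  manifest <- list(
    package = "galidr",
    version = as.character(utils::packageVersion("galidr")),
    seed = config$seed,
    stages = config$stages,
    thresholds = th,
    timings_s = timings
  )
  run <- structure(
    list(
      config = config, results = results,
      recovery = recovery, manifest = manifest
    ),
    class = "galidr_run"
  )
  if (!is.null(config$out_dir)) {
    run$manifest$outputs <- write_run_outputs(run, config$out_dir)
  }
  run
}

assemble_recovery <- function(config, results) {
  checks <- list()
  add <- function(check, value, pass) {
    checks[[length(checks) + 1]] <<- tibble::tibble(
      check = check, value = value, pass = pass
    )
  }
  gen <- results$generate
  if (!is.null(results$screen) && !is.null(gen)) {
    truth <- gen$population$truth
    ann <- results$screen$annotations
    planted <- truth[truth$has_idr, , drop = FALSE]
    if (nrow(planted) > 0) {
      found <- dplyr::inner_join(
        planted, ann[, c("accession", "start", "end")],
        by = "accession"
      )
      ok <- abs(found$start - found$idr_start) <= 3 &
        abs(found$end - found$idr_end) <= 3
      recall <- sum(ok) / nrow(planted)
      add("idr_recall_pm3", recall, recall >= 0.95)
    }
    decoy_surv <- sum(
      ann$pass_filter &
        ann$accession %in% truth$accession[!truth$is_homolog]
    )
    add("decoy_survivors", decoy_surv, decoy_surv == 0)
  }
  if (!is.null(results$motifs) && !is.null(gen)) {
    truth <- gen$population$truth
    reps <- results$motifs$repeats
    planted <- truth[truth$has_idr & truth$accession %in% reps$accession, ]
    if (nrow(planted) > 0) {
      got <- purrr::map2_lgl(
        planted$accession, seq_len(nrow(planted)),
        function(acc, i) {
          sub <- reps[reps$accession == acc & reps$motif == planted$repeat_motif[i], ]
          nrow(sub) > 0 && sub$count[1] >= planted$n_repeats_planted[i]
        }
      )
      add("motif_recovered_frac", mean(got), mean(got) >= 0.95)
    }
  }
  if (!is.null(results$relax) && !is.null(gen)) {
    tr <- gen$relax_truth$rates
    cond <- config$relax$conditions
    true_d <- function(type) {
      abs(
        mean(tr$rate[tr$condition == cond[2] & tr$rate_type == type]) -
          mean(tr$rate[tr$condition == cond[1] & tr$rate_type == type])
      )
    }
    comp <- results$relax$comparison
    z2 <- abs(comp$d_r2 - true_d("R2")) / comp$d_r2_se
    add("delta_r2_recovery_z", z2, z2 <= 3)
  }
  if (!is.null(results$csp) && !is.null(gen)) {
    tru <- gen$peaklists$truth
    got <- results$csp$csp
    j <- dplyr::inner_join(tru, got, by = "residue")
    agree <- mean(j$shifted == j$flagged)
    add("csp_flag_agreement", agree, agree >= 0.95)
  }
  if (!is.null(results$assays) && !is.null(gen)) {
    tru <- gen$assays$truth
    cal <- results$assays$calibration
    slope_err <- abs(cal$slope - tru$slope) / abs(tru$slope)
    add("bradford_slope_rel_err", slope_err, slope_err < 0.05)
    ag <- results$assays$agglutination
    err <- abs(ag$fraction - tru$s_over_t[ag$construct])
    add("s_over_t_max_abs_err", max(err), max(err) < 0.05)
  }
  if (length(checks) == 0) {
    return(tibble::tibble(check = character(), value = numeric(), pass = logical()))
  }
  dplyr::bind_rows(checks)
}

write_run_outputs <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character()
  save_tsv <- function(df, name) {
    path <- file.path(out_dir, name)
    df <- dplyr::mutate(df, dplyr::across(
      dplyr::where(is.list),
      ~ vapply(.x, paste, character(1), collapse = ",")
    ))
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    written <<- c(written, path)
  }
  res <- run$results
  if (!is.null(res$generate)) {
    write_fasta_tbl(
      res$generate$population$records, file.path(out_dir, "records.fasta")
    )
    written <- c(written, file.path(out_dir, "records.fasta"))
    save_tsv(res$generate$scores, "disorder_scores.tsv")
    save_tsv(res$generate$relax_data, "relaxation.tsv")
  }
  if (!is.null(res$screen)) {
    save_tsv(
      res$screen$annotations[, setdiff(names(res$screen$annotations), "idr_seq")],
      "annotations.tsv"
    )
    save_tsv(res$screen$funnel, "funnel.tsv")
    save_tsv(res$screen$clade_stats, "clade_stats.tsv")
  }
  if (!is.null(res$motifs)) {
    save_tsv(res$motifs$repeats, "repeats.tsv")
    save_tsv(res$motifs$nterm, "nterm_conservation.tsv")
  }
  if (!is.null(res$relax)) {
    save_tsv(res$relax$estimates, "rates.tsv")
    save_tsv(res$relax$condition_stats, "condition_stats.tsv")
    save_tsv(res$relax$comparison, "condition_comparison.tsv")
  }
  if (!is.null(res$csp)) {
    save_tsv(res$csp$csp, "csp.tsv")
    save_tsv(res$csp$intensity, "intensity_ratio.tsv")
  }
  if (!is.null(res$assays)) {
    save_tsv(res$assays$agglutination, "agglutination.tsv")
  }
  if (nrow(run$recovery) > 0) save_tsv(run$recovery, "recovery.tsv")
  manifest_path <- file.path(out_dir, "manifest.json")
  digests <- tools::md5sum(written)
  manifest <- run$manifest
  manifest$outputs <- tibble::tibble(
    file = basename(names(digests)), md5 = unname(digests)
  )
  jsonlite::write_json(
    manifest, manifest_path,
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  manifest$outputs
}

#' @export
print.galidr_run <- function(x, ...) {
  cat(sprintf(
    "<galidr_run> seed %d; stages: %s\n",
    x$config$seed, paste(names(x$results), collapse = ", ")
  ))
  if (nrow(x$recovery) > 0) {
    cat(sprintf(
      "  recovery: %d/%d checks pass\n",
      sum(x$recovery$pass), nrow(x$recovery)
    ))
  }
  invisible(x)
}

#' Assemble a run report
#'
#' Builds the machine-readable summary of a pipeline run: the screening
#' funnel counts (input, identity pass, IDR pass, composition pass), a
#' condition-comparison table laid out with one column per concentration
#' (rows R2, |dR2|, R1, |dR1|, R2/R1, |d(R2/R1)|), the truth-recovery
#' checks, and a plain-text rendering.
#'
#' @param run A `galidr_run` from [run_pipeline()].
#'
#' @return List with `funnel`, `condition_table`, `recovery`, and `text`
#'   (character vector of report lines).
#' @export
make_report <- function(run) {
  stopifnot(inherits(run, "galidr_run"))
  res <- run$results
  funnel <- if (!is.null(res$screen)) {
    res$screen$funnel
  } else {
    tibble::tibble(
      stage = c("input", "identity_pass", "idr_pass", "composition_pass"),
      n = rep(0L, 4)
    )
  }
  condition_table <- NULL
  if (!is.null(res$relax)) {
    st <- res$relax$condition_stats
    cmp <- res$relax$comparison
    fmt <- function(m, s) sprintf("%.2f ± %.2f", m, s)
    condition_table <- tibble::tibble(
      quantity = c("R2", "|dR2|", "R1", "|dR1|", "R2/R1", "|d(R2/R1)|")
    )
    for (i in seq_len(nrow(st))) {
      condition_table[[st$condition[i]]] <- c(
        fmt(st$r2[i], st$r2_se[i]),
        if (i == nrow(st)) fmt(cmp$d_r2, cmp$d_r2_se) else "",
        fmt(st$r1[i], st$r1_se[i]),
        if (i == nrow(st)) fmt(cmp$d_r1, cmp$d_r1_se) else "",
        fmt(st$r2_over_r1[i], st$r2_over_r1_se[i]),
        if (i == nrow(st)) fmt(cmp$d_ratio, cmp$d_ratio_se) else ""
      )
    }
  }
  text <- c(
    sprintf("galidr run (seed %d)", run$config$seed),
    "",
    "Screening funnel:",
    sprintf("  %-18s %6d", funnel$stage, funnel$n)
  )
  if (!is.null(condition_table)) {
    text <- c(text, "", "Relaxation condition comparison:")
    text <- c(text, paste(
      utils::capture.output(print(as.data.frame(condition_table))),
      sep = ""
    ))
  }
  if (nrow(run$recovery) > 0) {
    text <- c(
      text, "", "Recovery checks:",
      sprintf(
        "  %-24s %10.4g  %s", run$recovery$check, run$recovery$value,
        ifelse(run$recovery$pass, "pass", "FAIL")
      )
    )
  }
  list(
    funnel = funnel, condition_table = condition_table,
    recovery = run$recovery, text = text
  )
}
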