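# Seeded generators for galectin-like proteomes with recorded ground truth.
# Homologs are assembled as: conserved N-terminal motif + disordered region
# (repeat-motif copies embedded in a P/G/A/S/Q/T-rich filler, with aromatic
# and acidic content controlled) + a mutated copy of a folded CRD template.
# Decoys are unrelated sequences carrying neither the planted motif nor a
# disordered region.

#' Human galectin-3 N-terminal sequence constants
#'
#' `hgal3_nterm_motif` is the first 20 residues of human galectin-3;
#' `hgal3_nterm_fragment` is the conserved fragment spanning residues 5-20,
#' the default reference for [nterm_conservation()].  `galectin_crd_template`
#' is a galectin carbohydrate-recognition-domain (CRD) template (the
#' C-terminal folded domain of human galectin-3) used as the default folded
#' segment by [sim_proteome()].
#'
#' @format Character scalars.
#' @export
hgal3_nterm_motif <- "MADNFSLHDALSGSGNPNPQ"

#' @rdname hgal3_nterm_motif
#' @export
hgal3_nterm_fragment <- "FSLHDALSGSGNPNPQ"

#' @rdname hgal3_nterm_motif
#' @export
galectin_crd_template <- paste0(
  "GAPAGPLIVPYNLPLPGGVVPRMLITILGTVKPNANRIALDFQRGNDVAFHFNPRFNENNRRVIVCNTK",
  "LDNNWGREERQSVFPFESGKPFKIQVLVEPDHFKVAVNDAHLLQYNHRVKKLNEISKLGISGDIDLTSASYTMI"
)

# Chordate-like IDR filler alphabet and weights (proline/glycine/alanine
# dominated, with serine/glutamine/threonine as minor components).
IDR_FILLER_WEIGHTS <- c(P = 0.30, G = 0.25, A = 0.20, S = 0.15, Q = 0.05, T = 0.05)

#' Specification for a synthetic galectin-like proteome
#'
#' Bundles and validates every knob of [sim_proteome()].  Defaults describe a
#' vertebrate-like population: homologs carry a conserved N-terminal motif, a
#' long disordered region with an aromatic-containing tetrapeptide repeated
#' several times, and a mutated copy of a folded CRD template; decoys are
#' unrelated sequences without a disordered region.
#'
#' @param n_homologs,n_decoys Number of homolog / decoy records.
#' @param clades Character vector of clade labels assigned to homologs.
#' @param aromatic_weights Named list (one element per clade, or a single
#'   unnamed element recycled to all clades) of numeric vectors
#'   `c(F = , Y = , W = )` summing to 1: the relative frequencies of the three
#'   aromatic residue types among the aromatics of that clade's IDRs.
#' @param idr_length_range Integer range (min, max) of disordered-region
#'   lengths, residues (excluding the N-terminal motif).
#' @param repeat_motif Repeat unit planted in each homolog IDR; 3-8 residues,
#'   must contain at least one aromatic residue (F/Y/W).  Either a single
#'   string used for every clade or a named vector (one motif per clade);
#'   the defaults give each clade a motif built on its dominant aromatic
#'   type (tryptophan-based in fish, tyrosine-based in mammals).
#' @param n_repeats_range Integer range of planted repeat copy numbers.
#' @param crd_template Folded-segment template sequence (about 140 residues).
#' @param substitution_rate Per-site substitution probability applied to the
#'   CRD template in each homolog.
#' @param nterm_motif Conserved N-terminal motif prepended to each homolog.
#' @param idr_aromatic_frac Target fraction of IDR residues that are aromatic
#'   (default 0.12, i.e. above the 8% screening threshold).
#' @param idr_acidic_frac Target fraction of IDR residues that are D/E
#'   (default 0.01, i.e. below the 3% screening threshold).
#' @param seed Integer root seed; all randomness flows from it through named
#'   substreams.
#'
#' @return A validated list of class `proteome_spec`.
#' @export
#' @examples
#' spec <- proteome_spec(n_homologs = 5, n_decoys = 5, seed = 1)
#' pop <- sim_proteome(spec)
#' pop$truth
proteome_spec <- function(n_homologs = 50,
                          n_decoys = 50,
                          clades = c("fish", "amphibian", "reptile", "bird", "mammal"),
                          aromatic_weights = list(
                            fish      = c(F = 0.20, Y = 0.15, W = 0.65),
                            amphibian = c(F = 0.40, Y = 0.40, W = 0.20),
                            reptile   = c(F = 0.45, Y = 0.35, W = 0.20),
                            bird      = c(F = 0.30, Y = 0.50, W = 0.20),
                            mammal    = c(F = 0.15, Y = 0.75, W = 0.10)
                          ),
                          idr_length_range = c(90L, 160L),
                          repeat_motif = c(
                            fish = "WPGQ", amphibian = "FPGA",
                            reptile = "FPGQ", bird = "YPGQ", mammal = "YPGA"
                          ),
                          n_repeats_range = c(3L, 8L),
                          crd_template = galectin_crd_template,
                          substitution_rate = 0.10,
                          nterm_motif = hgal3_nterm_motif,
                          idr_aromatic_frac = 0.12,
                          idr_acidic_frac = 0.01,
                          seed = 1L) {
  if (!is_count(n_homologs) || !is_count(n_decoys)) {
    abort("`n_homologs` and `n_decoys` must be non-negative integers.")
  }
  stopifnot(length(clades) >= 1)
  if (length(aromatic_weights) == 1L && is.null(names(aromatic_weights))) {
    aromatic_weights <- setNames(
      rep(aromatic_weights, length(clades)), clades
    )
  }
  if (!all(clades %in% names(aromatic_weights))) {
    abort("`aromatic_weights` must have one named element per clade.")
  }
  for (cl in clades) {
    w <- aromatic_weights[[cl]]
    if (!all(c("F", "Y", "W") %in% names(w)) || abs(sum(w) - 1) > 1e-9) {
      abort(sprintf(
        "aromatic weights for clade '%s' must be named F/Y/W and sum to 1.", cl
      ))
    }
  }
  if (!nzchar(crd_template)) {
    abort("`crd_template` must be a non-empty sequence.")
  }
  crd_template <- check_sequence(crd_template, "crd_template")
  nterm_motif <- check_sequence(nterm_motif, "nterm_motif")
  if (length(repeat_motif) == 1L && is.null(names(repeat_motif))) {
    repeat_motif <- setNames(rep(repeat_motif, length(clades)), clades)
  }
  if (!all(clades %in% names(repeat_motif))) {
    abort("`repeat_motif` must be a single motif or one named motif per clade.")
  }
  repeat_motif <- repeat_motif[clades]
  for (m in repeat_motif) {
    m <- check_sequence(m, "repeat_motif")
    if (nchar(m) < 3 || nchar(m) > 8) {
      abort("each `repeat_motif` must be 3-8 residues long.")
    }
    if (!any(seq_chars(m) %in% AA_AROMATIC)) {
      abort("each `repeat_motif` must contain at least one aromatic residue (F/Y/W).")
    }
  }
  rng_ok <- function(r) length(r) == 2 && r[1] <= r[2] && r[1] >= 0
  if (!rng_ok(idr_length_range) || !rng_ok(n_repeats_range)) {
    abort("`idr_length_range` and `n_repeats_range` must be non-empty ranges.")
  }
  stopifnot(
    substitution_rate >= 0, substitution_rate <= 1,
    idr_aromatic_frac >= 0, idr_aromatic_frac < 1,
    idr_acidic_frac >= 0, idr_acidic_frac < 1
  )
  structure(
    list(
      n_homologs = as.integer(n_homologs), n_decoys = as.integer(n_decoys),
      clades = clades, aromatic_weights = aromatic_weights,
      idr_length_range = as.integer(idr_length_range),
      repeat_motif = repeat_motif,
      n_repeats_range = as.integer(n_repeats_range),
      crd_template = crd_template, substitution_rate = substitution_rate,
      nterm_motif = nterm_motif,
      idr_aromatic_frac = idr_aromatic_frac,
      idr_acidic_frac = idr_acidic_frac,
      seed = as.integer(seed)
    ),
    class = "proteome_spec"
  )
}

# Largest-remainder apportionment of `total` among weights `w`.
apportion <- function(total, w) {
  raw <- w * total
  n <- floor(raw)
  rem <- total - sum(n)
  if (rem > 0) {
    idx <- order(raw - n, decreasing = TRUE)[seq_len(rem)]
    n[idx] <- n[idx] + 1
  }
  n
}

# Build one disordered region of length `len` containing `n_rep` copies of
# `motif`, with aromatic residue types distributed per `weights` and acidic
# content per `acidic_frac`.  Returns the sequence string.
build_idr <- function(len, motif, n_rep, weights, aromatic_frac, acidic_frac) {
  motif_chars <- seq_chars(motif)
  motif_len <- length(motif_chars)
  if (n_rep * motif_len > len) {
    n_rep <- floor(len / motif_len)
  }
  free <- len - n_rep * motif_len

  # Aromatic budget for the whole IDR, allocated per type by exact
  # apportionment so realized type fractions track the clade weights; the
  # motif copies' own aromatics count against their type's allocation.
  target_total <- round(aromatic_frac * len)
  target_type <- apportion(target_total, weights[c("F", "Y", "W")])
  motif_type <- vapply(
    c("F", "Y", "W"), function(a) sum(motif_chars == a) * n_rep, numeric(1)
  )
  extra_type <- pmax(0, target_type - motif_type)
  n_acidic <- round(acidic_frac * len)

  n_extra <- sum(extra_type) + n_acidic
  if (n_extra > free) {
    scale <- free / n_extra
    extra_type <- floor(extra_type * scale)
    n_acidic <- floor(n_acidic * scale)
  }
  n_filler <- free - sum(extra_type) - n_acidic

  letters_loose <- c(
    rep(c("F", "Y", "W"), times = extra_type),
    sample(AA_NEGATIVE, n_acidic, replace = TRUE),
    sample(names(IDR_FILLER_WEIGHTS), n_filler,
      replace = TRUE, prob = IDR_FILLER_WEIGHTS
    )
  )
  tokens <- c(rep(motif, n_rep), sample(letters_loose))
  paste(sample(tokens), collapse = "")
}

mutate_sequence <- function(sequence, rate) {
  chars <- seq_chars(sequence)
  hit <- runif(length(chars)) < rate
  if (any(hit)) {
    chars[hit] <- vapply(
      chars[hit],
      function(a) sample(setdiff(AA_STANDARD, a), 1L),
      character(1)
    )
  }
  paste(chars, collapse = "")
}

# Random decoy sequence guaranteed not to contain any planted motif.
build_decoy <- function(len, motifs) {
  repeat {
    s <- paste(sample(AA_STANDARD, len, replace = TRUE), collapse = "")
    if (!any(vapply(motifs, grepl, logical(1), x = s, fixed = TRUE))) {
      return(s)
    }
  }
}

#' Generate a synthetic galectin-like proteome with ground truth
#'
#' Produces homolog records (conserved N-terminal motif + disordered region
#' with planted aromatic repeats + mutated CRD) and decoy records, together
#' with a truth table recording, per record, whether a disordered region was
#' planted, its interval (1-based inclusive; the N-terminal motif is part of
#' the disordered region, as in galectin-3), and the planted repeat count.
#' Identical spec (including seed) gives identical output.
#'
#' @param spec A [proteome_spec()].
#'
#' @return A list with tibbles `records` (`accession`, `sequence`, `clade`)
#'   and `truth` (`accession`, `is_homolog`, `has_idr`, `idr_start`,
#'   `idr_end`, `idr_length`, `n_repeats_planted`, `repeat_motif`, `clade`).
#' @export
sim_proteome <- function(spec) {
  stopifnot(inherits(spec, "proteome_spec"))
  with_substream(spec$seed, "proteome", {
    empty_rec <- tibble::tibble(
      accession = character(), sequence = character(), clade = character()
    )
    empty_truth <- tibble::tibble(
      accession = character(), is_homolog = logical(), has_idr = logical(),
      idr_start = integer(), idr_end = integer(), idr_length = integer(),
      n_repeats_planted = integer(), repeat_motif = character(),
      clade = character()
    )
    homologs <- if (spec$n_homologs > 0) {
      purrr::map(seq_len(spec$n_homologs), function(i) {
        clade <- sample(spec$clades, 1L)
        motif <- spec$repeat_motif[[clade]]
        len <- sample_range(spec$idr_length_range[1], spec$idr_length_range[2])
        n_rep <- sample_range(spec$n_repeats_range[1], spec$n_repeats_range[2])
        idr <- build_idr(
          len, motif, n_rep, spec$aromatic_weights[[clade]],
          spec$idr_aromatic_frac, spec$idr_acidic_frac
        )
        crd <- mutate_sequence(spec$crd_template, spec$substitution_rate)
        acc <- sprintf("HOM%04d", i)
        ntd_len <- nchar(spec$nterm_motif) + nchar(idr)
        list(
          record = tibble::tibble(
            accession = acc,
            sequence = paste0(spec$nterm_motif, idr, crd),
            clade = clade
          ),
          truth = tibble::tibble(
            accession = acc, is_homolog = TRUE, has_idr = TRUE,
            idr_start = 1L, idr_end = ntd_len, idr_length = ntd_len,
            n_repeats_planted = as.integer(n_rep),
            repeat_motif = motif, clade = clade
          )
        )
      })
    } else {
      list()
    }
    decoys <- if (spec$n_decoys > 0) {
      purrr::map(seq_len(spec$n_decoys), function(i) {
        len <- nchar(spec$crd_template) +
          sample_range(spec$idr_length_range[1], spec$idr_length_range[2])
        acc <- sprintf("DEC%04d", i)
        list(
          record = tibble::tibble(
            accession = acc,
            sequence = build_decoy(len, spec$repeat_motif),
            clade = NA_character_
          ),
          truth = tibble::tibble(
            accession = acc, is_homolog = FALSE, has_idr = FALSE,
            idr_start = NA_integer_, idr_end = NA_integer_,
            idr_length = 0L, n_repeats_planted = 0L,
            repeat_motif = NA_character_, clade = NA_character_
          )
        )
      })
    } else {
      list()
    }
    all <- c(homologs, decoys)
    list(
      records = dplyr::bind_rows(empty_rec, purrr::map(all, "record")),
      truth = dplyr::bind_rows(empty_truth, purrr::map(all, "truth"))
    )
  })
}

#' Synthesize per-residue disorder scores for a proteome
#'
#' Stand-in for an external disorder predictor: inside a planted disordered
#' region scores are centered on 0.8, outside on 0.2, with Gaussian noise of
#' standard deviation `noise_sd`, clipped to \[0, 1\].  The downstream
#' contract of the screening stage is "scores in, stretches out", so the
#' generator only needs to separate the two classes.
#'
#' @param records Record tibble from [sim_proteome()].
#' @param truth Matching truth tibble from [sim_proteome()].
#' @param noise_sd Standard deviation of the Gaussian noise (>= 0).
#' @param seed Integer seed.
#'
#' @return Tibble `accession`, `position` (1-based), `score`.
#' @export
sim_disorder_scores <- function(records, truth, noise_sd = 0.05, seed = 1L) {
  check_cols(records, c("accession", "sequence"), "records")
  check_cols(truth, c("accession", "has_idr"), "truth")
  if (noise_sd < 0) abort("`noise_sd` must be >= 0.")
  if (!setequal(records$accession, truth$accession)) {
    abort("`records` and `truth` describe different accessions.")
  }
  with_substream(seed, "disorder", {
    truth_idx <- truth[match(records$accession, truth$accession), ]
    out <- purrr::map2(seq_len(nrow(records)), records$accession, function(i, acc) {
      n <- nchar(records$sequence[i])
      mu <- rep(0.2, n)
      if (isTRUE(truth_idx$has_idr[i])) {
        mu[seq(truth_idx$idr_start[i], truth_idx$idr_end[i])] <- 0.8
      }
      score <- mu + rnorm(n, 0, noise_sd)
      tibble::tibble(
        accession = acc, position = seq_len(n),
        score = pmin(1, pmax(0, score))
      )
    })
    dplyr::bind_rows(
      tibble::tibble(
        accession = character(), position = integer(), score = numeric()
      ),
      out
    )
  })
}
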