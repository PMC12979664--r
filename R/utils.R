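# Shared internal helpers: seed substreams, residue classes, small checks.

# One root seed feeds every generator through named substreams so that the
# pipeline stages can be re-run independently yet reproducibly.  The mapping
# only needs to be deterministic and to separate stream names; it is not a
# cryptographic hash.
substream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(name))
  codes <- utf8ToInt(name)
  mix <- sum(codes * seq_along(codes) * 131L)
  as.integer((abs(seed) + mix) %% .Machine$integer.max)
}

with_substream <- function(seed, name, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(substream_seed(seed, name))
  force(code)
}

AA_STANDARD <- c(
  "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"
)
AA_AROMATIC <- c("F", "Y", "W")
AA_NEGATIVE <- c("D", "E")
AA_POSITIVE <- c("K", "R")
AA_NONSTANDARD <- c("X", "B", "Z", "U", "J", "O")

seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

# One uniform integer draw from [lo, hi]; safe when lo == hi (base sample()
# would treat a scalar as an upper bound).
sample_range <- function(lo, hi) {
  lo + sample.int(hi - lo + 1L, 1L) - 1L
}

check_sequence <- function(sequence, arg = "sequence") {
  if (!is.character(sequence) || length(sequence) != 1L || !nzchar(sequence)) {
    abort(sprintf("`%s` must be a single non-empty string.", arg))
  }
  chars <- seq_chars(toupper(sequence))
  bad <- setdiff(unique(chars), c(AA_STANDARD, AA_NONSTANDARD))
  if (length(bad) > 0) {
    abort(sprintf(
      "`%s` contains letters outside the amino-acid alphabet: %s",
      arg, paste(bad, collapse = ", ")
    ))
  }
  paste(chars, collapse = "")
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == floor(x)
}

check_cols <- function(df, cols, arg = "data") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf(
      "`%s` is missing required column(s): %s",
      arg, paste(missing, collapse = ", ")
    ))
  }
  invisible(df)
}
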