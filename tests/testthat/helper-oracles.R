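# Independent brute-force oracles used to cross-check the implementation.
# Each one is written from the definition, without reusing package code.

# All maximal runs of score > threshold with run length >= min_len, found by
# checking every interval endpoint pair directly.
oracle_runs <- function(score, threshold, min_len) {
  n <- length(score)
  above <- score > threshold
  out <- list()
  for (i in seq_len(n)) {
    if (!above[i]) next
    if (i > 1 && above[i - 1]) next # not a run start
    j <- i
    while (j < n && above[j + 1]) j <- j + 1
    if (j - i + 1 >= min_len) {
      out[[length(out) + 1]] <- c(start = i, end = j)
    }
  }
  if (length(out) == 0) {
    return(data.frame(start = integer(), end = integer()))
  }
  as.data.frame(do.call(rbind, out))
}

# Exhaustive k-mer table with >= min_count occurrences, then the same
# containment-suppression rule applied by direct pairwise checking.
oracle_repeats <- function(sequence, k_min, k_max, min_count) {
  n <- nchar(sequence)
  rows <- list()
  for (k in k_min:min(k_max, n)) {
    for (s in 1:(n - k + 1)) {
      rows[[length(rows) + 1]] <- data.frame(
        motif = substr(sequence, s, s + k - 1), k = k, start = s
      )
    }
  }
  tab <- do.call(rbind, rows)
  agg <- split(tab$start, paste(tab$k, tab$motif, sep = ":"))
  agg <- agg[lengths(agg) >= min_count]
  if (length(agg) == 0) {
    return(data.frame(motif = character(), count = integer()))
  }
  motifs <- sub("^[0-9]+:", "", names(agg))
  counts <- lengths(agg)
  keep <- rep(TRUE, length(agg))
  for (i in seq_along(agg)) {
    for (j in seq_along(agg)) {
      if (nchar(motifs[j]) <= nchar(motifs[i]) || counts[j] != counts[i]) next
      # every containment offset of motif i inside motif j
      for (o in 0:(nchar(motifs[j]) - nchar(motifs[i]))) {
        if (substr(motifs[j], o + 1, o + nchar(motifs[i])) == motifs[i] &&
          identical(sort(agg[[i]]), sort(agg[[j]] + o))) {
          keep[i] <- FALSE
        }
      }
    }
  }
  res <- data.frame(motif = motifs[keep], count = as.integer(counts[keep]))
  res[order(-res$count, -nchar(res$motif), res$motif), , drop = FALSE]
}

# Smith-Waterman best local score with linear gap penalty, plain DP.
oracle_sw_score <- function(a, b, match, mismatch, gap) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av)
  m <- length(bv)
  H <- matrix(0, n + 1, m + 1)
  best <- 0
  for (i in 1:n) {
    for (j in 1:m) {
      sub <- if (av[i] == bv[j]) match else mismatch
      H[i + 1, j + 1] <- max(
        0,
        H[i, j] + sub,
        H[i, j + 1] - gap,
        H[i + 1, j] - gap
      )
      best <- max(best, H[i + 1, j + 1])
    }
  }
  best
}

# One-sided binomial tail P(X >= k), X ~ Binomial(n, 1/2), by direct
# enumeration of choose() terms.
oracle_binom_tail <- function(k, n) {
  sum(choose(n, k:n)) * 0.5^n
}

# Type-7 (linear interpolation) quantile re-derived from its definition.
oracle_quantile7 <- function(x, p) {
  x <- sort(x)
  h <- (length(x) - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# Two-pass mean and standard deviation.
oracle_mean_sd <- function(x) {
  m <- sum(x) / length(x)
  list(mean = m, sd = sqrt(sum((x - m)^2) / (length(x) - 1)))
}

random_protein <- function(n, alphabet = c("A", "G", "P", "S", "Y", "W")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}
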