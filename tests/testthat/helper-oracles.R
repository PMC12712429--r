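# Naive string-scanning oracles, deliberately independent of the
# package's encoded k-mer machinery.

oracle_revcomp <- function(s) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

oracle_windows <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(character())
  substring(s, seq_len(n - k + 1), k:n)
}

oracle_kmers <- function(seqs, k, canonical) {
  words <- unlist(lapply(seqs, function(s) {
    w <- oracle_windows(s, k)
    w[grepl("^[ACGT]+$", w)]
  }))
  if (!length(words)) return(character())
  if (canonical) {
    rc <- vapply(words, oracle_revcomp, character(1))
    words <- ifelse(words <= rc, words, rc)
  }
  sort(unique(words))
}

oracle_map <- function(query_words, s, k, canonical) {
  w <- oracle_windows(s, k)
  valid <- grepl("^[ACGT]+$", w)
  if (canonical) {
    rc <- vapply(w, oracle_revcomp, character(1))
    w <- ifelse(w <= rc, w, rc)
  }
  which(valid & w %in% query_words) - 1L
}

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")

rand_peptide <- function(n) {
  aa <- c("A","R","N","D","C","Q","E","G","H","I",
          "L","K","M","F","P","S","T","W","Y","V")
  paste(sample(aa, n, TRUE), collapse = "")
}

# Per-base bitmap coverage oracle for window tracks.
oracle_coverage <- function(features, len, width, step) {
  bitmap <- logical(len)
  for (i in seq_len(nrow(features))) {
    if (features$end[i] > features$start[i]) {
      bitmap[(features$start[i] + 1):features$end[i]] <- TRUE
    }
  }
  starts <- seq(0, max(0, len - width), by = step)
  ends <- pmin(starts + width, len)
  if (len >= width && max(ends) < len) {
    starts <- c(starts, max(starts) + step)
    ends <- c(ends, len)
  }
  vapply(seq_along(starts), function(j) {
    sum(bitmap[(starts[j] + 1):ends[j]]) / (ends[j] - starts[j])
  }, numeric(1))
}

# Compact module layout for small time-course fixtures.
small_module_spec <- function() {
  list(
    list(label = "shared_up", size = 10, direction = "up", dependence = "shared"),
    list(label = "shared_down", size = 10, direction = "down", dependence = "shared"),
    list(label = "severe_up", size = 10, direction = "up", dependence = "severe-only")
  )
}

# 2x2 closed-form logistic-regression estimate.
oracle_or <- function(a, b, c, d) {
  or <- (a * d) / (b * c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  z <- log(or) / se
  list(or = or, se = se, p = 2 * pnorm(-abs(z)))
}
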