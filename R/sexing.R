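#' Sexed cohorts of k-mer sets
#'
#' Bundles per-individual [kmer_set] objects with sex labels for
#' heterogamety inference. All members must share `k` and the canonical
#' flag, and both sexes must be represented.
#'
#' @param sets list of [kmer_set] objects, one per individual.
#' @param sex character vector, `"male"` or `"female"`, one per set.
#' @param ids optional sample identifiers (default `names(sets)` or
#'   `S1..Sn`).
#' @return An object of class `sexed_cohort`.
#' @export
sexed_cohort <- function(sets, sex, ids = NULL) {
  if (!length(sets) || !all(vapply(sets, inherits, logical(1), "kmer_set"))) {
    stop("`sets` must be a non-empty list of kmer_set objects")
  }
  sex <- match.arg(as.character(sex), c("male", "female"), several.ok = TRUE)
  if (length(sex) != length(sets)) stop("`sex` must label every set")
  if (!all(c("male", "female") %in% sex)) {
    stop("cohort needs at least one member of each sex")
  }
  if (is.null(ids)) {
    ids <- names(sets)
    if (is.null(ids)) ids <- sprintf("S%d", seq_along(sets))
  }
  for (s in sets[-1]) check_compatible(sets[[1]], s)
  structure(list(sets = sets, sex = sex, ids = ids,
                 k = sets[[1]]$k, canonical = sets[[1]]$canonical),
            class = "sexed_cohort")
}

#' @export
print.sexed_cohort <- function(x, ...) {
  cat(sprintf("<sexed_cohort> %d males, %d females; k = %d (%s)\n",
              sum(x$sex == "male"), sum(x$sex == "female"), x$k,
              if (x$canonical) "canonical" else "forward-strand"))
  invisible(x)
}

#' Sex-specific k-mers of a cohort
#'
#' Male-specific words are those present in every male (intersection
#' across males) and absent from every female (difference against the
#' female union); female-specific words are defined symmetrically. The
#' intersection-minus-union rule is robust to per-sample sequencing
#' dropout; set `minuend = "union"` to instead start from all words seen
#' in the focal sex.
#'
#' @param cohort a [sexed_cohort].
#' @param minuend `"intersection"` (default) or `"union"`: how words of
#'   the focal sex are pooled before subtracting the other sex.
#' @return List with [kmer_set] elements `male_specific` and
#'   `female_specific`.
#' @export
sex_specific_kmers <- function(cohort, minuend = c("intersection", "union")) {
  stopifnot(inherits(cohort, "sexed_cohort"))
  minuend <- match.arg(minuend)
  pool <- function(sets, op) Reduce(op, sets)
  males <- cohort$sets[cohort$sex == "male"]
  females <- cohort$sets[cohort$sex == "female"]
  pool_op <- if (minuend == "intersection") kmer_intersect else kmer_union
  list(
    male_specific = kmer_setdiff(pool(males, pool_op), pool(females, kmer_union)),
    female_specific = kmer_setdiff(pool(females, pool_op), pool(males, kmer_union))
  )
}

#' Classify the heterogametic sex system
#'
#' An excess of male-specific over female-specific k-mers indicates XY
#' (heterogametic males); the reciprocal excess indicates ZW. The call is
#' `"XY"` when the male:female ratio is at least `tau`, `"ZW"` when it is
#' at most `1/tau`, and `"undetermined"` otherwise (including when both
#' counts are zero).
#'
#' @param male_specific,female_specific [kmer_set] objects or bare counts.
#' @param tau decision threshold on the count ratio (default 2).
#' @return Object of class `heterogamety_call` with fields
#'   `n_male_specific`, `n_female_specific`, `ratio`, `tau`, `system`.
#' @examples
#' classify_heterogamety(400, 100)$system
#' @export
classify_heterogamety <- function(male_specific, female_specific, tau = 2) {
  n_m <- if (inherits(male_specific, "kmer_set")) length(male_specific) else male_specific
  n_f <- if (inherits(female_specific, "kmer_set")) length(female_specific) else female_specific
  stopifnot(length(n_m) == 1, length(n_f) == 1, n_m >= 0, n_f >= 0, tau > 1)
  ratio <- if (n_f == 0 && n_m == 0) NaN else n_m / n_f
  system <- if (n_m == 0 && n_f == 0) {
    "undetermined"
  } else if (ratio >= tau) {
    "XY"
  } else if (ratio <= 1 / tau) {
    "ZW"
  } else {
    "undetermined"
  }
  structure(list(n_male_specific = n_m, n_female_specific = n_f,
                 ratio = ratio, tau = tau, system = system),
            class = "heterogamety_call")
}

#' @export
print.heterogamety_call <- function(x, ...) {
  cat(sprintf("<heterogamety_call> %s (male-specific %d : female-specific %d, ratio %.3g, tau %.2g)\n",
              x$system, x$n_male_specific, x$n_female_specific, x$ratio, x$tau))
  invisible(x)
}

#' Map a k-mer set onto an assembly
#'
#' Exact matching against the assembly's k-mer stream: a hit at 0-based
#' position `p` on a chromosome means the window `[p, p + k)`
#' canonicalizes (under the query's canonical flag) to a query word.
#' Windows containing non-ACGT symbols never match.
#'
#' @param query a [kmer_set].
#' @param assembly named character vector or `DNAStringSet` of
#'   chromosome sequences.
#' @return Named list of sorted 0-based integer hit positions per
#'   chromosome (a multiset: one entry per matching window).
#' @export
map_kmers <- function(query, assembly) {
  stopifnot(inherits(query, "kmer_set"))
  assembly <- as_sequence_chr(assembly)
  if (is.null(names(assembly))) names(assembly) <- sprintf("seq%d", seq_along(assembly))
  lapply(assembly, function(s) {
    kmer_hit_positions_cpp(s, query$k, query$canonical, query$codes)
  })
}

#' Sliding-window counts of positions along chromosomes
#'
#' Windows start at 0 and advance by `step`; a window `[s, s + width)` is
#' emitted while it fits on the chromosome, plus one final truncated
#' window ending at the chromosome length when the last full window falls
#' short of it. Values are counts of positions per window.
#'
#' @param positions named list of 0-based positions per chromosome (as
#'   returned by [map_kmers()]), or a bare numeric vector for a single
#'   chromosome.
#' @param chrom_lengths named numeric vector of chromosome lengths.
#' @param width,step window width and offset in bases (`width >= step >= 1`).
#' @return A [window_track] with the per-window counts.
#' @export
window_density <- function(positions, chrom_lengths, width = 2.5e6, step = 1e5) {
  if (!is.list(positions)) positions <- list(positions)
  if (!length(chrom_lengths)) stop("empty chromosome list")
  if (is.null(names(chrom_lengths))) {
    names(chrom_lengths) <- names(positions)[seq_along(chrom_lengths)]
  }
  if (step < 1 || width < step) stop("need width >= step >= 1")
  out <- lapply(names(chrom_lengths), function(chrom) {
    len <- chrom_lengths[[chrom]]
    w <- window_grid(len, width, step)
    pos <- positions[[chrom]]
    if (is.null(pos)) pos <- numeric()
    value <- count_in_windows(pos, w$start, w$end)
    data.frame(chrom = chrom, start = w$start, end = w$end, value = value)
  })
  window_track(do.call(rbind, out), width = width, step = step)
}

# Window starts/ends on [0, len): full windows plus one truncated tail.
window_grid <- function(len, width, step) {
  if (len < width) return(list(start = 0, end = len))
  starts <- seq(0, len - width, by = step)
  ends <- starts + width
  if (max(ends) < len) {
    starts <- c(starts, max(starts) + step)
    ends <- c(ends, len)
  }
  list(start = starts, end = ends)
}

# Count positions falling in each half-open window (windows may overlap).
count_in_windows <- function(pos, starts, ends) {
  if (!length(pos)) return(rep(0, length(starts)))
  pos <- sort(pos)
  # windows share a sorted start grid, so two binary searches suffice
  lo <- findInterval(starts - 0.5, pos)
  hi <- findInterval(ends - 0.5, pos)
  hi - lo
}

#' Call sex-determining-region candidates from a density track
#'
#' The genome-wide mean window value serves as background; windows at or
#' above `min_fold` times background are candidates, and maximal runs of
#' at least `min_run` consecutive candidate windows (per chromosome) are
#' merged into calls spanning from the first window start to the last
#' window end. Calls are sorted by fold over background, descending.
#'
#' @param track a [window_track] of k-mer hit counts.
#' @param min_fold minimum fold over background (> 1).
#' @param min_run minimum number of consecutive candidate windows.
#' @return A `data.frame` of class `sdr_call` with columns `chrom`,
#'   `start`, `end`, `mean_window_density`, `fold_over_background`,
#'   `n_windows`. Zero rows when the track is empty of signal.
#' @export
call_sdr <- function(track, min_fold = 3, min_run = 2) {
  stopifnot(inherits(track, "window_track"), min_fold > 1, min_run >= 1)
  background <- mean(track$value)
  empty <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                      mean_window_density = numeric(),
                      fold_over_background = numeric(), n_windows = integer())
  if (background == 0) return(structure(empty, class = c("sdr_call", "data.frame")))
  calls <- empty
  for (chrom in unique(track$chrom)) {
    tr <- track[track$chrom == chrom, ]
    cand <- tr$value >= min_fold * background
    r <- rle(cand)
    idx_end <- cumsum(r$lengths)
    idx_start <- idx_end - r$lengths + 1
    keep <- r$values & r$lengths >= min_run
    for (j in which(keep)) {
      i0 <- idx_start[j]; i1 <- idx_end[j]
      m <- mean(tr$value[i0:i1])
      calls <- rbind(calls, data.frame(
        chrom = chrom, start = tr$start[i0], end = tr$end[i1],
        mean_window_density = m, fold_over_background = m / background,
        n_windows = i1 - i0 + 1L))
    }
  }
  calls <- calls[order(-calls$fold_over_background), , drop = FALSE]
  rownames(calls) <- NULL
  structure(calls, class = c("sdr_call", "data.frame"))
}

#' One-stop sex-determining-region scan
#'
#' Maps male-specific (Y) k-mers onto an assembly, computes a window
#' density track and calls candidate intervals. Nonoverlapping 20-kb
#' windows are the default localization preset for Mb-scale chromosomes:
#' the merged call's resolution is on the order of one window width, so
#' narrow windows keep the boundary error small relative to plant SDRs of
#' a few hundred kb.
#'
#' @inheritParams map_kmers
#' @inheritParams window_density
#' @inheritParams call_sdr
#' @return List with elements `track` ([window_track]) and `calls`
#'   (`sdr_call`).
#' @export
sdr_scan <- function(query, assembly, width = 2e4, step = 2e4,
                     min_fold = 3, min_run = 2) {
  assembly <- as_sequence_chr(assembly)
  if (is.null(names(assembly))) names(assembly) <- sprintf("seq%d", seq_along(assembly))
  hits <- map_kmers(query, assembly)
  track <- window_density(hits, nchar(assembly), width = width, step = step)
  list(track = track, calls = call_sdr(track, min_fold = min_fold, min_run = min_run))
}
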