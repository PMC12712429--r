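#' Window tracks
#'
#' A `window_track` is a data frame of per-window values along one or
#' more chromosomes (`chrom`, `start`, `end`, `value`; 0-based half-open
#' coordinates) with the window `width` and `step` kept as attributes.
#'
#' @param df data frame with columns `chrom`, `start`, `end`, `value`.
#' @param width,step window geometry in bases.
#' @return An object of class `window_track` (a data frame).
#' @export
window_track <- function(df, width, step) {
  stopifnot(all(c("chrom", "start", "end", "value") %in% names(df)))
  if (any(!is.finite(df$value))) stop("window values must be finite")
  rownames(df) <- NULL
  structure(df, width = width, step = step,
            class = c("window_track", "data.frame"))
}

#' @export
print.window_track <- function(x, ...) {
  cat(sprintf("<window_track> %d windows on %d chromosome(s); width %g, step %g\n",
              nrow(x), length(unique(x$chrom)),
              attr(x, "width"), attr(x, "step")))
  print.data.frame(head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}

#' Fractional feature coverage per sliding window
#'
#' For each window the value is the length of the union of the selected
#' feature intervals intersected with the window, divided by the actual
#' window length (so the final truncated window is normalized by its own
#' length). Overlapping features are unioned, never double counted.
#'
#' @param features data frame with 0-based half-open columns `chrom`,
#'   `start`, `end` and optionally `class`.
#' @param chrom_lengths named numeric vector of chromosome lengths.
#' @param width,step window geometry (see [window_density()]).
#' @param class feature class to select; `NULL` uses all intervals. A
#'   class absent from `features` yields an all-zero track.
#' @return A [window_track] of coverage fractions in `[0, 1]`.
#' @export
feature_coverage_track <- function(features, chrom_lengths, width, step,
                                   class = NULL) {
  stopifnot(all(c("chrom", "start", "end") %in% names(features)))
  if (!length(chrom_lengths) || is.null(names(chrom_lengths))) {
    stop("`chrom_lengths` must be a named vector")
  }
  if (step < 1 || width < step) stop("need width >= step >= 1")
  if (!is.null(class)) features <- features[features$class %in% class, , drop = FALSE]
  bad <- !(features$chrom %in% names(chrom_lengths)) |
    features$end > chrom_lengths[features$chrom] | features$start < 0
  if (any(bad)) {
    i <- which(bad)[1]
    stop(sprintf("feature %s:[%g,%g) lies outside its chromosome",
                 features$chrom[i], features$start[i], features$end[i]))
  }
  if (any(features$start >= features$end)) stop("features need start < end")
  rows <- lapply(names(chrom_lengths), function(chrom) {
    len <- chrom_lengths[[chrom]]
    w <- window_grid(len, width, step)
    f <- features[features$chrom == chrom, , drop = FALSE]
    cov <- overlap_length(f$start, f$end, w$start, w$end)
    data.frame(chrom = chrom, start = w$start, end = w$end,
               value = cov / (w$end - w$start))
  })
  window_track(do.call(rbind, rows), width = width, step = step)
}

# Length of union(intervals) within each window, via IRanges::reduce.
overlap_length <- function(fs, fe, ws, we) {
  if (!length(fs)) return(rep(0, length(ws)))
  merged <- IRanges::reduce(IRanges::IRanges(start = fs + 1, end = fe))
  ms <- BiocGenerics::start(merged) - 1
  me <- BiocGenerics::end(merged)
  out <- numeric(length(ws))
  for (i in seq_along(ms)) {
    out <- out + pmax(0, pmin(me[i], we) - pmax(ms[i], ws))
  }
  out
}

#' Percent standard deviation of window coverage
#'
#' Dispersion of gene (or repeat) density across nonoverlapping windows:
#' the sample standard deviation of the first `n_windows` coverage
#' fractions, expressed in percent. A low value indicates the uniform
#' gene/repeat spread characteristic of genomes without repeat-dense
#' pericentromeres.
#'
#' @param track a [window_track] of coverage fractions built with
#'   `step == width` (disjoint windows).
#' @param n_windows number of leading windows to use (default: all).
#' @return Percent standard deviation (sample, n-1 denominator).
#' @export
density_dispersion <- function(track, n_windows = nrow(track)) {
  stopifnot(inherits(track, "window_track"))
  if (attr(track, "step") != attr(track, "width")) {
    stop("dispersion is defined over nonoverlapping windows (step == width)")
  }
  if (n_windows < 2) stop("need at least 2 windows")
  if (n_windows > nrow(track)) stop("only ", nrow(track), " windows available")
  100 * sd(track$value[seq_len(n_windows)])
}

#' Flag telomeric chromosome ends
#'
#' An end is flagged when at least `min_copies` tandem copies of the
#' telomere motif occur wholly within the terminal `terminal_window`
#' bases: the motif itself at the 3' end, its reverse complement at the
#' 5' end (plant telomeres read `TTTAGGG` toward the 3' terminus on each
#' strand).
#'
#' @param assembly named character vector or `DNAStringSet`.
#' @param motif telomere repeat unit (default plant `TTTAGGG`).
#' @param min_copies minimum tandem copies.
#' @param terminal_window bases inspected at each end; must be at least
#'   `min_copies * nchar(motif)`.
#' @return data frame with per-chromosome logical columns `p5` and `p3`.
#' @export
find_telomeric_ends <- function(assembly, motif = "TTTAGGG", min_copies = 3,
                                terminal_window = 1000) {
  assembly <- as_sequence_chr(assembly)
  if (is.null(names(assembly))) names(assembly) <- sprintf("seq%d", seq_along(assembly))
  if (!nzchar(motif)) stop("motif must be nonempty")
  if (terminal_window < min_copies * nchar(motif)) {
    stop("terminal_window shorter than the tandem repeat it must contain")
  }
  tandem <- strrep(motif, min_copies)
  tandem_rc <- revcomp_chr(tandem)
  p5 <- p3 <- logical(length(assembly))
  for (i in seq_along(assembly)) {
    s <- assembly[[i]]
    n <- nchar(s)
    head5 <- substr(s, 1, min(terminal_window, n))
    tail3 <- substr(s, max(1, n - terminal_window + 1), n)
    p5[i] <- grepl(tandem_rc, head5, fixed = TRUE)
    p3[i] <- grepl(tandem, tail3, fixed = TRUE)
  }
  data.frame(chrom = names(assembly), p5 = p5, p3 = p3)
}

revcomp_chr <- function(x) {
  vapply(x, function(s) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }, character(1), USE.NAMES = FALSE)
}
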