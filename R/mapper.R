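#' Uniform overlapping interval cover of a lens range
#'
#' Covers `[min(lens), max(lens)]` with `n_intervals` intervals of equal
#' length `L = range / (n - (n - 1) * overlap)`, each starting
#' `L * (1 - overlap)` after the previous, so consecutive intervals
#' overlap by exactly `overlap * L`. The last endpoint is clamped to the
#' lens maximum. No lens value is covered by more than
#' `ceiling(1 / (1 - overlap))` intervals.
#'
#' @param lens numeric lens values (at least 2 distinct values when
#'   `n_intervals > 1`).
#' @param n_intervals number of intervals (default 110).
#' @param overlap fractional overlap between consecutive intervals in
#'   `[0, 1)` (default 0.90).
#' @return data frame with columns `a`, `b` (closed interval bounds).
#' @examples
#' build_cover(c(0, 1), n_intervals = 2, overlap = 0.5)
#' @export
build_cover <- function(lens, n_intervals = 110, overlap = 0.90) {
  if (n_intervals < 1) stop("n_intervals must be >= 1")
  if (overlap < 0 || overlap >= 1) stop("overlap must lie in [0, 1)")
  if (any(!is.finite(lens))) stop("lens values must be finite")
  lo <- min(lens); hi <- max(lens)
  if (n_intervals > 1 && lo == hi) {
    stop("need >= 2 distinct lens values when n_intervals > 1")
  }
  if (n_intervals == 1) return(data.frame(a = lo, b = hi))
  L <- (hi - lo) / (n_intervals - (n_intervals - 1) * overlap)
  a <- lo + (seq_len(n_intervals) - 1) * L * (1 - overlap)
  b <- a + L
  b[n_intervals] <- hi
  data.frame(a = a, b = b)
}

#' Cluster the samples of one cover interval
#'
#' Single linkage with the first-gap histogram heuristic of the original
#' Mapper recipe: merge heights from the single-linkage dendrogram are
#' histogrammed into `gap_bins` equal bins over `[0, max(height)]` and
#' the dendrogram is cut at the left edge of the first empty bin that
#' follows an occupied one (the first gap separating small from large
#' merge heights). With no such gap (or a single sample) all samples form
#' one cluster. A fixed
#' `fallback_epsilon` cut height can be supplied instead.
#'
#' @param x samples x features numeric matrix (Euclidean distances).
#' @param gap_bins number of histogram bins (default 10).
#' @param fallback_epsilon optional fixed cut height overriding the gap
#'   heuristic.
#' @return List of character vectors of row names (sample ids), each one
#'   cluster, ordered by first member.
#' @export
cluster_preimage <- function(x, gap_bins = 10, fallback_epsilon = NULL) {
  x <- as.matrix(x)
  ids <- rownames(x)
  if (is.null(ids)) ids <- sprintf("s%d", seq_len(nrow(x)))
  if (nrow(x) == 1) return(list(ids))
  d <- dist(x)
  if (any(!is.finite(d))) stop("non-finite distances in preimage")
  hc <- hclust(d, method = "single")
  h <- hc$height
  # zero heights (coincident points) merge under any cutoff and would
  # otherwise fake a gap, so only positive heights enter the histogram
  h <- h[h > 0]
  cutoff <- if (!is.null(fallback_epsilon)) {
    fallback_epsilon
  } else if (!length(h)) {
    Inf  # all points coincide
  } else {
    breaks <- seq(0, max(h), length.out = gap_bins + 1)
    counts <- tabulate(pmin(findInterval(h, breaks, rightmost.closed = TRUE),
                            gap_bins), nbins = gap_bins)
    # the gap must separate small from large merge heights: first empty
    # bin after the first occupied one
    occupied <- which(counts > 0)[1]
    gap <- which(counts == 0 & seq_along(counts) > occupied)[1]
    if (is.na(gap)) Inf else breaks[gap]
  }
  membership <- if (is.infinite(cutoff)) {
    rep(1L, nrow(x))
  } else {
    cutree(hc, h = cutoff)
  }
  split(ids, membership)[order(vapply(split(seq_along(ids), membership), min, numeric(1)))]
}

#' Mapper graph of expression samples under a physiological lens
#'
#' Builds the Mapper topological summary of a genes x samples expression
#' matrix: the lens range (typically relative water content, anchored so
#' fully hydrated samples take the maximum) is covered by overlapping
#' intervals ([build_cover()]); the samples of each interval's preimage
#' are clustered ([cluster_preimage()]) into nodes; and nodes sharing
#' samples are joined by edges weighted by the shared count.
#'
#' @param expr genes x samples numeric matrix (TPM scale); column names
#'   are the sample ids.
#' @param lens named numeric vector of lens values, one per sample.
#' @param n_intervals,overlap cover parameters (defaults 110 and 0.90).
#' @param gap_bins,fallback_epsilon clustering parameters.
#' @param transform `"standardize_log"` (default: per-gene standardized
#'   `log2(TPM + 1)`) or `"none"`.
#' @param groups optional factor of sample group labels (e.g. drying
#'   group); the node majority is recorded.
#' @return Object of class `mapper_graph`: `nodes` (data frame with
#'   `node`, `interval`, `n_members`, `mean_lens`, `majority_group` and a
#'   `members` list column) and `edges` (data frame `from`, `to`,
#'   `shared`).
#' @export
mapper_graph <- function(expr, lens, n_intervals = 110, overlap = 0.90,
                         gap_bins = 10, fallback_epsilon = NULL,
                         transform = c("standardize_log", "none"),
                         groups = NULL) {
  transform <- match.arg(transform)
  expr <- as.matrix(expr)
  if (!nrow(expr) || !ncol(expr)) stop("empty expression matrix")
  samples <- colnames(expr)
  if (is.null(samples)) samples <- sprintf("s%d", seq_len(ncol(expr)))
  colnames(expr) <- samples
  if (is.null(names(lens))) names(lens) <- samples
  if (!all(samples %in% names(lens)) || any(!is.finite(lens[samples]))) {
    stop("lens must supply a finite value for every sample")
  }
  lens <- lens[samples]
  if (!is.null(groups)) groups <- setNames(as.character(groups), samples)

  x <- t(expr)
  if (transform == "standardize_log") {
    x <- log2(x + 1)
    sds <- apply(x, 2, sd)
    x <- scale(x, center = TRUE, scale = ifelse(sds > 0, sds, 1))
  }

  cover <- build_cover(lens, n_intervals, overlap)
  nodes <- list()
  for (i in seq_len(nrow(cover))) {
    inside <- samples[lens >= cover$a[i] & lens <= cover$b[i]]
    inside <- sort(inside)  # ascending-id determinism
    if (!length(inside)) next
    for (cl in cluster_preimage(x[inside, , drop = FALSE],
                                gap_bins = gap_bins,
                                fallback_epsilon = fallback_epsilon)) {
      nodes[[length(nodes) + 1]] <- list(interval = i, members = sort(cl))
    }
  }
  n_nodes <- length(nodes)
  node_df <- data.frame(
    node = seq_len(n_nodes),
    interval = vapply(nodes, `[[`, numeric(1), "interval"),
    n_members = vapply(nodes, function(n) length(n$members), numeric(1)),
    mean_lens = vapply(nodes, function(n) mean(lens[n$members]), numeric(1)),
    majority_group = vapply(nodes, function(n) {
      if (is.null(groups)) return(NA_character_)
      tb <- sort(table(groups[n$members]), decreasing = TRUE)
      names(tb)[1]
    }, character(1))
  )
  node_df$members <- lapply(nodes, `[[`, "members")

  edges <- data.frame(from = integer(), to = integer(), shared = integer())
  if (n_nodes > 1) {
    for (i in seq_len(n_nodes - 1)) {
      for (j in seq((i + 1), n_nodes)) {
        shared <- length(intersect(nodes[[i]]$members, nodes[[j]]$members))
        if (shared > 0) {
          edges <- rbind(edges, data.frame(from = i, to = j, shared = shared))
        }
      }
    }
  }
  structure(list(nodes = node_df, edges = edges, lens = lens,
                 cover = cover, samples = samples),
            class = "mapper_graph")
}

#' @export
print.mapper_graph <- function(x, ...) {
  cat(sprintf("<mapper_graph> %d nodes, %d edges over %d samples (%d intervals)\n",
              nrow(x$nodes), nrow(x$edges), length(x$samples), nrow(x$cover)))
  invisible(x)
}

#' Connected components of a Mapper graph
#'
#' @param graph a [mapper_graph].
#' @return Integer component label per node.
#' @export
graph_components <- function(graph) {
  n <- nrow(graph$nodes)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (r in seq_len(nrow(graph$edges))) {
    a <- find(graph$edges$from[r])
    b <- find(graph$edges$to[r])
    if (a != b) parent[max(a, b)] <- min(a, b)
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

#' Principal component scores of an expression matrix
#'
#' Samples are the observations (columns of `expr`). Variance fractions
#' are nonincreasing and sum to at most 1.
#'
#' @param expr genes x samples numeric matrix.
#' @param center,scale. passed to [stats::prcomp()].
#' @return List with `scores` (samples x components) and `var_frac`.
#' @export
pca_scores <- function(expr, center = TRUE, scale. = FALSE) {
  expr <- as.matrix(expr)
  if (nrow(expr) < 2 || ncol(expr) < 2) stop("need >= 2 genes and >= 2 samples")
  x <- t(expr)
  v <- apply(x, 2, var)
  if (all(v == 0)) stop("constant matrix: no variance to decompose")
  if (scale.) x <- x[, v > 0, drop = FALSE]
  p <- prcomp(x, center = center, scale. = scale.)
  var_frac <- p$sdev^2 / sum(p$sdev^2)
  list(scores = p$x, var_frac = var_frac)
}
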