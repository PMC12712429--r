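#' Relative water content
#'
#' RWC = (fresh - dry) / (turgid - dry), the mass fraction of the water a
#' tissue holds relative to full turgor. Values may mildly exceed 1 when
#' field-fresh tissue is supersaturated.
#'
#' @param fresh,turgid,dry tissue masses (grams); vectorized.
#' @return RWC fractions.
#' @examples
#' compute_rwc(9, 10, 2)
#' @export
compute_rwc <- function(fresh, turgid, dry) {
  if (any(turgid <= dry)) stop("turgid mass must exceed dry mass")
  if (any(fresh < dry)) stop("fresh mass cannot be below dry mass")
  (fresh - dry) / (turgid - dry)
}

#' Assign a drying-severity group from minimum RWC
#'
#' Plants are binned by the minimum relative water content they reached
#' during a drying time course: below the first threshold is
#' `desiccation`, between the thresholds (inclusive) is `severe`, and
#' above the second threshold is `mild`. Field observations leave a gap
#' between roughly 30% and 60% RWC; the classifier closes it at the
#' second threshold so every plant receives a group.
#'
#' @param min_rwc minimum RWC fraction(s) in `[0, 1.05]`.
#' @param thresholds two increasing fractions, default `c(0.10, 0.30)`.
#' @return factor with levels `mild`, `severe`, `desiccation`.
#' @examples
#' assign_drying_group(c(0.05, 0.20, 0.70))
#' @export
assign_drying_group <- function(min_rwc, thresholds = c(0.10, 0.30)) {
  stopifnot(length(thresholds) == 2, thresholds[1] < thresholds[2])
  if (any(min_rwc < 0 | min_rwc > 1.05)) stop("min_rwc outside [0, 1.05]")
  out <- ifelse(min_rwc < thresholds[1], "desiccation",
                ifelse(min_rwc <= thresholds[2], "severe", "mild"))
  factor(out, levels = c("mild", "severe", "desiccation"))
}

#' Bonferroni adjustment
#'
#' `p_adj = min(1, m * p_raw)`, order preserved. `m` defaults to the
#' number of tests supplied.
#'
#' @param p_raw raw p-values in `(0, 1]`.
#' @param m number of tests.
#' @return Adjusted p-values.
#' @export
bonferroni_adjust <- function(p_raw, m = length(p_raw)) {
  if (any(p_raw <= 0 | p_raw > 1)) stop("p-values must lie in (0, 1]")
  pmin(1, m * p_raw)
}

#' Classify differentially abundant transcripts
#'
#' Applies the differential-abundance thresholds to a per-gene,
#' per-comparison statistics table: `Up` requires `log2fc > lfc` and
#' `p_adj < alpha`, `Down` requires `log2fc < -lfc` and `p_adj < alpha`
#' (both inequalities strict); everything else is `NotDE`. When `p_adj`
#' is absent it is computed by Bonferroni correction of `p_raw`, by
#' default within each comparison.
#'
#' @param stats data frame with columns `gene`, `comparison`, `log2fc`
#'   and `p_adj` (or `p_raw`).
#' @param lfc log2 fold-change threshold (default 2).
#' @param alpha adjusted-p threshold (default 0.05).
#' @param m_scope when adjusting from `p_raw`: `"per_comparison"`
#'   (default, m = genes per comparison) or `"global"` (m = all rows).
#' @return The input with a `state` factor column (`Up`, `Down`, `NotDE`).
#' @export
classify_dats <- function(stats, lfc = 2, alpha = 0.05,
                          m_scope = c("per_comparison", "global")) {
  m_scope <- match.arg(m_scope)
  if (!"log2fc" %in% names(stats)) stop("missing log2fc column")
  if (!"p_adj" %in% names(stats)) {
    if (!"p_raw" %in% names(stats)) stop("need p_adj or p_raw")
    stats$p_adj <- if (m_scope == "global") {
      bonferroni_adjust(stats$p_raw, nrow(stats))
    } else {
      stats$p_adj <- NA_real_
      for (cmp in unique(stats$comparison)) {
        i <- stats$comparison == cmp
        stats$p_adj[i] <- bonferroni_adjust(stats$p_raw[i], sum(i))
      }
      stats$p_adj
    }
  }
  state <- rep("NotDE", nrow(stats))
  sig <- stats$p_adj < alpha & !is.na(stats$p_adj) & !is.na(stats$log2fc)
  state[sig & stats$log2fc > lfc] <- "Up"
  state[sig & stats$log2fc < -lfc] <- "Down"
  stats$state <- factor(state, levels = c("Up", "Down", "NotDE"))
  stats
}

#' Nonredundant up/down gene lists across time points
#'
#' Collapses per-comparison DAT calls (one drying group, one phase) into
#' nonredundant sets: a gene is in the `up` set if called `Up` in at
#' least one comparison, analogously for `down`. Genes appearing in both
#' sets across time points are flagged bidirectional and kept in both.
#'
#' @param calls data frame with columns `gene` and `state` (from
#'   [classify_dats()]), restricted to one group and phase.
#' @return List with sorted character vectors `up`, `down` and
#'   `bidirectional`.
#' @export
nonredundant_dats <- function(calls) {
  stopifnot(all(c("gene", "state") %in% names(calls)))
  up <- sort(unique(calls$gene[calls$state == "Up"]))
  down <- sort(unique(calls$gene[calls$state == "Down"]))
  list(up = up, down = down, bidirectional = intersect(up, down))
}

#' Three-set Venn decomposition
#'
#' Counts and lists the seven exclusive regions of three finite sets.
#'
#' @param A,B,C vectors (coerced to sets).
#' @param names labels for the three sets.
#' @return List of class `venn3` with `counts` (named numeric, summing to
#'   the union size) and `regions` (element lists).
#' @export
overlap_sets <- function(A, B, C, names = c("A", "B", "C")) {
  A <- unique(A); B <- unique(B); C <- unique(C)
  regions <- list(
    setdiff(A, union(B, C)),
    setdiff(B, union(A, C)),
    setdiff(C, union(A, B)),
    setdiff(intersect(A, B), C),
    setdiff(intersect(A, C), B),
    setdiff(intersect(B, C), A),
    intersect(intersect(A, B), C)
  )
  labels <- c(names,
              paste(names[1], names[2], sep = ":"),
              paste(names[1], names[3], sep = ":"),
              paste(names[2], names[3], sep = ":"),
              paste(names, collapse = ":"))
  names(regions) <- labels
  structure(list(counts = vapply(regions, length, numeric(1)),
                 regions = regions),
            class = "venn3")
}

#' @export
print.venn3 <- function(x, ...) {
  cat("<venn3> exclusive region counts:\n")
  print(x$counts)
  invisible(x)
}

#' Alluvial transition matrices between adjacent time points
#'
#' For each adjacent pair of time points, a 3x3 matrix counts genes
#' moving between `Up`, `Down` and `NotDE` states. Every matrix sums to
#' the number of genes; its row and column margins reproduce the state
#' counts at the flanking time points.
#'
#' @param states a genes x timepoints matrix or data frame of states
#'   (`"Up"`, `"Down"`, `"NotDE"`); every gene needs a state at every
#'   time point.
#' @return Named list of 3x3 transition matrices, one per adjacent pair.
#' @export
alluvial_flows <- function(states) {
  states <- as.matrix(states)
  if (any(is.na(states))) stop("ragged input: every gene needs a state at every time point")
  lv <- c("Up", "Down", "NotDE")
  if (!all(states %in% lv)) stop("states must be Up, Down or NotDE")
  nt <- ncol(states)
  if (nt < 2) return(list())
  cn <- colnames(states)
  if (is.null(cn)) cn <- sprintf("T%d", seq_len(nt))
  out <- vector("list", nt - 1)
  for (j in seq_len(nt - 1)) {
    out[[j]] <- table(factor(states[, j], levels = lv),
                      factor(states[, j + 1], levels = lv))
    out[[j]] <- unclass(as.matrix(out[[j]]))
    dimnames(out[[j]]) <- list(from = lv, to = lv)
  }
  names(out) <- paste(cn[-nt], cn[-1], sep = "->")
  out
}

#' Welch-test differential statistics (testing stand-in)
#'
#' Computes per-gene, per-timepoint statistics against baseline by a
#' Welch t-test on `log2(TPM + 1)` values. This is an explicit stand-in
#' statistic for exercising the DAT summarization pipeline on synthetic
#' data; the pipeline's public input is any per-comparison statistics
#' table (e.g. exported from a negative-binomial fit).
#'
#' @param expr genes x samples numeric matrix (TPM scale).
#' @param sample_tp timepoint label per sample (column).
#' @param baseline the baseline timepoint label.
#' @return data frame with `gene`, `comparison`, `log2fc`, `p_raw`.
#' @export
welch_de_stats <- function(expr, sample_tp, baseline) {
  stopifnot(ncol(expr) == length(sample_tp), baseline %in% sample_tp)
  lx <- log2(expr + 1)
  base <- lx[, sample_tp == baseline, drop = FALSE]
  if (ncol(base) < 2) stop("need >= 2 baseline samples")
  genes <- rownames(expr)
  if (is.null(genes)) genes <- sprintf("g%d", seq_len(nrow(expr)))
  tps <- setdiff(unique(sample_tp), baseline)
  m0 <- rowMeans(base)
  v0 <- apply(base, 1, var)
  n0 <- ncol(base)
  out <- lapply(tps, function(tp) {
    x <- lx[, sample_tp == tp, drop = FALSE]
    if (ncol(x) < 2) stop("need >= 2 samples at timepoint ", tp)
    m1 <- rowMeans(x)
    v1 <- apply(x, 1, var)
    n1 <- ncol(x)
    se2 <- v1 / n1 + v0 / n0
    tstat <- (m1 - m0) / sqrt(se2)
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v0 / n0)^2 / (n0 - 1))
    p <- 2 * pt(-abs(tstat), df)
    p[se2 == 0 & m1 == m0] <- 1  # no variance, no difference
    p[se2 == 0 & m1 != m0] <- .Machine$double.xmin
    data.frame(gene = genes, comparison = paste0(tp, "_vs_", baseline),
               log2fc = m1 - m0, p_raw = pmin(1, pmax(p, .Machine$double.xmin)))
  })
  do.call(rbind, out)
}
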