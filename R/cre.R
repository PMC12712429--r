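IUPAC_CODES <- c(A = "A", C = "C", G = "G", T = "T",
                 R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC",
                 B = "CGT", D = "AGT", H = "ACT", V = "ACG", N = "ACGT")

check_iupac <- function(pattern) {
  letters <- strsplit(toupper(pattern), "")[[1]]
  bad <- setdiff(letters, names(IUPAC_CODES))
  if (length(bad)) {
    stop("invalid IUPAC symbol(s) in motif: ", paste(unique(bad), collapse = ", "))
  }
  if (length(letters) < 4) stop("motif patterns must be at least 4 bases long")
  invisible(TRUE)
}

#' Expand an IUPAC pattern to a regular expression
#'
#' Utility used by the test oracles and available for export of scanning
#' rules; each degenerate symbol becomes a character class.
#'
#' @param pattern IUPAC nucleotide string.
#' @return A regular expression string.
#' @export
iupac_to_regex <- function(pattern) {
  check_iupac(pattern)
  letters <- strsplit(toupper(pattern), "")[[1]]
  paste0(vapply(letters, function(l) {
    e <- IUPAC_CODES[[l]]
    if (nchar(e) == 1) e else paste0("[", e, "]")
  }, character(1)), collapse = "")
}

#' Extract strand-aware upstream promoter regions
#'
#' For a plus-strand gene the promoter is the `upstream` bases
#' immediately 5' of the gene start, reported 5' to 3'; for a
#' minus-strand gene it is the reverse complement of the bases
#' immediately 3' of the gene end. Promoters are truncated (never
#' padded) at contig boundaries and the truncation is flagged.
#'
#' @param annotation a GFF3 file path, a `GRanges`, or a data frame with
#'   1-based inclusive `start`, `end` plus `chrom`, `strand` and `gene`
#'   columns. From GFF3/GRanges only `type == "gene"` features are used
#'   and the identifier is taken from `id_field`.
#' @param genome named character vector, `DNAStringSet`, or FASTA path.
#' @param upstream promoter length in bases (default 1000).
#' @param id_field GFF3 attribute holding the gene id (default `"ID"`).
#' @return `DNAStringSet` of promoters named by gene, with `truncated`
#'   logical metadata column.
#' @export
extract_promoters <- function(annotation, genome, upstream = 1000,
                              id_field = "ID") {
  genes <- as_gene_table(annotation, id_field)
  genome <- as_genome_set(genome)
  missing_chrom <- setdiff(genes$chrom, names(genome))
  if (length(missing_chrom)) {
    stop("annotation references absent contig(s): ",
         paste(missing_chrom, collapse = ", "))
  }
  bad_strand <- !(genes$strand %in% c("+", "-"))
  if (any(bad_strand)) {
    stop("unknown strand for gene(s): ",
         paste(genes$gene[bad_strand], collapse = ", "))
  }
  n <- nrow(genes)
  proms <- character(n)
  truncated <- logical(n)
  for (i in seq_len(n)) {
    clen <- length(genome[[genes$chrom[i]]])
    if (genes$start[i] < 1 || genes$end[i] > clen) {
      stop("gene ", genes$gene[i], " lies outside its contig")
    }
    if (genes$strand[i] == "+") {
      from <- max(1L, genes$start[i] - upstream)
      to <- genes$start[i] - 1L
    } else {
      from <- genes$end[i] + 1L
      to <- min(clen, genes$end[i] + upstream)
    }
    if (to < from) {
      warning("gene ", genes$gene[i], " sits at the contig edge: zero-length promoter")
      proms[i] <- ""
      truncated[i] <- TRUE
      next
    }
    s <- Biostrings::subseq(genome[[genes$chrom[i]]], from, to)
    if (genes$strand[i] == "-") s <- Biostrings::reverseComplement(s)
    proms[i] <- as.character(s)
    truncated[i] <- (to - from + 1L) < upstream
  }
  out <- Biostrings::DNAStringSet(proms)
  names(out) <- genes$gene
  S4Vectors::mcols(out)$truncated <- truncated
  out
}

as_gene_table <- function(annotation, id_field) {
  if (is.character(annotation) && length(annotation) == 1) {
    annotation <- rtracklayer::import(annotation)
  }
  if (methods::is(annotation, "GRanges")) {
    gr <- annotation
    if ("type" %in% names(S4Vectors::mcols(gr))) {
      gr <- gr[S4Vectors::mcols(gr)$type == "gene"]
    }
    ids <- if (id_field %in% names(S4Vectors::mcols(gr))) {
      as.character(S4Vectors::mcols(gr)[[id_field]])
    } else {
      names(gr)
    }
    if (is.null(ids) || any(is.na(ids))) {
      ids <- sprintf("gene%d", seq_along(gr))
    }
    return(data.frame(gene = ids,
                      chrom = as.character(GenomicRanges::seqnames(gr)),
                      start = BiocGenerics::start(gr),
                      end = BiocGenerics::end(gr),
                      strand = as.character(BiocGenerics::strand(gr))))
  }
  stopifnot(all(c("gene", "chrom", "start", "end", "strand") %in% names(annotation)))
  as.data.frame(annotation)
}

as_genome_set <- function(genome) {
  if (is.character(genome) && length(genome) == 1 && file.exists(genome)) {
    genome <- Biostrings::readDNAStringSet(genome)
    names(genome) <- sub("\\s.*$", "", names(genome))
  } else if (is.character(genome)) {
    genome <- Biostrings::DNAStringSet(genome)
  }
  stopifnot(methods::is(genome, "DNAStringSet"))
  genome
}

#' Scan promoters for degenerate motifs
#'
#' A cell of the returned binary matrix is 1 when the promoter (or, with
#' `both_strands`, its reverse complement) contains at least one match of
#' the IUPAC pattern, where each degenerate symbol matches its base
#' class.
#'
#' @param promoters `DNAStringSet` or named character vector.
#' @param motifs data frame with columns `id` and `pattern`, or a named
#'   character vector of IUPAC patterns.
#' @param both_strands also scan the reverse complement (default `TRUE`).
#' @return Object of class `motif_hit_matrix`: genes x motifs binary
#'   matrix.
#' @export
scan_motifs <- function(promoters, motifs, both_strands = TRUE) {
  promoters <- as_genome_set(as_sequence_chr(promoters))
  if (is.null(names(promoters))) names(promoters) <- sprintf("gene%d", seq_along(promoters))
  motifs <- as_motif_table(motifs)
  hits <- matrix(0L, nrow = length(promoters), ncol = nrow(motifs),
                 dimnames = list(names(promoters), motifs$id))
  for (j in seq_len(nrow(motifs))) {
    check_iupac(motifs$pattern[j])
    pat <- Biostrings::DNAString(toupper(motifs$pattern[j]))
    n_fwd <- Biostrings::vcountPattern(pat, promoters, fixed = "subject")
    n <- n_fwd
    if (both_strands) {
      n <- n + Biostrings::vcountPattern(Biostrings::reverseComplement(pat),
                                         promoters, fixed = "subject")
    }
    hits[, j] <- as.integer(n > 0)
  }
  structure(hits, class = c("motif_hit_matrix", class(hits)))
}

as_motif_table <- function(motifs) {
  if (is.character(motifs)) {
    ids <- names(motifs)
    if (is.null(ids)) ids <- sprintf("motif%d", seq_along(motifs))
    return(data.frame(id = ids, pattern = unname(motifs)))
  }
  stopifnot(all(c("id", "pattern") %in% names(motifs)))
  as.data.frame(motifs)
}

#' Per-motif enrichment between up- and downregulated genes
#'
#' Each motif is tested for association with the gene group by a binomial
#' logistic regression of group (up = 1) on motif presence. For a binary
#' predictor the fitted odds ratio equals the 2x2 table estimate
#' `OR = (a d) / (b c)` with Wald standard error
#' `sqrt(1/a + 1/b + 1/c + 1/d)`, where `a` counts upregulated genes with
#' the motif, `b` without, and `c`, `d` the downregulated analogues.
#' Tables with an empty cell receive the Haldane-Anscombe +0.5 correction
#' and are flagged. P-values are two-sided normal (Wald); an odds ratio
#' above 1 means enrichment in upregulated genes.
#'
#' @param hits a [scan_motifs()] matrix (genes x motifs, binary).
#' @param groups `"up"`/`"down"` label per gene (row).
#' @param adjust `"none"` (default, raw p) or `"BH"` to append a
#'   Benjamini-Hochberg column `p_adj`.
#' @return data frame with columns `motif`, `a`, `b`, `c`, `d`,
#'   `odds_ratio`, `beta`, `se`, `p_value`, `direction`, `separation`.
#' @export
enrich_motifs <- function(hits, groups, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  hits <- as.matrix(hits)
  groups <- as.character(groups)
  stopifnot(length(groups) == nrow(hits), all(groups %in% c("up", "down")))
  if (!all(c("up", "down") %in% groups)) stop("both groups must be nonempty")
  up <- groups == "up"
  res <- lapply(colnames(hits), function(m) {
    present <- hits[, m] > 0
    a <- sum(up & present); b <- sum(up & !present)
    c_ <- sum(!up & present); d <- sum(!up & !present)
    fit <- or_glm(a, b, c_, d)
    data.frame(motif = m, a = a, b = b, c = c_, d = d,
               odds_ratio = fit$or, beta = fit$beta, se = fit$se,
               p_value = fit$p, separation = fit$separation)
  })
  res <- do.call(rbind, res)
  res$direction <- ifelse(res$odds_ratio > 1, "up-enriched",
                          ifelse(res$odds_ratio < 1, "down-enriched", "none"))
  if (adjust == "BH") res$p_adj <- stats::p.adjust(res$p_value, "BH")
  rownames(res) <- NULL
  res
}

#' Logistic-regression odds ratio of one 2x2 table
#'
#' Fits `group (up = 1) ~ presence` by iteratively reweighted least
#' squares on the aggregated binomial data and reports the presence
#' coefficient. With an empty cell the maximum likelihood estimate
#' diverges, so the +0.5-corrected closed form is reported instead with
#' `separation = TRUE`.
#'
#' @param a,b up-group genes with / without the motif.
#' @param c,d down-group genes with / without the motif.
#' @return List with `or`, `beta`, `se`, `p`, `separation`.
#' @export
or_glm <- function(a, b, c, d) {
  if (min(a + b, c + d) == 0) stop("a group of size 0")
  if (min(a, b, c, d) == 0) {
    a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5
    beta <- log((a * d) / (b * c))
    se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
    z <- beta / se
    return(list(or = exp(beta), beta = beta, se = se,
                p = 2 * pnorm(-abs(z)), separation = TRUE))
  }
  # aggregated binomial rows: presence = 1 and presence = 0
  x <- cbind(1, c(1, 0))
  y <- c(a / (a + c), b / (b + d))
  w <- c(a + c, b + d)
  fit <- stats::glm.fit(x, y, weights = w, family = binomial(),
                        control = stats::glm.control(epsilon = 1e-12,
                                                     maxit = 100))
  beta <- fit$coefficients[2]
  # Wald SE from the inverse Fisher information, as summary.glm computes it
  p <- fit$rank
  cov <- chol2inv(fit$qr$qr[seq_len(p), seq_len(p), drop = FALSE])
  se <- sqrt(cov[2, 2])
  z <- beta / se
  list(or = unname(exp(beta)), beta = unname(beta), se = se,
       p = 2 * pnorm(-abs(z)), separation = FALSE)
}
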