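#' Write and read k-mer sets as sorted plain text
#'
#' One word per line, with a `#k=<k> canonical=<flag>` header line.
#'
#' @param x a [kmer_set].
#' @param path file path.
#' @return `path` (write) or a [kmer_set] (read).
#' @export
write_kmer_set <- function(x, path) {
  stopifnot(inherits(x, "kmer_set"))
  writeLines(c(sprintf("#k=%d canonical=%s", x$k, x$canonical), kmer_words(x)),
             path)
  invisible(path)
}

#' @rdname write_kmer_set
#' @export
read_kmer_set <- function(path) {
  lines <- readLines(path)
  header <- lines[1]
  k <- as.integer(sub("^#k=(\\d+).*$", "\\1", header))
  canonical <- grepl("canonical=TRUE", header)
  kmer_set(lines[-1][nzchar(lines[-1])], k = k, canonical = canonical)
}

#' Write a window track as bedGraph
#'
#' @param track a [window_track].
#' @param path output path.
#' @export
write_track_bedgraph <- function(track, path) {
  stopifnot(inherits(track, "window_track"))
  write.table(data.frame(track$chrom, format(track$start, scientific = FALSE, trim = TRUE),
                         format(track$end, scientific = FALSE, trim = TRUE), track$value),
              path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write SDR calls as BED (plus optional JSON sidecar)
#'
#' @param calls an `sdr_call` data frame from [call_sdr()].
#' @param path BED output path.
#' @param json_path optional JSON output path with the full call fields.
#' @export
write_sdr_calls <- function(calls, path, json_path = NULL) {
  bed <- data.frame(calls$chrom,
                    format(calls$start, scientific = FALSE, trim = TRUE),
                    format(calls$end, scientific = FALSE, trim = TRUE),
                    sprintf("sdr_call_%d", seq_len(nrow(calls))),
                    round(calls$fold_over_background, 3))
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  if (!is.null(json_path)) {
    jsonlite::write_json(as.data.frame(calls), json_path, digits = NA)
  }
  invisible(path)
}

#' Write a Mapper graph as JSON
#'
#' Nodes (with members) and weighted edges, for plotting or export to
#' graph tools.
#'
#' @param graph a [mapper_graph].
#' @param path output path.
#' @export
write_mapper_json <- function(graph, path) {
  stopifnot(inherits(graph, "mapper_graph"))
  nodes <- graph$nodes
  payload <- list(
    nodes = lapply(seq_len(nrow(nodes)), function(i) {
      list(node = nodes$node[i], interval = nodes$interval[i],
           members = nodes$members[[i]], mean_lens = nodes$mean_lens[i],
           majority_group = nodes$majority_group[i])
    }),
    edges = graph$edges
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an expression matrix from TSV
#'
#' First column gene ids, remaining columns samples.
#'
#' @param path TSV path.
#' @return Numeric matrix genes x samples.
#' @export
read_expression_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Write an expression matrix to TSV
#'
#' @param expr genes x samples matrix.
#' @param path TSV path.
#' @export
write_expression_tsv <- function(expr, path) {
  df <- data.frame(gene = rownames(expr), expr, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
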