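#' K-mer sets
#'
#' A `kmer_set` holds the distinct fixed-length nucleotide words of one
#' individual or assembly. Words are stored internally as sorted 2-bit
#' integer codes (exact in a double for `k <= 26`), which makes the
#' meryl-style set algebra used for sex-chromosome inference fast and
#' deterministic. When `canonical = TRUE` each word is replaced by the
#' lexicographically smaller of itself and its reverse complement, so
#' counting is strand-independent.
#'
#' @param words character vector of k-length ACGT words (may be empty).
#' @param k word length. Must be odd when `canonical = TRUE` (an even-k
#'   palindrome equals its own reverse complement, making the canonical
#'   form ill-defined as a strand indicator).
#' @param canonical logical; store canonical (strand-independent) words.
#' @return An object of class `kmer_set` with fields `k`, `canonical` and
#'   sorted unique `codes`.
#' @seealso [count_kmers()], [kmer_words()]
#' @examples
#' ks <- kmer_set(c("ACG", "CGT"), k = 3)
#' kmer_words(ks)
#' @export
kmer_set <- function(words = character(), k, canonical = TRUE) {
  check_k(k, canonical)
  codes <- if (length(words)) encode_kmers_cpp(words, as.integer(k), canonical) else numeric()
  new_kmer_set(codes, k, canonical)
}

new_kmer_set <- function(codes, k, canonical) {
  structure(
    list(k = as.integer(k), canonical = isTRUE(canonical), codes = codes),
    class = "kmer_set"
  )
}

check_k <- function(k, canonical) {
  if (length(k) != 1 || is.na(k) || k < 1 || k != as.integer(k)) {
    stop("`k` must be a single positive integer")
  }
  if (k > 26) {
    stop("`k` must be <= 26 (codes are stored exactly in doubles)")
  }
  if (canonical && k %% 2 == 0) {
    stop("canonical k-mers require odd `k`: even-length palindromes make ",
         "the canonical form ill-defined")
  }
  invisible(TRUE)
}

#' Count the distinct k-mers of a set of sequences
#'
#' Enumerates every window of length `k` containing only A/C/G/T (windows
#' spanning any other symbol, e.g. N, are skipped) over all input
#' sequences and returns the distinct words as a [kmer_set].
#'
#' @param sequences character vector or `Biostrings::DNAStringSet`.
#' @inheritParams kmer_set
#' @return A [kmer_set].
#' @examples
#' kmer_words(count_kmers("ACGTA", k = 3, canonical = FALSE))
#' kmer_words(count_kmers("ACGTA", k = 3, canonical = TRUE))
#' @export
count_kmers <- function(sequences, k = 21, canonical = TRUE) {
  check_k(k, canonical)
  sequences <- as_sequence_chr(sequences)
  codes <- kmer_codes_cpp(sequences, as.integer(k), canonical)
  new_kmer_set(codes, k, canonical)
}

as_sequence_chr <- function(x) {
  if (methods::is(x, "XStringSet") || methods::is(x, "XString")) {
    return(as.character(x))
  }
  if (!is.character(x)) stop("sequences must be character or a DNAStringSet")
  x
}

#' @export
length.kmer_set <- function(x) length(x$codes)

#' Decode a k-mer set to its words
#'
#' @param x a [kmer_set].
#' @return Sorted character vector of words.
#' @export
kmer_words <- function(x) {
  stopifnot(inherits(x, "kmer_set"))
  if (!length(x$codes)) return(character())
  decode_kmers_cpp(x$codes, x$k)
}

#' @export
print.kmer_set <- function(x, ...) {
  cat(sprintf("<kmer_set> %d distinct %d-mers (%s)\n",
              length(x$codes), x$k,
              if (x$canonical) "canonical" else "forward-strand"))
  if (length(x$codes)) {
    shown <- decode_kmers_cpp(head(x$codes, 5), x$k)
    cat("  ", paste(shown, collapse = " "),
        if (length(x$codes) > 5) "..." else "", "\n")
  }
  invisible(x)
}

check_compatible <- function(a, b) {
  if (a$k != b$k) stop("k-mer sets have mixed k values (", a$k, " vs ", b$k, ")")
  if (a$canonical != b$canonical) stop("k-mer sets mix canonical and forward-strand words")
  invisible(TRUE)
}

#' Set algebra on k-mer sets
#'
#' Intersection, union and difference of [kmer_set] objects sharing the
#' same `k` and canonical flag.
#'
#' @param a,b [kmer_set] objects.
#' @return A [kmer_set].
#' @export
kmer_intersect <- function(a, b) {
  check_compatible(a, b)
  new_kmer_set(sorted_intersect_cpp(a$codes, b$codes), a$k, a$canonical)
}

#' @rdname kmer_intersect
#' @export
kmer_union <- function(a, b) {
  check_compatible(a, b)
  new_kmer_set(sorted_union_cpp(a$codes, b$codes), a$k, a$canonical)
}

#' @rdname kmer_intersect
#' @export
kmer_setdiff <- function(a, b) {
  check_compatible(a, b)
  new_kmer_set(sorted_setdiff_cpp(a$codes, b$codes), a$k, a$canonical)
}
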