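# Kyte-Doolittle hydropathy scale.
KD_SCALE <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5,
              E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
              M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
              Y = -1.3, V = 4.2)

# Average residue masses (Da); a peptide adds one water (18.015 Da).
RESIDUE_MASS <- c(G = 57.052, A = 71.079, S = 87.078, P = 97.117, V = 99.133,
                  T = 101.105, C = 103.139, L = 113.159, I = 113.159,
                  N = 114.104, D = 115.089, Q = 128.131, K = 128.174,
                  E = 129.116, M = 131.193, H = 137.141, F = 147.177,
                  R = 156.188, Y = 163.176, W = 186.213)
WATER_MASS <- 18.015

# pKa values for Henderson-Hasselbalch charge summation.
PKA <- list(nterm = 8.6, cterm = 3.6,
            positive = c(K = 10.8, R = 12.5, H = 6.5),
            negative = c(D = 3.9, E = 4.1, C = 8.5, Y = 10.1))

check_peptide <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1 || is.na(sequence)) {
    stop("sequence must be a single string")
  }
  if (!nzchar(sequence)) stop("empty peptide sequence")
  letters <- strsplit(sequence, "")[[1]]
  bad <- which(!(letters %in% names(KD_SCALE)))
  if (length(bad)) {
    stop(sprintf("nonstandard residue '%s' at position %d",
                 letters[bad[1]], bad[1]))
  }
  letters
}

#' Grand average of hydropathy (GRAVY)
#'
#' Mean Kyte-Doolittle hydropathy over residues; positive values indicate
#' hydrophobic peptides.
#'
#' @param sequence one peptide string over the 20 standard letters.
#' @return GRAVY score in `[-4.5, 4.5]`.
#' @examples
#' gravy("AAA")
#' @export
gravy <- function(sequence) {
  mean(KD_SCALE[check_peptide(sequence)])
}

#' Peptide molecular weight
#'
#' Sum of average residue masses plus one water (18.015 Da).
#'
#' @inheritParams gravy
#' @return Mass in daltons.
#' @examples
#' molecular_weight("GG")
#' @export
molecular_weight <- function(sequence) {
  sum(RESIDUE_MASS[check_peptide(sequence)]) + WATER_MASS
}

#' Net charge at a given pH
#'
#' Henderson-Hasselbalch summation: each positive group (N-terminus, K,
#' R, H) contributes `1 / (1 + 10^(pH - pKa))` and each negative group
#' (C-terminus, D, E, C, Y) contributes `-1 / (1 + 10^(pKa - pH))`.
#' Termini are always included; cysteine bridges are not modeled.
#'
#' @inheritParams gravy
#' @param pH solution pH in (0, 14).
#' @return Signed net charge.
#' @export
net_charge <- function(sequence, pH = 7.0) {
  stopifnot(pH > 0, pH < 14)
  letters <- check_peptide(sequence)
  pos_pka <- c(PKA$nterm, unname(PKA$positive[letters[letters %in% names(PKA$positive)]]))
  neg_pka <- c(PKA$cterm, unname(PKA$negative[letters[letters %in% names(PKA$negative)]]))
  sum(1 / (1 + 10^(pH - pos_pka))) - sum(1 / (1 + 10^(neg_pka - pH)))
}

#' Isoelectric point
#'
#' The pH at which [net_charge()] is zero, found by bisection.
#'
#' @inheritParams gravy
#' @return pI estimate.
#' @export
isoelectric_point <- function(sequence) {
  uniroot(function(p) net_charge(sequence, p), c(0.01, 13.99),
          tol = 1e-9)$root
}

#' Charge-hydropathy disorder proxy
#'
#' Uversky-style classification: with normalized mean hydropathy
#' `h_norm = mean((KD + 4.5) / 9)` and mean absolute net charge per
#' residue at pH 7, the score is
#' `h_norm - (mean_abs_charge + 1.151) / 2.785`; peptides score below the
#' charge-hydropathy boundary (score < 0) are predicted intrinsically
#' disordered. This is a transparent sequence-composition proxy; external
#' per-peptide disorder predictions can be substituted downstream.
#'
#' @inheritParams gravy
#' @return List with `ch_score` and logical `predicted_disordered`
#'   (strictly negative scores only).
#' @export
disorder_proxy <- function(sequence) {
  letters <- check_peptide(sequence)
  h_norm <- mean((KD_SCALE[letters] + 4.5) / 9)
  mac <- abs(net_charge(sequence, 7.0)) / length(letters)
  score <- h_norm - (mac + 1.151) / 2.785
  list(ch_score = unname(score), predicted_disordered = unname(score < 0))
}

#' Peptide feature table
#'
#' Computes the full descriptor record for each peptide: length, GRAVY,
#' molecular weight, net charge at `pH`, mean absolute charge per
#' residue, normalized hydropathy, charge-hydropathy score and the
#' disorder call.
#'
#' @param sequences named character vector or `AAStringSet`.
#' @param pH pH for the charge terms (default 7).
#' @return data frame, one row per peptide.
#' @export
peptide_features <- function(sequences, pH = 7.0) {
  if (methods::is(sequences, "XStringSet")) sequences <- as.character(sequences)
  ids <- names(sequences)
  if (is.null(ids)) ids <- sprintf("pep%d", seq_along(sequences))
  rows <- lapply(seq_along(sequences), function(i) {
    s <- sequences[[i]]
    letters <- check_peptide(s)
    nc <- net_charge(s, pH)
    dp <- disorder_proxy(s)
    data.frame(peptide = ids[i], length = length(letters),
               gravy = gravy(s), mol_weight = molecular_weight(s),
               net_charge = nc, mean_abs_charge = abs(nc) / length(letters),
               h_norm = mean((KD_SCALE[letters] + 4.5) / 9),
               ch_score = dp$ch_score,
               predicted_disordered = dp$predicted_disordered)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Correlation and PCA summary of peptide features
#'
#' Pearson correlations over the numeric feature columns and a PCA on the
#' standardized features. Zero-variance features are dropped with a
#' warning.
#'
#' @param records a [peptide_features()] data frame (>= 3 rows).
#' @param features feature columns to summarize.
#' @return List with `correlation` (symmetric matrix), `scores` (peptide
#'   x component) and `var_frac`.
#' @export
feature_summary <- function(records,
                            features = c("gravy", "mol_weight", "net_charge",
                                         "mean_abs_charge", "ch_score")) {
  stopifnot(nrow(records) >= 3, all(features %in% names(records)))
  x <- as.matrix(records[, features, drop = FALSE])
  v <- apply(x, 2, var)
  if (any(v == 0)) {
    warning("dropping zero-variance feature(s): ",
            paste(features[v == 0], collapse = ", "))
    x <- x[, v > 0, drop = FALSE]
  }
  if (ncol(x) < 2) stop("need >= 2 features with nonzero variance")
  p <- prcomp(x, center = TRUE, scale. = TRUE)
  rownames(p$x) <- records$peptide
  list(correlation = cor(x), scores = p$x,
       var_frac = p$sdev^2 / sum(p$sdev^2))
}
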