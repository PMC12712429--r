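BASES <- c("A", "C", "G", "T")

random_dna <- function(n) {
  paste(sample(BASES, n, replace = TRUE), collapse = "")
}

# Substitute each base independently with probability `rate` (always to a
# different base). Raw-vector arithmetic keeps this fast at Mb scale.
mutate_sequence <- function(sequence, rate) {
  if (rate == 0) return(sequence)
  r <- charToRaw(sequence)
  n <- length(r)
  idx <- which(runif(n) < rate)
  if (!length(idx)) return(sequence)
  base_raw <- charToRaw(paste(BASES, collapse = ""))
  cur <- match(r[idx], base_raw) - 1L
  r[idx] <- base_raw[((cur + sample.int(3, length(idx), replace = TRUE)) %% 4L) + 1L]
  rawToChar(r)
}

#' Simulate a sexed diploid cohort with a planted Y-specific region
#'
#' Builds an X/Y reference chromosome pair in which the Y carries a
#' contiguous region of novel sequence replacing the homologous X
#' interval (replacement, not insertion, so both haplotypes have equal
#' length and window coordinates stay comparable), plus optional
#' autosomes. Each individual is diploid: females carry two X-derived
#' haplotypes, males one X- and one Y-derived haplotype, every haplotype
#' differing from its reference by i.i.d. substitutions at `snp_rate`
#' (the inter-haplotype SNP density scale observed in highly heterozygous
#' outcrossers, about 47 SNPs per 10 kb at the default).
#'
#' @param n_autosomes autosome count (>= 0, default 1).
#' @param chrom_length chromosome length in bases.
#' @param sdr_length sex-determining-region length in bases (default
#'   700 kb, a small plant SDR); must be below `chrom_length`.
#' @param snp_rate substitutions per base between any haplotype and its
#'   reference, in `[0, 0.1)` (default 0.004738).
#' @param n_males,n_females cohort sizes (defaults 5 and 5).
#' @param seed integer seed; identical seeds give byte-identical output.
#' @param out_dir optional directory: writes reference and per-individual
#'   FASTA files plus a JSON truth record.
#' @return List with `reference` (named chromosome sequences, X and Y
#'   kept as `chrX`/`chrY`), `individuals` (per individual: `id`, `sex`,
#'   named diploid `haplotypes`), and `truth` (`chrom`, 0-based half-open
#'   `start`/`end` of the SDR on the Y).
#' @export
simulate_sexed_genomes <- function(n_autosomes = 1, chrom_length = 2e6,
                                   sdr_length = 7e5, snp_rate = 0.004738,
                                   n_males = 5, n_females = 5, seed = 1,
                                   out_dir = NULL) {
  if (sdr_length >= chrom_length) stop("invalid config: sdr_length must be < chrom_length")
  if (snp_rate < 0 || snp_rate >= 0.1) stop("invalid config: snp_rate outside [0, 0.1)")
  if (n_males < 1 || n_females < 1) stop("invalid config: need >= 1 of each sex")
  if (n_autosomes < 0) stop("invalid config: n_autosomes must be >= 0")
  with_seed(seed, {
    autosomes <- setNames(
      lapply(seq_len(n_autosomes), function(i) random_dna(chrom_length)),
      if (n_autosomes) sprintf("chr%d", seq_len(n_autosomes)) else character()
    )
    x_chrom <- random_dna(chrom_length)
    sdr_start <- sample.int(chrom_length - sdr_length + 1L, 1) - 1L  # 0-based
    y_chrom <- paste0(substr(x_chrom, 1, sdr_start),
                      random_dna(sdr_length),
                      substr(x_chrom, sdr_start + sdr_length + 1, chrom_length))
    reference <- c(autosomes, list(chrX = x_chrom, chrY = y_chrom))

    make_individual <- function(id, sex) {
      hap <- function(ref_names, hap_tag) {
        if (!length(ref_names)) return(list())
        setNames(
          lapply(ref_names, function(nm) mutate_sequence(reference[[nm]], snp_rate)),
          paste0(ref_names, "_", hap_tag)
        )
      }
      auto_names <- if (is.null(names(autosomes))) character() else names(autosomes)
      sex_pair <- if (sex == "male") c("chrX", "chrY") else c("chrX", "chrX")
      haplotypes <- c(
        hap(auto_names, "h1"), hap(auto_names, "h2"),
        setNames(list(mutate_sequence(reference[[sex_pair[1]]], snp_rate)),
                 paste0(sex_pair[1], "_h1")),
        setNames(list(mutate_sequence(reference[[sex_pair[2]]], snp_rate)),
                 paste0(sex_pair[2], "_h2"))
      )
      list(id = id, sex = sex, haplotypes = haplotypes)
    }
    ids_m <- sprintf("M%02d", seq_len(n_males))
    ids_f <- sprintf("F%02d", seq_len(n_females))
    individuals <- c(
      lapply(ids_m, make_individual, sex = "male"),
      lapply(ids_f, make_individual, sex = "female")
    )
    names(individuals) <- c(ids_m, ids_f)
    truth <- list(chrom = "chrY", start = sdr_start, end = sdr_start + sdr_length)

    if (!is.null(out_dir)) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      write_fasta_chr(unlist(reference), file.path(out_dir, "reference.fa"))
      for (ind in individuals) {
        write_fasta_chr(unlist(ind$haplotypes),
                        file.path(out_dir, paste0(ind$id, ".fa")))
      }
      jsonlite::write_json(truth, file.path(out_dir, "sdr_truth.json"),
                           auto_unbox = TRUE)
    }
    list(reference = reference, individuals = individuals, truth = truth)
  })
}

write_fasta_chr <- function(seqs, path) {
  dna <- Biostrings::DNAStringSet(unlist(seqs))
  Biostrings::writeXStringSet(dna, path)
  invisible(path)
}

#' Per-individual k-mer sets of a simulated cohort
#'
#' @param genomes result of [simulate_sexed_genomes()].
#' @param k odd word length in `[3, 25]` (default 21).
#' @param canonical store canonical words (default `TRUE`).
#' @return Named list of [kmer_set] objects, one per individual.
#' @export
simulate_individual_kmer_sets <- function(genomes, k = 21, canonical = TRUE) {
  if (k %% 2 == 0) stop("k must be odd: canonical form is ill-defined for palindromes")
  if (k < 3) stop("k must be >= 3")
  lapply(genomes$individuals, function(ind) {
    count_kmers(unlist(ind$haplotypes, use.names = FALSE), k = k, canonical = canonical)
  })
}

default_module_spec <- function() {
  list(
    list(label = "shared_up", size = 100, direction = "up", dependence = "shared"),
    list(label = "shared_down", size = 100, direction = "down", dependence = "shared"),
    list(label = "severe_up", size = 50, direction = "up", dependence = "severe-only"),
    list(label = "severe_down", size = 50, direction = "down", dependence = "severe-only"),
    list(label = "mild_up", size = 25, direction = "up", dependence = "mild-only")
  )
}

#' Simulate a field dehydration-rehydration expression time course
#'
#' Plants dry along piecewise-linear relative-water-content trajectories
#' from a hydrated baseline to a plant-specific minimum at the last
#' dehydration time point, then recover after a rain event; per-plant
#' minima place equal numbers of plants in the `mild`, `severe` and
#' `desiccation` drying groups. Module genes respond on the log2 scale
#' with amplitude `effect_size` scaled by each plant's dehydration
#' progress (0 at baseline, 1 at its own minimum RWC), gated by the
#' module's severity dependence: `shared` modules respond in every group,
#' `severe-only` modules only in severe/desiccation plants, `mild-only`
#' modules only in mild plants. All remaining genes are stationary noise.
#' Abundances carry log-normal multiplicative noise of log2-scale
#' standard deviation `noise_dispersion`.
#'
#' @param n_plants number of plants (default 12; must divide by 3).
#' @param n_timepoints sampling points (default 13: one baseline, six
#'   dehydration, six rehydration).
#' @param n_genes total genes (module sizes must fit inside).
#' @param module_spec list of modules, each
#'   `list(label, size, direction = "up"|"down",
#'   dependence = "shared"|"severe-only"|"mild-only")`.
#' @param effect_size peak log2 fold change of module genes (default 3).
#' @param noise_dispersion log2-scale noise standard deviation (default
#'   0.25).
#' @param seed integer seed.
#' @return List with `expression` (genes x samples TPM matrix),
#'   `metadata` (sample, plant, sex, timepoint, phase, masses, rwc,
#'   group) and `truth` (gene, label, direction, dependence).
#' @export
simulate_timecourse_expression <- function(n_plants = 12, n_timepoints = 13,
                                           n_genes = 2000,
                                           module_spec = default_module_spec(),
                                           effect_size = 3,
                                           noise_dispersion = 0.25,
                                           seed = 1) {
  if (n_plants %% 3 != 0) stop("invalid config: n_plants must divide into three drying groups")
  if (n_timepoints < 3) stop("invalid config: need baseline, dehydration and rehydration points")
  sizes <- vapply(module_spec, `[[`, numeric(1), "size")
  if (sum(sizes) > n_genes) stop("invalid config: module sizes exceed n_genes")
  with_seed(seed, {
    plants <- sprintf("P%02d", seq_len(n_plants))
    sex <- rep(c("male", "female"), length.out = n_plants)
    group <- rep(c("mild", "severe", "desiccation"), each = n_plants / 3)
    min_rwc <- c(runif(n_plants / 3, 0.60, 0.80),
                 runif(n_plants / 3, 0.12, 0.28),
                 runif(n_plants / 3, 0.03, 0.08))
    baseline_rwc <- 0.95

    # timepoint grid: baseline, then dehydration to the pre-rain minimum,
    # then linear recovery over the first 2/3 of the rehydration points
    n_dehyd <- ceiling((n_timepoints - 1) / 2)
    tp_min <- 1 + n_dehyd
    tp_recovered <- min(n_timepoints, tp_min + ceiling((n_timepoints - tp_min) * 2 / 3))
    rwc_at <- function(p, t) {
      if (t <= 1) return(baseline_rwc)
      if (t <= tp_min) {
        return(baseline_rwc - (baseline_rwc - min_rwc[p]) * (t - 1) / (tp_min - 1))
      }
      if (t >= tp_recovered) return(baseline_rwc)
      min_rwc[p] + (baseline_rwc - min_rwc[p]) * (t - tp_min) / (tp_recovered - tp_min)
    }
    tps <- sprintf("T%02d", seq_len(n_timepoints))
    phase <- c("baseline", rep("dehydration", tp_min - 1),
               rep("rehydration", n_timepoints - tp_min))

    meta <- expand.grid(plant = seq_len(n_plants), tp = seq_len(n_timepoints))
    meta$sample <- paste(plants[meta$plant], tps[meta$tp], sep = "_")
    meta$rwc <- mapply(rwc_at, meta$plant, meta$tp)
    dry <- runif(n_plants, 0.5, 1.5)
    turgid <- dry + runif(n_plants, 1.0, 2.0)
    meta$dry_mass <- dry[meta$plant]
    meta$turgid_mass <- turgid[meta$plant]
    meta$fresh_mass <- meta$dry_mass + meta$rwc * (meta$turgid_mass - meta$dry_mass)

    # per-gene truth
    genes <- sprintf("g%04d", seq_len(n_genes))
    truth <- data.frame(gene = genes, label = "background",
                        direction = NA_character_, dependence = NA_character_)
    at <- 0
    for (m in module_spec) {
      idx <- at + seq_len(m$size)
      truth$label[idx] <- m$label
      truth$direction[idx] <- m$direction
      truth$dependence[idx] <- m$dependence
      at <- at + m$size
    }

    base_log2 <- runif(n_genes, 3, 9)
    dir_sign <- ifelse(is.na(truth$direction), 0,
                       ifelse(truth$direction == "up", 1, -1))
    # dehydration progress of each sample relative to its plant's minimum
    progress <- (baseline_rwc - meta$rwc) / (baseline_rwc - min_rwc[meta$plant])
    grp_s <- group[meta$plant]
    gate_by_dep <- rbind(
      "shared" = rep(1, nrow(meta)),
      "severe-only" = as.numeric(grp_s %in% c("severe", "desiccation")),
      "mild-only" = as.numeric(grp_s == "mild")
    )
    gate_mat <- matrix(0, n_genes, nrow(meta))
    di <- match(truth$dependence, rownames(gate_by_dep))
    gate_mat[!is.na(di), ] <- gate_by_dep[di[!is.na(di)], , drop = FALSE]
    signal <- (dir_sign * effect_size) %o% progress * gate_mat
    log2tpm <- base_log2 + signal +
      matrix(rnorm(n_genes * nrow(meta), sd = noise_dispersion),
             n_genes, nrow(meta))
    expr <- 2^log2tpm
    dimnames(expr) <- list(genes, meta$sample)

    metadata <- data.frame(
      sample = meta$sample, plant = plants[meta$plant],
      sex = sex[meta$plant], timepoint = tps[meta$tp],
      phase = phase[meta$tp],
      fresh_mass = meta$fresh_mass, turgid_mass = meta$turgid_mass,
      dry_mass = meta$dry_mass, rwc = meta$rwc,
      group = group[meta$plant]
    )
    list(expression = expr, metadata = metadata, truth = truth)
  })
}

#' Simulate promoter sets with group-differential motif frequencies
#'
#' Promoters are i.i.d. uniform ACGT backgrounds of `promoter_length`
#' bases; each motif is planted (one concrete instantiation of its IUPAC
#' pattern at a position not overlapping previously planted motifs) with
#' probability `freq_up` in upregulated-gene promoters and `freq_down` in
#' downregulated ones, so planting never destroys another planted motif.
#'
#' @param n_up,n_down promoter counts per group (defaults 50 and 50).
#' @param promoter_length bases (default 1000; must fit every motif).
#' @param motif_freqs data frame with columns `id`, `pattern` (IUPAC),
#'   `freq_up`, `freq_down` in `[0, 1]`.
#' @param seed integer seed.
#' @return List with `sequences` (named character), `groups`
#'   (`"up"`/`"down"` per promoter) and `truth` (promoter, motif,
#'   planted flag, 0-based position or NA).
#' @export
simulate_promoter_set <- function(n_up = 50, n_down = 50,
                                  promoter_length = 1000,
                                  motif_freqs, seed = 1) {
  stopifnot(all(c("id", "pattern", "freq_up", "freq_down") %in% names(motif_freqs)))
  if (any(motif_freqs$freq_up < 0 | motif_freqs$freq_up > 1 |
          motif_freqs$freq_down < 0 | motif_freqs$freq_down > 1)) {
    stop("invalid config: motif frequencies must lie in [0, 1]")
  }
  if (any(nchar(motif_freqs$pattern) > promoter_length)) {
    stop("invalid config: motif longer than promoter")
  }
  for (p in motif_freqs$pattern) check_iupac(p)
  with_seed(seed, {
    n <- n_up + n_down
    ids <- c(sprintf("up%03d", seq_len(n_up)), sprintf("down%03d", seq_len(n_down)))
    groups <- c(rep("up", n_up), rep("down", n_down))
    seqs <- character(n)
    truth <- list()
    for (i in seq_len(n)) {
      s <- strsplit(random_dna(promoter_length), "")[[1]]
      occupied <- matrix(numeric(0), ncol = 2)  # [start, end) planted spans
      for (j in seq_len(nrow(motif_freqs))) {
        freq <- if (groups[i] == "up") motif_freqs$freq_up[j] else motif_freqs$freq_down[j]
        planted <- runif(1) < freq
        pos <- NA_integer_
        if (planted) {
          len <- nchar(motif_freqs$pattern[j])
          pos <- place_motif(promoter_length, len, occupied)
          if (!is.na(pos)) {
            inst <- instantiate_iupac(motif_freqs$pattern[j])
            s[(pos + 1):(pos + len)] <- strsplit(inst, "")[[1]]
            occupied <- rbind(occupied, c(pos, pos + len))
          } else {
            planted <- FALSE
          }
        }
        truth[[length(truth) + 1]] <- data.frame(
          promoter = ids[i], motif = motif_freqs$id[j],
          planted = planted, position = pos)
      }
      seqs[i] <- paste(s, collapse = "")
    }
    names(seqs) <- ids
    list(sequences = seqs, groups = groups, truth = do.call(rbind, truth))
  })
}

# Random 0-based start avoiding previously planted spans; NA if no slot
# found in 200 draws.
place_motif <- function(prom_len, motif_len, occupied) {
  for (try in seq_len(200)) {
    pos <- sample.int(prom_len - motif_len + 1L, 1) - 1L
    if (!nrow(occupied)) return(pos)
    clash <- any(pos < occupied[, 2] & (pos + motif_len) > occupied[, 1])
    if (!clash) return(pos)
  }
  NA_integer_
}

# One concrete sequence drawn uniformly from an IUPAC pattern.
instantiate_iupac <- function(pattern) {
  letters <- strsplit(toupper(pattern), "")[[1]]
  paste(vapply(letters, function(l) {
    opts <- strsplit(IUPAC_CODES[[l]], "")[[1]]
    if (length(opts) == 1) opts else sample(opts, 1)
  }, character(1)), collapse = "")
}

#' Default amino-acid composition biases for peptide simulation
#'
#' Uniform composition shifted toward the defining residues of each
#' class: `acidic` toward E/D, `hydrophobic` toward I/V/L/A, `disordered`
#' toward E/K/S/P/Q (a LEA-like composition) and `ordered` toward
#' I/V/L/F/A (a folded, ELIP-like composition).
#'
#' @param class one of `"acidic"`, `"hydrophobic"`, `"disordered"`,
#'   `"ordered"`.
#' @return Named frequency vector over the 20 residues, summing to 1.
#' @export
peptide_class_bias <- function(class = c("acidic", "hydrophobic",
                                         "disordered", "ordered")) {
  class <- match.arg(class)
  aa <- names(KD_SCALE)
  w <- setNames(rep(1, 20), aa)
  boost <- switch(class,
                  acidic = c(E = 12, D = 12),
                  hydrophobic = c(I = 10, V = 10, L = 10, A = 6),
                  disordered = c(E = 8, K = 8, S = 6, P = 6, Q = 4),
                  ordered = c(I = 8, V = 8, L = 8, F = 5, A = 5))
  w[names(boost)] <- w[names(boost)] + boost
  w / sum(w)
}

#' Simulate labeled peptide sets
#'
#' Sequences are drawn i.i.d. from per-class amino-acid composition
#' vectors, giving classes with distinct charge/hydropathy structure.
#'
#' @param classes named list of composition vectors (each a named
#'   frequency vector over the 20 standard residues summing to 1 within
#'   1e-9), e.g. from [peptide_class_bias()].
#' @param n_per_class peptides per class (default 100).
#' @param length peptide length (default 100).
#' @param seed integer seed.
#' @return List with `sequences` (named character) and `labels`.
#' @export
simulate_peptide_set <- function(classes, n_per_class = 100, length = 100,
                                 seed = 1) {
  stopifnot(is.list(classes), !is.null(names(classes)))
  for (nm in names(classes)) {
    comp <- classes[[nm]]
    if (!all(names(comp) %in% names(KD_SCALE)) || length(comp) == 0) {
      stop("class ", nm, ": composition must be named by standard residues")
    }
    if (abs(sum(comp) - 1) > 1e-9) {
      stop("class ", nm, ": composition frequencies must sum to 1")
    }
    if (any(comp < 0)) stop("class ", nm, ": negative frequencies")
  }
  with_seed(seed, {
    seqs <- character(0)
    labels <- character(0)
    for (nm in names(classes)) {
      comp <- classes[[nm]]
      new <- vapply(seq_len(n_per_class), function(i) {
        paste(sample(names(comp), length, replace = TRUE, prob = comp),
              collapse = "")
      }, character(1))
      names(new) <- sprintf("%s_%03d", nm, seq_len(n_per_class))
      seqs <- c(seqs, new)
      labels <- c(labels, rep(nm, n_per_class))
    }
    list(sequences = seqs, labels = labels)
  })
}
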