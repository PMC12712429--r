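#' Default end-to-end pipeline configuration
#'
#' The simulation conditions the whole pipeline is validated under: a
#' 5-male/5-female cohort on a 2-Mb sex chromosome carrying a 200-kb
#' Y-specific region at realistic inter-haplotype SNP density; 12 plants
#' over 13 time points in three drying groups; a promoter set with one
#' strongly group-differential W-box-like motif; and disordered-vs-
#' ordered peptide classes. Any field can be overridden via the YAML
#' config handed to [run_pipeline()].
#'
#' @return Nested configuration list.
#' @export
default_config <- function() {
  list(
    genomes = list(n_autosomes = 0, chrom_length = 2e6, sdr_length = 2e5,
                   snp_rate = 0.004738, n_males = 5, n_females = 5,
                   k = 21, window_width = 2e4, min_fold = 3, min_run = 2),
    expression = list(n_plants = 12, n_timepoints = 13, n_genes = 2000,
                      effect_size = 3, noise_dispersion = 0.25,
                      lfc = 2, alpha = 0.05,
                      n_intervals = 110, overlap = 0.9),
    promoters = list(n_up = 50, n_down = 50, promoter_length = 1000,
                     motif_id = "ACGTABREMOTIFA2OSEM", motif_pattern = "ACGTGKC",
                     freq_up = 0.8, freq_down = 0.2, n_replicates = 100),
    peptides = list(classes = c("disordered", "ordered"),
                    n_per_class = 100, length = 100)
  )
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Run the full synthetic-data pipeline
#'
#' Simulates every input and pushes it through the package's four
#' analysis arms: (1) k-mer sexing and SDR localization, (2) time-course
#' differential-abundance summarization plus Mapper and PCA, (3)
#' promoter motif enrichment (with a replicate power estimate), and (4)
#' peptide feature profiling. Returns the recovery metrics for each arm
#' and optionally writes the main artifacts.
#'
#' @param config `NULL` (defaults), a YAML file path, or a nested list
#'   overriding [default_config()] fields.
#' @param seed integer seed driving every stage's simulation.
#' @param out_dir optional output directory for tables/graphs.
#' @return List of per-stage results and a `metrics` summary.
#' @export
run_pipeline <- function(config = NULL, seed = 1, out_dir = NULL) {
  cfg <- default_config()
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.null(config)) cfg <- merge_config(cfg, config)
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  sexing <- pipeline_sexing(cfg$genomes, seed, out_dir)
  expression <- pipeline_expression(cfg$expression, seed + 1L, out_dir)
  cre <- pipeline_cre(cfg$promoters, seed + 2L, out_dir)
  peptides <- pipeline_peptides(cfg$peptides, seed + 3L, out_dir)

  metrics <- c(sexing$metrics, expression$metrics, cre$metrics, peptides$metrics)
  list(sexing = sexing, expression = expression, cre = cre,
       peptides = peptides, metrics = metrics)
}

pipeline_sexing <- function(g, seed, out_dir) {
  sim <- simulate_sexed_genomes(
    n_autosomes = g$n_autosomes, chrom_length = g$chrom_length,
    sdr_length = g$sdr_length, snp_rate = g$snp_rate,
    n_males = g$n_males, n_females = g$n_females, seed = seed)
  sets <- simulate_individual_kmer_sets(sim, k = g$k)
  sex <- vapply(sim$individuals, `[[`, character(1), "sex")
  cohort <- sexed_cohort(sets, sex)
  spec <- sex_specific_kmers(cohort)
  call <- classify_heterogamety(spec$male_specific, spec$female_specific)
  assembly <- unlist(sim$reference)
  scan <- sdr_scan(spec$male_specific, assembly, width = g$window_width,
                   step = g$window_width, min_fold = g$min_fold,
                   min_run = g$min_run)
  top <- if (nrow(scan$calls)) scan$calls[1, ] else NULL
  jac <- if (!is.null(top) && top$chrom == sim$truth$chrom) {
    interval_jaccard(c(top$start, top$end),
                     c(sim$truth$start, sim$truth$end))
  } else {
    0
  }
  if (!is.null(out_dir)) {
    write_sdr_calls(scan$calls, file.path(out_dir, "sdr_calls.bed"),
                    file.path(out_dir, "sdr_calls.json"))
    write_track_bedgraph(scan$track, file.path(out_dir, "ymer_density.bedgraph"))
  }
  list(call = call, scan = scan, truth = sim$truth,
       metrics = list(sex_system = call$system,
                      kmer_ratio = call$ratio,
                      sdr_jaccard = jac))
}

pipeline_expression <- function(e, seed, out_dir) {
  sim <- simulate_timecourse_expression(
    n_plants = e$n_plants, n_timepoints = e$n_timepoints, n_genes = e$n_genes,
    effect_size = e$effect_size, noise_dispersion = e$noise_dispersion,
    seed = seed)
  md <- sim$metadata
  baseline_tp <- md$timepoint[md$phase == "baseline"][1]
  dehyd_tps <- unique(md$timepoint[md$phase == "dehydration"])

  # per-group DAT calls over the dehydration phase
  nonred <- list()
  for (grp in unique(md$group)) {
    cols <- md$group == grp
    stats <- welch_de_stats(sim$expression[, cols, drop = FALSE],
                            md$timepoint[cols], baseline_tp)
    calls <- classify_dats(stats, lfc = e$lfc, alpha = e$alpha)
    dehyd <- calls[sub("_vs_.*", "", calls$comparison) %in% dehyd_tps, ]
    nonred[[grp]] <- nonredundant_dats(dehyd)
  }

  recovery <- dat_recovery(sim$truth, nonred)
  venn_up <- overlap_sets(nonred[["mild"]]$up, nonred[["severe"]]$up,
                          nonred[["desiccation"]]$up,
                          names = c("mild", "severe", "desiccation"))

  graph <- mapper_graph(sim$expression, setNames(md$rwc, md$sample),
                        n_intervals = e$n_intervals, overlap = e$overlap,
                        groups = md$group)
  covered <- all(md$sample %in% unlist(graph$nodes$members))
  pca <- pca_scores(log2(sim$expression + 1))
  pc1_cor <- cor(pca$scores[md$sample, 1], md$rwc)

  if (!is.null(out_dir)) {
    write_expression_tsv(sim$expression, file.path(out_dir, "expression_tpm.tsv"))
    write.table(md, file.path(out_dir, "sample_metadata.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write_mapper_json(graph, file.path(out_dir, "mapper_graph.json"))
  }
  list(nonredundant = nonred, venn_up = venn_up, graph = graph, pca = pca,
       metadata = md, truth = sim$truth,
       metrics = list(de_sensitivity = recovery$sensitivity,
                      de_fdr = recovery$fdr,
                      pc1_rwc_abs_cor = abs(pc1_cor),
                      mapper_samples_covered = covered))
}

# Sensitivity: fraction of planted module genes recovered in the correct
# direction in at least one drying group where the module is active.
# FDR: fraction of (gene, direction, group) calls not matching a planted
# module active in that group.
dat_recovery <- function(truth, nonred) {
  active_groups <- function(dep) {
    switch(dep,
           "shared" = c("mild", "severe", "desiccation"),
           "severe-only" = c("severe", "desiccation"),
           "mild-only" = "mild",
           character())
  }
  planted <- truth[truth$label != "background", ]
  hit <- vapply(seq_len(nrow(planted)), function(i) {
    dirset <- if (planted$direction[i] == "up") "up" else "down"
    any(vapply(active_groups(planted$dependence[i]), function(g) {
      planted$gene[i] %in% nonred[[g]][[dirset]]
    }, logical(1)))
  }, logical(1))
  n_called <- 0
  n_false <- 0
  for (g in names(nonred)) {
    for (dirset in c("up", "down")) {
      called <- nonred[[g]][[dirset]]
      n_called <- n_called + length(called)
      ok <- called %in% planted$gene[
        planted$direction == dirset &
          vapply(planted$dependence, function(d) g %in% active_groups(d), logical(1))]
      n_false <- n_false + sum(!ok)
    }
  }
  list(sensitivity = mean(hit),
       fdr = if (n_called) n_false / n_called else 0)
}

pipeline_cre <- function(p, seed, out_dir) {
  motifs <- data.frame(id = p$motif_id, pattern = p$motif_pattern,
                       freq_up = p$freq_up, freq_down = p$freq_down)
  sim <- simulate_promoter_set(n_up = p$n_up, n_down = p$n_down,
                               promoter_length = p$promoter_length,
                               motif_freqs = motifs, seed = seed)
  hits <- scan_motifs(sim$sequences, motifs[, c("id", "pattern")])
  enr <- enrich_motifs(hits, sim$groups)

  rejected <- logical(p$n_replicates)
  for (r in seq_len(p$n_replicates)) {
    s <- simulate_promoter_set(n_up = p$n_up, n_down = p$n_down,
                               promoter_length = p$promoter_length,
                               motif_freqs = motifs, seed = seed + r)
    h <- scan_motifs(s$sequences, motifs[, c("id", "pattern")])
    e2 <- enrich_motifs(h, s$groups)
    rejected[r] <- e2$p_value[1] < 0.05 && e2$odds_ratio[1] > 1
  }
  if (!is.null(out_dir)) {
    write.table(enr, file.path(out_dir, "cre_enrichment.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(enrichment = enr,
       metrics = list(cre_odds_ratio = enr$odds_ratio[1],
                      cre_p_value = enr$p_value[1],
                      cre_power = mean(rejected)))
}

pipeline_peptides <- function(pp, seed, out_dir) {
  classes <- setNames(lapply(pp$classes, peptide_class_bias), pp$classes)
  sim <- simulate_peptide_set(classes, n_per_class = pp$n_per_class,
                              length = pp$length, seed = seed)
  feats <- peptide_features(sim$sequences)
  summ <- feature_summary(feats)
  # midpoint-threshold separation of the two classes along PC1
  acc <- NA_real_
  if (length(unique(sim$labels)) == 2) {
    pc1 <- summ$scores[, 1]
    lv <- unique(sim$labels)
    mid <- mean(c(mean(pc1[sim$labels == lv[1]]), mean(pc1[sim$labels == lv[2]])))
    side <- pc1 > mid
    acc <- max(mean(side == (sim$labels == lv[1])),
               mean(side == (sim$labels == lv[2])))
  }
  if (!is.null(out_dir)) {
    write.table(feats, file.path(out_dir, "peptide_features.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(features = feats, summary = summ, labels = sim$labels,
       metrics = list(gravy_ch_cor = unname(summ$correlation["gravy", "ch_score"]),
                      pc1_class_accuracy = acc))
}
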