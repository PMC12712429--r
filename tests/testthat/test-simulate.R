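test_that("all simulators are byte-identical under a fixed seed", {
  g1 <- simulate_sexed_genomes(n_autosomes = 0, chrom_length = 2e4,
                               sdr_length = 5e3, seed = 1)
  g2 <- simulate_sexed_genomes(n_autosomes = 0, chrom_length = 2e4,
                               sdr_length = 5e3, seed = 1)
  expect_identical(g1, g2)
  e1 <- simulate_timecourse_expression(n_genes = 100, module_spec = small_module_spec(), seed = 3)
  e2 <- simulate_timecourse_expression(n_genes = 100, module_spec = small_module_spec(), seed = 3)
  expect_identical(e1, e2)
  mot <- data.frame(id = "W", pattern = "TTGACY", freq_up = 0.5, freq_down = 0.5)
  p1 <- simulate_promoter_set(10, 10, 200, mot, seed = 4)
  p2 <- simulate_promoter_set(10, 10, 200, mot, seed = 4)
  expect_identical(p1, p2)
  cls <- list(acidic = peptide_class_bias("acidic"))
  s1 <- simulate_peptide_set(cls, 5, 30, seed = 5)
  s2 <- simulate_peptide_set(cls, 5, 30, seed = 5)
  expect_identical(s1, s2)
  # different seeds diverge
  expect_false(identical(g1$reference$chrX,
                         simulate_sexed_genomes(n_autosomes = 0,
                                                chrom_length = 2e4,
                                                sdr_length = 5e3,
                                                seed = 2)$reference$chrX))
})

test_that("zero SNP rate leaves females identical and males differing only in the SDR", {
  sim <- simulate_sexed_genomes(n_autosomes = 1, chrom_length = 1e4,
                                sdr_length = 2e3, snp_rate = 0, seed = 8)
  females <- Filter(function(i) i$sex == "female", sim$individuals)
  males <- Filter(function(i) i$sex == "male", sim$individuals)
  for (f in females) expect_identical(f$haplotypes, females[[1]]$haplotypes)
  # male chrY haplotype differs from chrX exactly inside the SDR
  m <- males[[1]]
  x <- m$haplotypes$chrX_h1
  y <- m$haplotypes$chrY_h2
  s <- sim$truth$start; e <- sim$truth$end
  expect_identical(substr(y, 1, s), substr(x, 1, s))
  expect_identical(substr(y, e + 1, nchar(y)), substr(x, e + 1, nchar(x)))
  expect_false(identical(substr(y, s + 1, e), substr(x, s + 1, e)))
})

test_that("Y-SDR 21-mers are absent from every female genome (brute force)", {
  sim <- simulate_sexed_genomes(n_autosomes = 0, chrom_length = 5e4,
                                sdr_length = 1e4, seed = 7)
  k <- 21
  sdr_seq <- substr(sim$reference$chrY, sim$truth$start + 1, sim$truth$end)
  # k-mers wholly inside the truth SDR
  sdr_words <- oracle_kmers(sdr_seq, k, canonical = TRUE)
  female_seqs <- unlist(lapply(
    Filter(function(i) i$sex == "female", sim$individuals),
    function(i) unlist(i$haplotypes, use.names = FALSE)))
  female_words <- oracle_kmers(female_seqs, k, canonical = TRUE)
  expect_length(intersect(sdr_words, female_words), 0)
  # config validation
  expect_error(simulate_sexed_genomes(chrom_length = 1e4, sdr_length = 1e4),
               "invalid config")
  expect_error(simulate_sexed_genomes(snp_rate = 0.5), "invalid config")
})

test_that("individual k-mer sets equal brute-force enumeration", {
  sim <- simulate_sexed_genomes(n_autosomes = 0, chrom_length = 3e3,
                                sdr_length = 500, n_males = 1, n_females = 1,
                                seed = 2)
  sets <- simulate_individual_kmer_sets(sim, k = 7)
  for (id in names(sets)) {
    expect_identical(kmer_words(sets[[id]]),
                     oracle_kmers(unlist(sim$individuals[[id]]$haplotypes),
                                  7, TRUE))
  }
  expect_error(simulate_individual_kmer_sets(sim, k = 8), "odd")
})

test_that("time-course RWC declines, recovers, and balances the drying groups", {
  sim <- simulate_timecourse_expression(n_genes = 50, module_spec = small_module_spec(), seed = 6)
  md <- sim$metadata
  expect_equal(nrow(md), 12 * 13)
  # recomputing RWC from the masses reproduces the stored trajectory
  expect_equal(compute_rwc(md$fresh_mass, md$turgid_mass, md$dry_mass), md$rwc,
               tolerance = 1e-12)
  # four plants per drying group, as called from minimum RWC
  min_rwc <- tapply(md$rwc, md$plant, min)
  expect_equal(as.vector(table(assign_drying_group(min_rwc))), c(4L, 4L, 4L))
  expect_equal(sort(unique(md$group)), c("desiccation", "mild", "severe"))
  # decline then recovery around the rain event
  one <- md[md$plant == "P09", ]
  one <- one[order(one$timepoint), ]
  tp_min <- which.min(one$rwc)
  expect_true(all(diff(one$rwc[1:tp_min]) <= 0))
  expect_gte(one$rwc[13], 0.9)
})

test_that("noiseless module genes move in their planted direction in every plant", {
  sim <- simulate_timecourse_expression(n_genes = 400, noise_dispersion = 0,
                                        seed = 9)
  md <- sim$metadata
  up_gene <- sim$truth$gene[sim$truth$label == "shared_up"][1]
  down_gene <- sim$truth$gene[sim$truth$label == "shared_down"][1]
  for (p in unique(md$plant)) {
    rows <- md[md$plant == p, ]
    at_min <- rows$sample[which.min(rows$rwc)]
    at_base <- rows$sample[rows$phase == "baseline"]
    expect_gt(sim$expression[up_gene, at_min], sim$expression[up_gene, at_base])
    expect_lt(sim$expression[down_gene, at_min], sim$expression[down_gene, at_base])
  }
  # severity gating: severe-only genes move >4-fold in desiccation plants,
  # <1.2-fold in mild plants
  sev_gene <- sim$truth$gene[sim$truth$label == "severe_up"][1]
  for (p in unique(md$plant)) {
    rows <- md[md$plant == p, ]
    fold <- sim$expression[sev_gene, rows$sample[which.min(rows$rwc)]] /
      sim$expression[sev_gene, rows$sample[rows$phase == "baseline"]]
    if (rows$group[1] == "desiccation") expect_gt(fold, 4)
    if (rows$group[1] == "mild") expect_lt(fold, 1.2)
  }
})

test_that("promoter planting respects frequencies and never destroys motifs", {
  mot <- data.frame(id = c("W", "G"), pattern = c("TTGACY", "ACGTGKC"),
                    freq_up = c(1, 0.5), freq_down = c(0, 0.5))
  sim <- simulate_promoter_set(n_up = 30, n_down = 30, promoter_length = 300,
                               motif_freqs = mot, seed = 10)
  hits <- scan_motifs(sim$sequences, mot[, c("id", "pattern")])
  # freq (1, 0): all up promoters carry the motif
  expect_true(all(hits[sim$groups == "up", "W"] == 1))
  # every planted motif is recoverable at its recorded position
  tr <- sim$truth[sim$truth$planted, ]
  for (i in seq_len(nrow(tr))) {
    pat <- mot$pattern[mot$id == tr$motif[i]]
    window <- substr(sim$sequences[[tr$promoter[i]]],
                     tr$position[i] + 1, tr$position[i] + nchar(pat))
    expect_true(grepl(iupac_to_regex(pat), window))
  }
  expect_error(simulate_promoter_set(5, 5, 4,
                                     data.frame(id = "m", pattern = "ACGTA",
                                                freq_up = 1, freq_down = 1)),
               "longer than promoter")
})

test_that("peptide classes carry their composition signature", {
  cls <- list(acidic = peptide_class_bias("acidic"),
              hydrophobic = peptide_class_bias("hydrophobic"))
  sim <- simulate_peptide_set(cls, n_per_class = 25, length = 80, seed = 11)
  feats <- peptide_features(sim$sequences)
  expect_lt(mean(feats$net_charge[sim$labels == "acidic"]), 0)
  expect_gt(mean(feats$gravy[sim$labels == "hydrophobic"]), 0)
  bad <- list(x = c(A = 0.5, C = 0.4))
  expect_error(simulate_peptide_set(bad, 2, 10), "sum to 1")
})
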