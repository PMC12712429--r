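test_that("promoter extraction is strand-aware and truncates at contig edges", {
  contig <- rand_dna(2000)
  genome <- c(ctg = contig)
  genes <- data.frame(
    gene = c("plus", "minus", "edge"),
    chrom = "ctg",
    start = c(1001, 201, 401),
    end = c(1500, 500, 900),
    strand = c("+", "-", "+"))
  pr <- extract_promoters(genes, genome, upstream = 1000)
  # plus strand: the 1000 bases immediately 5' of the start
  expect_equal(as.character(pr[["plus"]]), substr(contig, 1, 1000))
  # minus strand: reverse complement of the bases 3' of the gene end
  expect_equal(as.character(pr[["minus"]]),
               oracle_revcomp(substr(contig, 501, 1500)))
  # truncated at the contig start
  expect_equal(as.character(pr[["edge"]]), substr(contig, 1, 400))
  expect_equal(S4Vectors::mcols(pr)$truncated, c(FALSE, FALSE, TRUE))
  # unknown strand errors with the gene named
  bad <- genes; bad$strand[1] <- "*"
  expect_error(extract_promoters(bad, genome), "plus")
  # gene flush at the contig start: zero-length promoter with a warning
  flush <- data.frame(gene = "g0", chrom = "ctg", start = 1, end = 50, strand = "+")
  expect_warning(p0 <- extract_promoters(flush, genome), "zero-length")
  expect_equal(BiocGenerics::width(p0), 0)
})

test_that("promoter extraction consumes GFF3 through the standard importer", {
  gff <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "ctg\ttest\tgene\t1001\t1500\t.\t+\t.\tID=gA",
    "ctg\ttest\tmRNA\t1001\t1500\t.\t+\t.\tID=gA.1;Parent=gA",
    "ctg\ttest\tgene\t201\t500\t.\t-\t.\tID=gB"
  ), gff)
  contig <- rand_dna(2000)
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">ctg description text", contig), fa)
  pr <- extract_promoters(gff, fa, upstream = 300)
  expect_setequal(names(pr), c("gA", "gB"))
  expect_equal(as.character(pr[["gA"]]), substr(contig, 701, 1000))
  expect_equal(as.character(pr[["gB"]]), oracle_revcomp(substr(contig, 501, 800)))
})

test_that("degenerate motif scanning matches on either strand", {
  proms <- c(p1 = "AATTGACA", p2 = "GGCAGCTGTT", p3 = "GGTCAAGG", p4 = "AAAAAAAA")
  motifs <- data.frame(id = c("WBOX", "EBOX"), pattern = c("TTGAC", "CANNTG"))
  hits <- scan_motifs(proms, motifs, both_strands = TRUE)
  expect_equal(hits["p1", "WBOX"], 1L)
  expect_equal(hits["p2", "EBOX"], 1L)
  expect_equal(hits["p3", "WBOX"], 1L)  # reverse complement GTCAA
  expect_equal(unname(hits["p4", ]), c(0L, 0L))
  # forward-only scanning misses the reverse-strand site
  fwd <- scan_motifs(proms, motifs, both_strands = FALSE)
  expect_equal(fwd["p3", "WBOX"], 0L)
  expect_error(scan_motifs(proms, c(bad = "TTQACG")), "IUPAC")
  expect_error(scan_motifs(proms, c(short = "TTG")), "at least 4")
})

test_that("IUPAC scanning agrees with a regex-expansion oracle", {
  set.seed(23)
  motifs <- c(m1 = "ACGTGKC", m2 = "CACGTG", m3 = "TTGACY", m4 = "MACGYGB")
  for (i in 1:30) {
    s <- rand_dna(300)
    hits <- scan_motifs(setNames(s, "p"), motifs, both_strands = TRUE)
    for (m in names(motifs)) {
      expected <- grepl(iupac_to_regex(motifs[[m]]), s) ||
        grepl(iupac_to_regex(motifs[[m]]), oracle_revcomp(s))
      expect_equal(unname(hits["p", m]) == 1, expected)
    }
  }
})

test_that("enrichment reproduces the closed-form 2x2 logistic estimates", {
  f <- or_glm(8, 2, 2, 8)
  expect_equal(f$or, 16, tolerance = 1e-9)
  expect_equal(f$beta, log(16), tolerance = 1e-9)
  expect_equal(f$se, sqrt(1.25), tolerance = 1e-9)
  expect_equal(f$p, 0.0131, tolerance = 5e-3)
  expect_false(f$separation)
  # equal proportions: null
  nullfit <- or_glm(10, 10, 10, 10)
  expect_equal(nullfit$or, 1, tolerance = 1e-9)
  expect_equal(nullfit$p, 1, tolerance = 1e-9)
  # complete separation: Haldane-Anscombe correction
  sepfit <- or_glm(10, 0, 0, 10)
  expect_true(sepfit$separation)
  expect_equal(sepfit$or, (10.5 * 10.5) / (0.5 * 0.5))
  expect_error(or_glm(0, 0, 5, 5), "size 0")
})

test_that("the aggregated IRLS fit equals stats::glm on expanded data", {
  set.seed(31)
  for (i in 1:10) {
    a <- sample(1:20, 1); b <- sample(1:20, 1)
    c_ <- sample(1:20, 1); d <- sample(1:20, 1)
    y <- c(rep(1, a + b), rep(0, c_ + d))
    x <- c(rep(1, a), rep(0, b), rep(1, c_), rep(0, d))
    ref <- summary(glm(y ~ x, family = binomial(),
                       control = glm.control(epsilon = 1e-12,
                                             maxit = 100)))$coefficients
    fit <- or_glm(a, b, c_, d)
    expect_equal(fit$beta, unname(ref["x", "Estimate"]), tolerance = 1e-6)
    expect_equal(fit$se, unname(ref["x", "Std. Error"]), tolerance = 1e-6)
    expect_equal(fit$p, unname(ref["x", "Pr(>|z|)"]), tolerance = 1e-6)
  }
})

test_that("enrich_motifs assembles tables, directions and label-swap symmetry", {
  set.seed(41)
  hits <- matrix(rbinom(200 * 3, 1, c(0.7, 0.3, 0.5)), ncol = 3, byrow = TRUE,
                 dimnames = list(sprintf("g%d", 1:200), c("mA", "mB", "mC")))
  groups <- rep(c("up", "down"), each = 100)
  res <- enrich_motifs(hits, groups)
  expect_equal(res$motif, c("mA", "mB", "mC"))
  expect_true(all(res$a + res$b == 100))
  expect_true(all((res$odds_ratio > 1) == (res$direction == "up-enriched") |
                    res$odds_ratio <= 1))
  # swapping labels inverts odds ratios and keeps p-values
  swapped <- enrich_motifs(hits, ifelse(groups == "up", "down", "up"))
  keep <- !res$separation
  expect_equal(swapped$odds_ratio[keep], 1 / res$odds_ratio[keep],
               tolerance = 1e-9)
  expect_equal(swapped$p_value, res$p_value, tolerance = 1e-9)
  # BH adjustment appends a column without changing raw p
  adj <- enrich_motifs(hits, groups, adjust = "BH")
  expect_equal(adj$p_adj, p.adjust(adj$p_value, "BH"))
  expect_error(enrich_motifs(hits, rep("up", 200)), "both groups")
})
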