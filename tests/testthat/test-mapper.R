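test_that("the interval cover follows the closed-form geometry", {
  cov <- build_cover(c(0, 1), n_intervals = 2, overlap = 0.5)
  expect_equal(cov$a, c(0, 1 / 3))
  expect_equal(cov$b, c(2 / 3, 1))
  one <- build_cover(c(0.2, 0.9), n_intervals = 1)
  expect_equal(c(one$a, one$b), c(0.2, 0.9))
  expect_error(build_cover(c(0, 1), 2, overlap = 1), "overlap")
  expect_error(build_cover(c(0, 1), 0), "n_intervals")
  expect_error(build_cover(c(0.5, 0.5), 3), "distinct")
})

test_that("no lens value is covered by more intervals than the overlap bound", {
  set.seed(10)
  for (i in 1:20) {
    lens <- runif(30)
    n <- sample(2:110, 1)
    overlap <- sample(c(0, 0.25, 0.5, 0.9), 1)
    cov <- build_cover(lens, n, overlap)
    n_cover <- vapply(lens, function(v) sum(v >= cov$a & v <= cov$b), numeric(1))
    expect_lte(max(n_cover), ceiling(1 / (1 - overlap)))
    expect_gte(min(n_cover), 1)
    # consecutive intervals overlap by exactly overlap * L
    if (n > 1) {
      L <- cov$b[1] - cov$a[1]
      expect_equal(cov$b[1] - cov$a[2], overlap * L, tolerance = 1e-12)
    }
  }
})

test_that("preimage clustering separates well-split groups and merges ties", {
  set.seed(6)
  # two tight groups separated by far more than their internal spread
  x <- rbind(matrix(rnorm(20, 0, 0.05), ncol = 2),
             matrix(rnorm(20, 10, 0.05), ncol = 2))
  rownames(x) <- sprintf("s%02d", 1:20)
  cl <- cluster_preimage(x)
  expect_length(cl, 2)
  expect_setequal(cl[[1]], sprintf("s%02d", 1:10))
  # one sample: one singleton cluster
  expect_equal(cluster_preimage(matrix(1, 1, 2)), list("s1"))
  # all pairwise distances equal: a single cluster
  eq <- diag(3)  # equilateral in 3-d
  rownames(eq) <- c("a", "b", "c")
  expect_length(cluster_preimage(eq), 1)
  # fixed-epsilon fallback cuts where told
  expect_length(cluster_preimage(x, fallback_epsilon = 100), 1)
})

test_that("mapper separates lens-disjoint expression groups into components", {
  set.seed(2)
  expr <- cbind(matrix(rnorm(30, 0, 0.01), ncol = 3),
                matrix(rnorm(30, 5, 0.01), ncol = 3))
  colnames(expr) <- sprintf("s%d", 1:6)
  rownames(expr) <- sprintf("g%d", 1:10)
  lens <- setNames(c(0.1, 0.11, 0.09, 0.9, 0.91, 0.89), colnames(expr))
  g <- mapper_graph(expr, lens, n_intervals = 2, overlap = 0.1)
  expect_equal(nrow(g$nodes), 2)
  expect_equal(nrow(g$edges), 0)
  expect_equal(max(graph_components(g)), 2)
})

test_that("identical samples spread over the lens give a connected chain", {
  expr <- matrix(5, nrow = 10, ncol = 10,
                 dimnames = list(sprintf("g%d", 1:10), sprintf("s%02d", 1:10)))
  lens <- setNames(seq(0, 1, length.out = 10), colnames(expr))
  g <- mapper_graph(expr, lens, n_intervals = 5, overlap = 0.5,
                    transform = "none")
  expect_gte(nrow(g$edges), nrow(g$nodes) - 1)
  expect_equal(max(graph_components(g)), 1)
})

test_that("one interval reduces mapper to plain clustering with no edges", {
  set.seed(3)
  expr <- matrix(2^rnorm(50, 5), nrow = 5)
  colnames(expr) <- sprintf("s%d", 1:10)
  lens <- setNames(runif(10), colnames(expr))
  g <- mapper_graph(expr, lens, n_intervals = 1)
  expect_equal(nrow(g$edges), 0)
  expect_equal(sort(unlist(g$nodes$members)), sort(colnames(expr)))
})

test_that("mapper invariants hold on random matrices", {
  set.seed(14)
  for (i in 1:25) {
    n_s <- sample(6:25, 1)
    expr <- matrix(2^rnorm(20 * n_s, 5), nrow = 20)
    colnames(expr) <- sprintf("s%02d", seq_len(n_s))
    lens <- setNames(runif(n_s), colnames(expr))
    g <- mapper_graph(expr, lens, n_intervals = sample(2:12, 1),
                      overlap = runif(1, 0.1, 0.9))
    # every sample appears in at least one node
    expect_true(all(colnames(expr) %in% unlist(g$nodes$members)))
    # edge weights equal recomputed member intersections; no self edges
    if (nrow(g$edges)) {
      expect_true(all(g$edges$from != g$edges$to))
      recomputed <- mapply(function(a, b) {
        length(intersect(g$nodes$members[[a]], g$nodes$members[[b]]))
      }, g$edges$from, g$edges$to)
      expect_equal(g$edges$shared, unname(recomputed))
      expect_true(all(recomputed >= 1))
    }
    # an edge exists iff two nodes share members
    for (a in seq_len(nrow(g$nodes) - 1)) {
      for (b in seq((a + 1), nrow(g$nodes))) {
        sh <- length(intersect(g$nodes$members[[a]], g$nodes$members[[b]]))
        has_edge <- any(g$edges$from == a & g$edges$to == b)
        expect_equal(has_edge, sh > 0)
      }
    }
  }
})

test_that("duplicating every sample preserves the mapper structure", {
  set.seed(9)
  expr <- matrix(2^rnorm(100, 5), nrow = 10)
  colnames(expr) <- sprintf("a%02d", 1:10)
  lens <- setNames(runif(10), colnames(expr))
  g1 <- mapper_graph(expr, lens, n_intervals = 4, overlap = 0.5)
  expr2 <- cbind(expr, expr)
  colnames(expr2) <- c(colnames(expr), sprintf("b%02d", 1:10))
  lens2 <- setNames(rep(lens, 2), colnames(expr2))
  g2 <- mapper_graph(expr2, lens2, n_intervals = 4, overlap = 0.5)
  expect_equal(nrow(g1$nodes), nrow(g2$nodes))
  expect_equal(g1$nodes$interval, g2$nodes$interval)
  expect_equal(nrow(g1$edges), nrow(g2$edges))
  # memberships double but map onto the originals
  expect_equal(vapply(g2$nodes$members, function(m) length(unique(sub("^b", "a", m))),
                      numeric(1)),
               g1$nodes$n_members)
})

test_that("node mean lens is nondecreasing in interval index for singletons", {
  expr <- matrix(seq(1, 40), nrow = 4)
  colnames(expr) <- sprintf("s%d", 1:10)
  lens <- setNames(seq(0, 1, length.out = 10), colnames(expr))
  g <- mapper_graph(expr, lens, n_intervals = 10, overlap = 0,
                    fallback_epsilon = 1e-9, transform = "none")
  singleton <- g$nodes$n_members == 1
  if (sum(singleton) > 1) {
    ml <- g$nodes$mean_lens[singleton][order(g$nodes$interval[singleton])]
    expect_true(all(diff(ml) >= 0))
  }
})

test_that("PCA scores expose rank-1 structure and rotation invariance", {
  # two exact antipodal sample groups: PC1 carries all the variance
  expr <- cbind(matrix(1, 5, 3), matrix(-1, 5, 3)) + 5
  colnames(expr) <- sprintf("s%d", 1:6)
  p <- pca_scores(expr)
  expect_equal(p$var_frac[1], 1, tolerance = 1e-9)
  expect_true(all(diff(p$var_frac) <= 1e-12))
  # orthogonal rotation of the gene space leaves variance fractions unchanged
  set.seed(17)
  x <- matrix(rnorm(60), nrow = 6)
  q <- qr.Q(qr(matrix(rnorm(36), 6, 6)))
  p1 <- pca_scores(x)
  p2 <- pca_scores(q %*% x)
  expect_equal(p1$var_frac, p2$var_frac, tolerance = 1e-9)
  expect_error(pca_scores(matrix(3, 4, 4)), "constant")
})
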