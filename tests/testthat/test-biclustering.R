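test_that("normalization drops constant genes and z-scores the rest", {
  m <- rbind(g1 = c(10L, 20L, 40L, 80L), g2 = c(5L, 5L, 5L, 5L), g3 = c(1L, 9L, 3L, 7L))
  colnames(m) <- paste0("s", 1:4)
  expect_message(z <- normalize_for_biclustering(m, rep(1, 4)), "constant")
  expect_false("g2" %in% rownames(z))
  expect_true(all(abs(rowMeans(z)) < 1e-10))
  expect_equal(unname(apply(z, 1, sd)), rep(1, 2))
  expect_error(normalize_for_biclustering(m[, 1, drop = FALSE], 1), "at least 2 samples")
})

test_that("ISA recovers a planted high-SNR block exactly and deterministically", {
  E <- planted_block_matrix(seed = 42)
  res <- run_isa(E, seed = 1)
  hit <- vapply(res$biclusters, function(b) {
    setequal(b$genes, paste0("g", 1:10)) && setequal(b$samples, paste0("s", 1:8))
  }, logical(1))
  expect_true(any(hit))
  res2 <- run_isa(E, seed = 1)
  expect_identical(lapply(res$biclusters, unclass), lapply(res2$biclusters, unclass))
})

test_that("ISA returns nothing when thresholds exceed any structure", {
  set.seed(7)
  N <- matrix(rnorm(50 * 40), 50, 40,
              dimnames = list(paste0("g", 1:50), paste0("s", 1:40)))
  res <- run_isa(N, gene_threshold = 10, sample_threshold = 10, seed = 2)
  expect_equal(length(res), 0L)
  expect_error(run_isa(N[1, , drop = FALSE], seed = 1), "at least 2 genes")
})

test_that("ISA fixed points are stable under re-iteration from the solution", {
  E <- planted_block_matrix(seed = 42)
  res <- run_isa(E, seed = 1)
  Er <- funbic:::.row_zscore(E)
  Ec <- t(funbic:::.row_zscore(t(E)))
  for (b in res$biclusters[seq_len(min(5, length(res)))]) {
    G <- match(b$genes, rownames(E))
    S2 <- funbic:::.threshold_cut(colMeans(Er[G, , drop = FALSE]), 2)
    expect_setequal(colnames(E)[S2], b$samples)
    G2 <- funbic:::.threshold_cut(rowMeans(Ec[, S2, drop = FALSE]), 2)
    expect_setequal(rownames(E)[G2], b$genes)
  }
})

test_that("plaid recovers a planted additive block and rejects pure noise", {
  E <- matrix(0, 50, 40, dimnames = list(paste0("g", 1:50), paste0("s", 1:40)))
  E[1:10, 1:8] <- 5
  res <- run_plaid(E, seed = 3)
  expect_gte(length(res), 1L)
  expect_setequal(res$biclusters[[1]]$genes, paste0("g", 1:10))
  expect_setequal(res$biclusters[[1]]$samples, paste0("s", 1:8))

  set.seed(8)
  N <- matrix(rnorm(60 * 30), 60, 30,
              dimnames = list(paste0("g", 1:60), paste0("s", 1:30)))
  expect_equal(length(run_plaid(N, seed = 4)), 0L)

  res2 <- run_plaid(E, seed = 3)
  expect_identical(lapply(res$biclusters, unclass), lapply(res2$biclusters, unclass))
})

test_that("combining sets concatenates without deduplication", {
  mk <- function(n, alg) {
    bicluster_set(lapply(seq_len(n), function(i) {
      bicluster(paste0(alg, "_", i), alg, paste0("g", i), paste0("s", i))
    }))
  }
  combo <- combine_bicluster_sets(list(mk(2, "a"), mk(3, "b")))
  expect_equal(length(combo), 5L)
  expect_equal(vapply(combo$biclusters, `[[`, "", "id"), paste0("bc_", 1:5))

  with_empty <- combine_bicluster_sets(list(mk(2, "a"), bicluster_set(list())))
  expect_equal(length(with_empty), 2L)

  dup <- combine_bicluster_sets(list(mk(1, "a"), mk(1, "a")))
  expect_equal(length(dup), 2L) # duplicates retained

  m1 <- matrix(1, 2, 2, dimnames = list(c("g1", "g2"), c("s1", "s2")))
  m2 <- matrix(1, 2, 2, dimnames = list(c("gA", "gB"), c("s1", "s2")))
  s1 <- bicluster_set(list(bicluster("x", "a", "g1", "s1")), source = funbic:::.source_sig(m1))
  s2 <- bicluster_set(list(bicluster("y", "a", "gA", "s1")), source = funbic:::.source_sig(m2))
  expect_error(combine_bicluster_sets(list(s1, s2)), "different source")
})

test_that("pair-based Jaccard matches its definition in both modes", {
  a <- bicluster("a", "x", c("g1", "g2"), c("s1", "s2"))
  b <- bicluster("b", "x", c("g2", "g3"), c("s2", "s3"))
  expect_equal(bicluster_jaccard(a, a), 1)
  expect_equal(bicluster_jaccard(a, a, mode = "rectangles"), 1)
  expect_equal(bicluster_jaccard(a, b), 1 / 9)
  expect_equal(bicluster_jaccard(a, b, mode = "rectangles"), pair_jaccard_oracle(a, b))
  disj <- bicluster("c", "x", c("g8", "g9"), c("s1", "s2"))
  expect_equal(bicluster_jaccard(a, disj), 0)
})

test_that("Jaccard is symmetric, bounded, and 1 only for identical biclusters", {
  set.seed(9)
  genes <- paste0("g", 1:12); samples <- paste0("s", 1:10)
  for (i in 1:50) {
    a <- bicluster("a", "x", sample(genes, sample(1:6, 1)), sample(samples, sample(1:5, 1)))
    b <- bicluster("b", "x", sample(genes, sample(1:6, 1)), sample(samples, sample(1:5, 1)))
    for (mode in c("literal", "rectangles")) {
      j <- bicluster_jaccard(a, b, mode)
      expect_equal(j, bicluster_jaccard(b, a, mode))
      expect_gte(j, 0); expect_lte(j, 1)
      expect_equal(j == 1,
                   setequal(a$genes, b$genes) && setequal(a$samples, b$samples))
    }
  }
})

test_that("the Jaccard matrix is symmetric with unit diagonal and equivariant", {
  b1 <- bicluster("b1", "x", c("g1", "g2"), c("s1", "s2"))
  b2 <- bicluster("b2", "x", c("g1", "g2"), c("s1", "s2"))
  b3 <- bicluster("b3", "x", c("g9", "g8"), c("s9", "s8"))
  J <- jaccard_matrix(bicluster_set(list(b1, b2, b3)))
  expect_equal(diag(J), c(b1 = 1, b2 = 1, b3 = 1))
  expect_equal(J, t(J))
  expect_setequal(J[upper.tri(J)], c(1, 0, 0))
  Jp <- jaccard_matrix(bicluster_set(list(b3, b1, b2)))
  expect_equal(Jp[c("b1", "b2", "b3"), c("b1", "b2", "b3")],
               J[c("b1", "b2", "b3"), c("b1", "b2", "b3")])
  expect_error(jaccard_matrix(bicluster_set(list(b1))), "at least 2")
})
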