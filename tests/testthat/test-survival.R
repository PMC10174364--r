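test_that("PCA stratification splits at the component median", {
  set.seed(701)
  # 6 genes x 4 samples, two samples shifted: PC1 separates them
  expr <- matrix(rnorm(24, sd = 0.1), 6, 4,
                 dimnames = list(paste0("g", 1:6), paste0("s", 1:4)))
  expr[, 3:4] <- expr[, 3:4] + 3
  lab <- pca_stratify(expr, "pc1-median")
  expect_equal(as.vector(sort(table(lab))), c(2L, 2L))
  expect_equal(length(unique(lab[c("s1", "s2")])), 1)
  expect_equal(length(unique(lab[c("s3", "s4")])), 1)

  # odd sample count: the sample at the median joins the low group
  expr5 <- cbind(expr, s5 = rnorm(6, sd = 0.1))
  lab5 <- pca_stratify(expr5, "pc1-median")
  expect_equal(as.vector(sort(table(lab5))), c(2L, 3L))
  expect_equal(names(which.max(table(lab5))), "low")
})

test_that("k-means stratification recovers well-separated clouds exactly", {
  set.seed(702)
  expr <- matrix(rnorm(40, sd = 0.1), 5, 8,
                 dimnames = list(paste0("g", 1:5), paste0("s", 1:8)))
  expr[, 5:8] <- expr[, 5:8] + 10
  lab <- pca_stratify(expr, "kmeans2", seed = 1)
  expect_equal(length(unique(lab[1:4])), 1)
  expect_equal(length(unique(lab[5:8])), 1)
  expect_false(lab[1] == lab[5])

  expect_error(pca_stratify(matrix(1, 5, 8), "pc1-median"), "constant")
  expect_error(pca_stratify(expr[, 1:3], "pc1-median"), "at least 4")
})

test_that("KM curve reproduces closed-form product-limit values", {
  km <- km_curve(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$survival, c(2 / 3, 1 / 3, 0))

  cens <- km_curve(c(4, 7, 9), c(0, 0, 0))
  expect_true(all(cens$survival == 1))

  one <- km_curve(c(5, 10), c(1, 0))
  expect_equal(one$survival[one$time == 5], 0.5)

  expect_error(km_curve(c(-1, 2), c(1, 1)), "nonnegative")
  expect_error(km_curve(c(1, 2), 1), "length")
})

test_that("KM equals one minus the empirical CDF without censoring", {
  set.seed(703)
  for (i in 1:20) {
    tt <- round(rexp(15, 0.1), 2)
    km <- km_curve(tt, rep(1, 15))
    ecdf_surv <- vapply(km$time, function(x) mean(tt > x), numeric(1))
    expect_equal(km$survival, ecdf_surv, tolerance = 1e-12)
  }
})

test_that("log-rank behaves at its null and under strong separation", {
  r <- logrank_test(c(1, 2, 3, 1, 2, 3), c(1, 1, 1, 1, 1, 1), rep(c("a", "b"), each = 3))
  expect_equal(r$statistic, 0, tolerance = 1e-12)
  expect_equal(r$p, 1)

  r0 <- logrank_test(c(1, 2, 3, 4), c(0, 0, 0, 0), c("a", "a", "b", "b"))
  expect_equal(r0$p, 1)

  set.seed(704)
  tt <- c(rexp(50, 1), rexp(50, 5))
  grp <- rep(c("slow", "fast"), each = 50)
  expect_lt(logrank_test(tt, rep(1, 100), grp)$p, 0.01)

  expect_error(logrank_test(c(1, 2), c(1, 1), c("a", "a")), "two nonempty groups")
})

test_that("chi-square log-rank p agrees with a permutation reference", {
  set.seed(705)
  for (i in 1:10) {
    n <- 24
    tt <- rexp(n, 0.2); ev <- rbinom(n, 1, 0.8)
    grp <- sample(rep(c("a", "b"), n / 2))
    p1 <- logrank_test(tt, ev, grp)$p
    p2 <- logrank_test(tt, ev, grp, method = "permutation", n_perm = 2000, seed = i)$p
    expect_equal(p1, p2, tolerance = 0.08)
  }
})

.small_cfg <- function(...) {
  generator_config(n_genes = 500,
                   group_sizes = c(colon_normal = 20, colon_tumor = 20,
                                   endometrium_normal = 20, endometrium_tumor = 20),
                   n_tissue_de = 50, n_cancer_de = 40,
                   modules_per_class = c(colon_tumor = 1, endometrium_tumor = 1,
                                         colon_normal = 1, endometrium_normal = 1),
                   module_genes = 20, module_samples = 10, ...)
}

test_that("a planted hazard-multiplying module is flagged survival-significant", {
  sim <- generate_cohort(.small_cfg(), seed = 31)
  sf <- size_factors(sim$counts, pseudo_reference = TRUE)
  lognorm <- log2(sweep(sim$counts, 2, sf, "/") + 1)
  mod <- Filter(function(m) m$class == "colon_tumor", sim$truth$modules)[[1]]
  bic <- bicluster("planted", "truth", mod$genes, mod$samples)
  res <- bicluster_survival_screen(bic, lognorm, sim$samples, cohort = "colon", seed = 1)
  expect_true(res$significant)
  expect_named(res$p_values, c("pc1-median", "pc2-median", "kmeans2"))
  expect_s3_class(res, "survival_result")
})

test_that("null gene sets are flagged at about the family-wise chance rate", {
  # rate over random null gene sets and cohort realizations; three correlated
  # stratifications at alpha 0.05 give a family-wise chance rate below 0.15
  rates <- vapply(31:34, function(cs) {
    sim <- generate_cohort(generator_config(hazard_multiplier = 1), seed = cs)
    sf <- size_factors(sim$counts, pseudo_reference = TRUE)
    lognorm <- log2(sweep(sim$counts, 2, sf, "/") + 1)
    null_genes <- names(sim$truth$gene_class)[sim$truth$gene_class == "null"]
    set.seed(cs + 700)
    mean(replicate(50, {
      bic <- bicluster("r", "rand", sample(null_genes, 20), sim$samples$sample[1])
      bicluster_survival_screen(bic, lognorm, sim$samples, cohort = "colon",
                                seed = 1)$significant
    }))
  }, numeric(1))
  expect_lte(mean(rates), 0.15)
})

test_that("the screen validates its inputs", {
  sim <- generate_cohort(.small_cfg(), seed = 33)
  sf <- size_factors(sim$counts, pseudo_reference = TRUE)
  lognorm <- log2(sweep(sim$counts, 2, sf, "/") + 1)
  bad <- bicluster("bad", "x", c("gX1", "gX2"), sim$samples$sample[1:3])
  expect_error(bicluster_survival_screen(bad, lognorm, sim$samples, cohort = "colon"),
               "absent from matrix")
  ok <- bicluster("ok", "x", rownames(lognorm)[1:5], sim$samples$sample[1:3])
  nosurv <- sim$samples; nosurv$os_time <- NULL; nosurv$os_event <- NULL
  expect_error(bicluster_survival_screen(ok, lognorm, nosurv, cohort = "colon"),
               "survival columns")
  expect_error(bicluster_survival_screen(ok, lognorm, sim$samples), "no enriched class")
})
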