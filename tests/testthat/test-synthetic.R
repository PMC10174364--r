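.small_gen <- function(...) {
  generator_config(n_genes = 500,
                   group_sizes = c(colon_normal = 20, colon_tumor = 20,
                                   endometrium_normal = 20, endometrium_tumor = 20),
                   n_tissue_de = 50, n_cancer_de = 40,
                   modules_per_class = c(colon_tumor = 1, endometrium_tumor = 1,
                                         colon_normal = 1, endometrium_normal = 1),
                   module_genes = 20, module_samples = 10, ...)
}

test_that("the toy ontology has the complete-tree size and placement invariants", {
  cfg <- generator_config(ontology_depth = 4, ontology_branching = 2,
                          modules_per_class = c(colon_tumor = 1, endometrium_tumor = 1,
                                                colon_normal = 1, endometrium_normal = 1))
  onto <- generate_ontology(cfg, seed = 1)
  expect_equal(length(onto$dag$terms), 31) # 1 + 2 + 4 + 8 + 16

  onto3 <- generate_ontology(generator_config(), seed = 1)
  for (mid in names(Filter(function(m) grepl("tumor", m$class),
                           setNames(funbic:::.gene_layout(generator_config())$modules,
                                    vapply(funbic:::.gene_layout(generator_config())$modules,
                                           `[[`, "", "id"))))) {
    mt <- onto3$module_terms[[mid]]
    expect_true(any(onto3$deg_terms %in% ancestors(onto3$dag, mt)))
  }
  # deterministic given seed
  onto3b <- generate_ontology(generator_config(), seed = 1)
  expect_identical(onto3$annot$map, onto3b$annot$map)
  expect_identical(onto3$dag$edges, onto3b$dag$edges)
})

test_that("infeasible module placement is rejected", {
  cfg <- generator_config(ontology_branching = 2,
                          modules_per_class = c(colon_tumor = 4, endometrium_tumor = 4))
  expect_error(generate_ontology(cfg, seed = 1), "too small")
})

test_that("generator validates its configuration", {
  expect_error(generator_config(group_sizes = c(colon_normal = 1, colon_tumor = 40,
                                                endometrium_normal = 40, endometrium_tumor = 40)),
               "at least 2")
  expect_error(generator_config(module_samples = 100), "exceeds")
  expect_error(generator_config(tissue_lfc = -1), "nonnegative")
  expect_error(generator_config(n_genes = 100), "exceed n_genes")
  expect_error(generator_config(ontology_depth = 2), "depth")
})

test_that("cohorts have the configured shape and are reproducible", {
  cfg <- .small_gen()
  sim <- generate_cohort(cfg, seed = 5)
  expect_equal(dim(sim$counts), c(500, 80))
  expect_equal(unname(table(sim$samples$tissue, sim$samples$condition)["colon", "tumor"]), 20)
  expect_true(all(sim$counts >= 0))
  expect_true(all(!is.na(sim$samples$os_time[sim$samples$condition == "tumor"])))
  expect_true(all(is.na(sim$samples$os_time[sim$samples$condition == "normal"])))

  sim2 <- generate_cohort(cfg, seed = 5)
  expect_identical(sim$counts, sim2$counts)
  expect_identical(sim$samples, sim2$samples)
  sim3 <- generate_cohort(cfg, seed = 6)
  expect_false(identical(sim$counts, sim3$counts))
})

test_that("realized cancer fold changes track the configured effect", {
  cfg <- generator_config()  # 40/group, lfc 2
  sim <- generate_cohort(cfg, seed = 7)
  lay <- funbic:::.gene_layout(cfg)
  colon_up <- lay$cancer_de[seq(1, length(lay$cancer_de), by = 2)]
  ct <- sim$samples$sample[sim$samples$tissue == "colon" & sim$samples$condition == "tumor"]
  et <- sim$samples$sample[sim$samples$tissue == "endometrium" & sim$samples$condition == "tumor"]
  lfc <- log2(rowMeans(sim$counts[colon_up, ct]) / rowMeans(sim$counts[colon_up, et]))
  expect_equal(mean(lfc), cfg$cancer_lfc, tolerance = 0.3)
})

test_that("module samples stay inside their class and raise their hazard", {
  cfg <- .small_gen()
  sim <- generate_cohort(cfg, seed = 8)
  for (m in sim$truth$modules) {
    grp <- sim$samples[match(m$samples, sim$samples$sample), ]
    expect_equal(unique(paste(grp$tissue, grp$condition, sep = "_")), m$class)
    if (grepl("tumor", m$class)) {
      expect_true(all(sim$truth$hazard[m$samples] >= cfg$baseline_hazard * cfg$hazard_multiplier))
    }
  }
})

test_that("the DEG stage recovers planted cancer genes and excludes tissue genes", {
  hits <- c(); fps <- c()
  for (seed in 1:5) {
    cfg <- generator_config()
    sim <- generate_cohort(cfg, seed = seed)
    sf <- size_factors(sim$counts, pseudo_reference = TRUE)
    st <- sim$samples
    grp <- function(t, cd) st$sample[st$tissue == t & st$condition == cd]
    tum <- select_degs(nb_deg_test(sim$counts, grp("colon", "tumor"),
                                   grp("endometrium", "tumor"), sf = sf))
    nor <- select_degs(nb_deg_test(sim$counts, grp("colon", "normal"),
                                   grp("endometrium", "normal"), sf = sf))
    cs <- cancer_specific_degs(tum, nor)
    cls <- sim$truth$gene_class
    hits <- c(hits, mean(names(cls)[cls == "cancer_de"] %in% cs$genes))
    fps <- c(fps, mean(names(cls)[cls == "tissue_de"] %in% cs$genes))
  }
  expect_gte(mean(hits), 0.9)
  expect_lte(mean(fps), 0.05)
})
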