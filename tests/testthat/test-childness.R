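test_that("up/down counts match path enumeration on the toy chain and diamond", {
  ch <- chain_dag()
  expect_equal(max_deg_count_up(ch, "D", c("A", "C")), 2L)
  expect_equal(max_deg_count_up(ch, "A", c("B", "C", "D")), 0L) # root: no ancestors
  expect_equal(max_deg_count_down(ch, "A", c("A", "C")), 1L)    # self excluded
  expect_equal(max_deg_count_down(ch, "D", c("A", "C")), 0L)    # leaf
  expect_equal(max_deg_count_down(ch, "B", c("C", "D")), 2L)

  di <- diamond_dag()
  expect_equal(max_deg_count_up(di, "D", "B"), 1L)
  expect_error(max_deg_count_up(ch, "zz", "A"), "unknown term")
})

test_that("count_self adds the query term's own reference status", {
  ch <- chain_dag()
  expect_equal(max_deg_count_up(ch, "C", c("A", "C")), 1L)
  expect_equal(max_deg_count_up(ch, "C", c("A", "C"), count_self = TRUE), 2L)
})

test_that("term childness reproduces the worked chain scores", {
  ch <- chain_dag()
  deg <- c("A", "C")
  expect_equal(term_childness(ch, "B", deg), 0.5)  # 1 / (1 + 1)
  expect_equal(term_childness(ch, "D", deg), 1.0)  # 2 / (2 + 0)
  # a term with no reference relative in either direction scores 0
  dag2 <- ontology_dag(c("A", "B", "C", "D", "Z"),
                       edges = data.frame(child = c("B", "C", "D", "A"),
                                          parent = c("A", "B", "C", "Z"),
                                          relation = "is_a"))
  expect_equal(term_childness(dag2, "Z", deg), 0)
  expect_warning(p <- term_childness(ch, "B", character(0)), "empty reference")
  expect_equal(p, 0)
})

test_that("term-set childness is the mean of member scores", {
  ch <- chain_dag()
  deg <- c("A", "C")
  expect_equal(term_set_childness(ch, c("B", "D"), deg), 0.75)
  expect_equal(term_set_childness(ch, "D", deg), 1.0)
  expect_error(term_set_childness(ch, character(0), deg), "empty term set")
})

test_that("gene childness is the max over annotated terms", {
  ch <- chain_dag()
  deg <- c("A", "C")
  an <- propagate_annotations(ch, term_annotation(list(g1 = c("B", "D"), g2 = "A", g3 = "B")))
  # propagation adds ancestors; D still scores 1.0 and dominates
  expect_equal(gene_childness(ch, an, "g1", deg), 1.0)
  expect_equal(gene_childness(ch, an, "g2", deg), 0)   # root only
  expect_equal(gene_childness(ch, an, "g3", deg),
               max(term_childness(ch, "B", deg), term_childness(ch, "A", deg)))
  expect_warning(s <- gene_childness(ch, an, "missing", deg), "no annotated terms")
  expect_equal(s, 0)
})

test_that("functional selection uses a strict threshold", {
  sc <- c(b1 = 0.7, b2 = 0.5, b3 = 0.6)
  expect_equal(select_functional_biclusters(sc), "b1")
  expect_equal(select_functional_biclusters(c(x = 0.1, y = 0.2)), character(0))
})

test_that("group comparison is a two-sided Wilcoxon rank-sum test", {
  expect_equal(compare_childness_groups(c(1, 2, 3), c(4, 5, 6)), 0.1)
  expect_equal(compare_childness_groups(c(1, 2), c(1, 2)), 1.0)
  expect_equal(compare_childness_groups(0, 1), 1.0)
  expect_error(compare_childness_groups(numeric(0), 1), "nonempty")
})

test_that("DP up/down counts equal exhaustive path enumeration on random DAGs", {
  set.seed(402)
  for (i in 1:200) {
    dag <- random_dag(12)
    deg <- sample(dag$terms, sample(0:length(dag$terms), 1))
    t <- sample(dag$terms, 1)
    expect_equal(max_deg_count_up(dag, t, deg), updown_oracle(dag, t, deg, "up"))
    expect_equal(max_deg_count_down(dag, t, deg), updown_oracle(dag, t, deg, "down"))
  }
})

test_that("childness is bounded and characterized by its up/down counts", {
  set.seed(403)
  for (i in 1:100) {
    dag <- random_dag(12)
    deg <- sample(dag$terms, sample(1:length(dag$terms), 1))
    for (t in sample(dag$terms, min(4, length(dag$terms)))) {
      s <- term_childness(dag, t, deg)
      up <- max_deg_count_up(dag, t, deg)
      down <- max_deg_count_down(dag, t, deg)
      expect_gte(s, 0); expect_lte(s, 1)
      expect_equal(s == 1, up > 0 && down == 0)
      expect_equal(s == 0, up == 0)
    }
  }
})

test_that("adding a reference ancestor never lowers, a descendant never raises, childness", {
  set.seed(404)
  for (i in 1:100) {
    dag <- random_dag(12)
    deg <- sample(dag$terms, sample(1:max(1, length(dag$terms) %/% 2), 1))
    t <- sample(dag$terms, 1)
    base <- term_childness(dag, t, deg)
    anc <- setdiff(ancestors(dag, t), deg)
    if (length(anc)) {
      expect_gte(term_childness(dag, t, c(deg, sample(anc, 1))), base)
    }
    des <- setdiff(descendants(dag, t), deg)
    if (length(des)) {
      expect_lte(term_childness(dag, t, c(deg, sample(des, 1))), base)
    }
  }
})

test_that("childness_report tabulates terms for export", {
  ch <- chain_dag()
  rp <- childness_report(ch, c("B", "D"), c("A", "C"))
  expect_equal(rp$childness, c(0.5, 1.0))
  expect_equal(rp$up, c(1L, 2L))
  expect_equal(rp$down, c(1L, 0L))
})
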