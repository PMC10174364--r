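# Shared fixtures and independent brute-force oracles.

# ---- toy DAG builders -------------------------------------------------------

# chain D -> C -> B -> A (is_a, child -> parent)
chain_dag <- function() {
  ontology_dag(c("A", "B", "C", "D"),
               edges = data.frame(child = c("B", "C", "D"),
                                  parent = c("A", "B", "C"),
                                  relation = "is_a"))
}

# diamond D -> {B, C}, B -> A, C -> A
diamond_dag <- function() {
  ontology_dag(c("A", "B", "C", "D"),
               edges = data.frame(child = c("D", "D", "B", "C"),
                                  parent = c("B", "C", "A", "A"),
                                  relation = "is_a"))
}

# random DAG over n terms: edges only from higher to lower index, so acyclic
# by construction; a fraction of edges is of the regulates family to check
# that closures ignore them.
random_dag <- function(n_max = 15, p_edge = 0.3, with_regulates = FALSE) {
  n <- sample(2:n_max, 1)
  terms <- paste0("t", seq_len(n))
  ch <- character(0); pa <- character(0); rel <- character(0)
  for (j in 2:n) {
    for (i in 1:(j - 1)) {
      if (stats::runif(1) < p_edge) {
        ch <- c(ch, terms[j]); pa <- c(pa, terms[i])
        kinds <- if (with_regulates) c("is_a", "part_of", "regulates") else c("is_a", "part_of")
        rel <- c(rel, sample(kinds, 1))
      }
    }
  }
  ontology_dag(terms, edges = data.frame(child = ch, parent = pa, relation = rel,
                                         stringsAsFactors = FALSE))
}

# ---- brute-force reachability / path oracles --------------------------------

.oracle_adj <- function(dag, relations) {
  n <- length(dag$terms)
  A <- matrix(FALSE, n, n, dimnames = list(dag$terms, dag$terms))
  e <- dag$edges[dag$edges$relation %in% relations, , drop = FALSE]
  if (nrow(e)) A[cbind(e$child, e$parent)] <- TRUE
  A
}

# transitive closure by iterated boolean matrix product
closure_oracle <- function(dag, relations = c("is_a", "part_of")) {
  A <- .oracle_adj(dag, relations)
  R <- A
  repeat {
    R2 <- R | ((R %*% A) > 0)
    if (identical(R2, R)) break
    R <- R2
  }
  R # R[x, y] TRUE iff y is a (strict) ancestor of x
}

# maximum number of deg terms on any directed path from `term`, excluding the
# term itself, by exhaustive DFS over all paths
updown_oracle <- function(dag, term, deg_terms, direction = c("up", "down"),
                          relations = c("is_a", "part_of")) {
  direction <- match.arg(direction)
  A <- .oracle_adj(dag, relations)
  if (direction == "down") A <- t(A)
  best <- 0L
  recurse <- function(node, count) {
    best <<- max(best, count)
    for (nb in dag$terms[A[node, ]]) {
      recurse(nb, count + as.integer(nb %in% deg_terms))
    }
  }
  recurse(term, 0L)
  best
}

# ---- Fisher enumeration oracle ----------------------------------------------

# two-sided exact p by direct enumeration of margin-fixed tables with
# choose()-based probabilities (independent of dhyper)
fisher_oracle <- function(a, b, cc, d) {
  r1 <- a + b; r2 <- cc + d; c1 <- a + cc; n <- r1 + r2
  lo <- max(0, c1 - r2); hi <- min(c1, r1)
  xs <- lo:hi
  pr <- choose(r1, xs) * choose(r2, c1 - xs) / choose(n, c1)
  pobs <- pr[xs == a]
  min(1, sum(pr[pr <= pobs * (1 + 1e-12)]))
}

# ---- bicluster helpers -------------------------------------------------------

# Jaccard from explicit (gene, sample) pair sets: the oracle for the
# rectangles mode
pair_jaccard_oracle <- function(a, b) {
  pairs <- function(x) as.vector(outer(x$genes, x$samples, paste, sep = "\r"))
  pa <- pairs(a); pb <- pairs(b)
  length(intersect(pa, pb)) / length(union(pa, pb))
}

module_jaccard <- function(bic, genes, samples) {
  gi <- length(intersect(bic$genes, genes)); si <- length(intersect(bic$samples, samples))
  gu <- length(union(bic$genes, genes)); su <- length(union(bic$samples, samples))
  (gi * si) / (gu * su)
}

best_module_match <- function(set, genes, samples) {
  best <- 0; bid <- NA_character_
  for (b in set$biclusters) {
    j <- module_jaccard(b, genes, samples)
    if (j > best) { best <- j; bid <- b$id }
  }
  list(jaccard = best, id = bid)
}

# planted high-SNR ISA example matrix: 50x40 standard normal with a 10x8
# block raised by +5
planted_block_matrix <- function(seed = 42) {
  set.seed(seed)
  E <- matrix(stats::rnorm(50 * 40), 50, 40,
              dimnames = list(paste0("g", 1:50), paste0("s", 1:40)))
  E[1:10, 1:8] <- E[1:10, 1:8] + 5
  E
}

# small sample table for selection / survival tests
toy_sample_table <- function(n_colon_t = 3, n_endo_t = 3, n_colon_n = 0, n_endo_n = 0) {
  df <- data.frame(
    sample = c(sprintf("ct%02d", seq_len(n_colon_t)), sprintf("et%02d", seq_len(n_endo_t)),
               sprintf("cn%02d", seq_len(n_colon_n)), sprintf("en%02d", seq_len(n_endo_n))),
    tissue = c(rep("colon", n_colon_t), rep("endometrium", n_endo_t),
               rep("colon", n_colon_n), rep("endometrium", n_endo_n)),
    condition = c(rep("tumor", n_colon_t + n_endo_t), rep("normal", n_colon_n + n_endo_n)),
    stringsAsFactors = FALSE
  )
  sample_table(df)
}
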