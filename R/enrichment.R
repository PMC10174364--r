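# GO biological-process over-representation testing for gene sets
# (in-repo replacement for an external annotation service, with BH
# correction in place of its proprietary multiple-testing method).

#' Hypergeometric upper-tail probability
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: drawing `n` genes from a
#' universe of `N` of which `K` carry the term.
#'
#' @param k observed overlap (query genes carrying the term).
#' @param K background genes carrying the term.
#' @param n query size.
#' @param N background size.
#' @return Exact upper-tail probability.
#' @export
hypergeom_upper_tail <- function(k, K, n, N) {
  if (any(c(k, K, n, N) < 0) || k > min(K, n) || K > N || n > N) {
    stop("inconsistent hypergeometric arguments: k=", k, " K=", K, " n=", n, " N=", N)
  }
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' GO BP over-representation test for a gene set
#'
#' One hypergeometric upper-tail test per term whose background annotation
#' count lies in `[min_term, max_term]`, with BH adjustment within that
#' family. The universe is restricted to background genes that carry at least
#' one propagated annotation; query genes must be a subset of the background.
#'
#' @param query a [gene_set()] or character vector of gene ids.
#' @param background a [gene_set()] or character vector (the gene universe).
#' @param annot a propagated [term_annotation()].
#' @param dag an [ontology_dag()]; only its terms are tested.
#' @param alpha adjusted-p threshold flagging a term as enriched.
#' @param min_term,max_term background-count bounds for testable terms.
#' @return An `enrichment_table` data.frame: `term`, `name`, `k`, `K`, `n`,
#'   `N`, `pvalue`, `padj`, `enriched`, ordered by p-value.
#' @export
enrich_gene_set <- function(query, background, annot, dag,
                            alpha = 0.05, min_term = 3, max_term = 2000) {
  if (inherits(query, "gene_set")) query <- query$genes
  if (inherits(background, "gene_set")) background <- background$genes
  if (length(query) == 0) stop("empty query gene set")
  out_of_bg <- setdiff(query, background)
  if (length(out_of_bg)) {
    stop("query gene(s) missing from background: ", paste(utils::head(out_of_bg, 3), collapse = ", "))
  }
  stopifnot(inherits(annot, "term_annotation"))
  if (!isTRUE(annot$propagated)) {
    annot <- propagate_annotations(dag, annot)
  }
  bg <- intersect(background, names(annot$map))
  bg <- bg[lengths(annot$map[bg]) > 0]
  q <- intersect(query, bg)
  N <- length(bg); n <- length(q)
  if (n == 0) stop("no query gene carries an annotation")
  term_genes <- split(rep(bg, lengths(annot$map[bg])),
                      unlist(annot$map[bg], use.names = FALSE))
  term_genes <- term_genes[names(term_genes) %in% dag$terms]
  Kv <- lengths(term_genes)
  keep <- Kv >= min_term & Kv <= max_term
  term_genes <- term_genes[keep]; Kv <- Kv[keep]
  if (length(term_genes) == 0) {
    res <- data.frame(term = character(), name = character(), k = integer(),
                      K = integer(), n = integer(), N = integer(),
                      pvalue = numeric(), padj = numeric(), enriched = logical())
    class(res) <- c("enrichment_table", "data.frame")
    return(res)
  }
  kv <- vapply(term_genes, function(g) length(intersect(g, q)), integer(1))
  pv <- mapply(hypergeom_upper_tail, k = kv, K = Kv,
               MoreArgs = list(n = n, N = N))
  res <- data.frame(
    term = names(term_genes),
    name = unname(dag$name[names(term_genes)]),
    k = unname(kv), K = unname(Kv), n = n, N = N,
    pvalue = unname(pv),
    padj = bh_adjust(unname(pv)),
    row.names = NULL
  )
  res$enriched <- res$padj < alpha
  res <- res[order(res$pvalue, res$term), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("enrichment_table", "data.frame")
  res
}
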