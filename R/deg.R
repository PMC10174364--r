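# Differential expression between two sample groups: median-of-ratios size
# factors, a negative-binomial Wald test with gene-wise method-of-moments
# dispersion (a deliberately simple stand-in for the full shrinkage machinery
# of dedicated DE packages, with the same downstream thresholds), and the
# normal-DEG exclusion that yields cancer-specific DEGs.

#' Median-of-ratios size factors
#'
#' For genes with nonzero counts in every sample, each sample's factor is the
#' median ratio of its counts to the gene-wise geometric means. Factors are
#' reported as computed, with no rescaling.
#'
#' @param counts integer matrix, genes x samples.
#' @param pseudo_reference if no gene is expressed in all samples, fall back
#'   to a pseudo-reference computed from `log(count + 0.5)`; off by default.
#' @return Named numeric vector of positive per-sample factors.
#' @export
size_factors <- function(counts, pseudo_reference = FALSE) {
  all_pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(all_pos)) {
    if (!pseudo_reference) {
      stop("no gene has nonzero counts in all samples; ",
           "set pseudo_reference = TRUE to use a pseudo-reference gene")
    }
    loggeo <- rowMeans(log(counts + 0.5))
    ratios <- log(counts + 0.5) - loggeo
    return(exp(apply(ratios, 2, stats::median)))
  }
  sub <- counts[all_pos, , drop = FALSE]
  loggeo <- rowMeans(log(sub))
  ratios <- log(sub) - loggeo
  exp(apply(ratios, 2, stats::median))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate values, capped at 1. Input values must lie in
#' \eqn{[0, 1]}.
#'
#' @param pvals numeric vector of raw p-values.
#' @return Adjusted p-values in input order.
#' @export
bh_adjust <- function(pvals) {
  ok <- !is.na(pvals)
  if (any(pvals[ok] < 0 | pvals[ok] > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

#' Negative-binomial Wald test between two groups
#'
#' Counts are normalized by size factors; per gene, the dispersion is
#' estimated by pooled within-group method of moments (floored at 1e-8), the
#' fold change is `log2((meanA + 0.5) / (meanB + 0.5))` on normalized means,
#' and the Wald p-value comes from the delta-method standard error of the
#' log fold change under the NB variance `mu + alpha mu^2`. Genes with
#' all-zero counts in both groups are excluded and counted in the
#' `n_excluded` attribute. No dispersion or fold-change shrinkage is applied.
#'
#' @param counts integer matrix, genes x samples, with dimnames.
#' @param group_a,group_b disjoint character vectors of sample ids, each of
#'   size at least 2. The fold change is A over B.
#' @param sf optional precomputed size factors for all samples of `counts`.
#' @return A `deg_table` data.frame: `gene`, `baseMean`, `log2FC`, `pvalue`,
#'   `padj`, `direction`.
#' @export
nb_deg_test <- function(counts, group_a, group_b, sf = NULL) {
  if (length(intersect(group_a, group_b))) stop("groups overlap")
  if (length(group_a) < 2 || length(group_b) < 2) stop("each group needs at least 2 samples")
  miss <- setdiff(c(group_a, group_b), colnames(counts))
  if (length(miss)) stop("unknown sample id: ", paste(miss, collapse = ", "))
  if (is.null(sf)) {
    sf <- size_factors(counts[, c(group_a, group_b), drop = FALSE], pseudo_reference = TRUE)
  } else {
    if (is.null(names(sf))) {
      stopifnot(length(sf) == ncol(counts))
      names(sf) <- colnames(counts)
    }
  }
  sf <- sf[c(group_a, group_b)]
  if (anyNA(sf)) stop("size factors missing for some samples")
  sub <- counts[, c(group_a, group_b), drop = FALSE]
  zero <- rowSums(sub) == 0
  excluded <- rownames(sub)[zero]
  sub <- sub[!zero, , drop = FALSE]
  norm <- sweep(sub, 2, sf, "/")
  ia <- seq_along(group_a)
  ib <- length(group_a) + seq_along(group_b)
  A <- norm[, ia, drop = FALSE]; B <- norm[, ib, drop = FALSE]
  nA <- length(ia); nB <- length(ib)
  mA <- rowMeans(A); mB <- rowMeans(B)
  vA <- apply(A, 1, stats::var); vB <- apply(B, 1, stats::var)
  vpool <- ((nA - 1) * vA + (nB - 1) * vB) / (nA + nB - 2)
  mpool <- (mA * nA + mB * nB) / (nA + nB)
  disp <- pmax((vpool - mpool) / mpool^2, 1e-8)
  lfc <- log2((mA + 0.5) / (mB + 0.5))
  varA <- (mA * mean(1 / sf[ia]) + disp * mA^2) / nA
  varB <- (mB * mean(1 / sf[ib]) + disp * mB^2) / nB
  se2 <- (varA / (mA + 0.5)^2 + varB / (mB + 0.5)^2) / log(2)^2
  z <- lfc / sqrt(se2)
  p <- 2 * stats::pnorm(-abs(z))
  out <- data.frame(
    gene = rownames(sub),
    baseMean = (mA * nA + mB * nB) / (nA + nB),
    log2FC = lfc,
    pvalue = p,
    padj = bh_adjust(p),
    direction = ifelse(lfc >= 0, "up", "down"),
    row.names = NULL
  )
  class(out) <- c("deg_table", "data.frame")
  attr(out, "n_excluded") <- length(excluded)
  attr(out, "excluded") <- excluded
  out
}

#' Labelled gene set
#'
#' @param label a short label.
#' @param genes character vector of gene ids.
#' @return An object of class `gene_set`.
#' @export
gene_set <- function(label, genes) {
  structure(list(label = label, genes = unique(as.character(genes))),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat("gene_set '", x$label, "': ", length(x$genes), " genes\n", sep = "")
  invisible(x)
}

#' Threshold a DEG table
#'
#' Genes with adjusted p strictly below `alpha` and absolute log2 fold change
#' strictly above `min_abs_lfc`.
#'
#' @param table a `deg_table` from [nb_deg_test()].
#' @param alpha adjusted-p threshold (default 0.001).
#' @param min_abs_lfc absolute log2 fold-change threshold (default 1).
#' @param label label for the resulting set.
#' @return A [gene_set()].
#' @export
select_degs <- function(table, alpha = 0.001, min_abs_lfc = 1, label = "degs") {
  keep <- table$padj < alpha & abs(table$log2FC) > min_abs_lfc
  gene_set(label, table$gene[keep])
}

#' Cancer-specific DEGs by normal-DEG exclusion
#'
#' Set difference of the tumor-contrast DEGs and the normal-contrast DEGs,
#' with the Venn counts (tumor, normal, intersection, result) attached as the
#' `venn` attribute.
#'
#' @param tumor_degs,normal_degs [gene_set()]s over the same gene universe.
#' @return A [gene_set()] of cancer-specific genes.
#' @export
cancer_specific_degs <- function(tumor_degs, normal_degs) {
  stopifnot(inherits(tumor_degs, "gene_set"), inherits(normal_degs, "gene_set"))
  inter <- intersect(tumor_degs$genes, normal_degs$genes)
  res <- gene_set("cancer_specific", setdiff(tumor_degs$genes, normal_degs$genes))
  attr(res, "venn") <- c(tumor = length(tumor_degs$genes),
                         normal = length(normal_degs$genes),
                         intersection = length(inter),
                         result = length(res$genes))
  res
}
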