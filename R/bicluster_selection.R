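# Cancer-specific bicluster selection: Fisher exact enrichment of the
# bicluster's sample composition for one tumor class, BH correction over the
# whole family of bicluster x class tests, and the q < 0.001 / OR > 1 rule.

#' Two-sided Fisher exact test on a 2x2 table
#'
#' The two-sided p-value is the sum of probabilities of all tables with the
#' observed margins whose hypergeometric probability does not exceed that of
#' the observed table (with a relative slack of 1e-12 for floating-point
#' ties). The odds ratio is the sample cross-product `ad/bc`, reported as
#' `Inf` when `bc = 0`; the Haldane-Anscombe-corrected value
#' (0.5 added to each cell) is reported alongside.
#'
#' @param tbl 2x2 matrix of nonnegative integers, or a length-4 vector
#'   `(a, b, c, d)` read row-wise.
#' @return A list with `p`, `odds_ratio`, `odds_ratio_ha`.
#' @export
fisher_exact_2x2 <- function(tbl) {
  x <- as.integer(tbl)
  if (length(x) != 4) stop("need a 2x2 table")
  if (any(x < 0)) stop("negative cell count")
  a <- x[1]; b <- x[2]; cc <- x[3]; d <- x[4]
  r1 <- a + b; r2 <- cc + d; c1 <- a + cc
  lo <- max(0L, c1 - r2); hi <- min(c1, r1)
  support <- lo:hi
  probs <- stats::dhyper(support, r1, r2, c1)
  p_obs <- probs[support == a]
  p <- sum(probs[probs <= p_obs * (1 + 1e-12)])
  p <- min(p, 1)
  or <- if (b * cc == 0) {
    if (a * d == 0) NaN else Inf
  } else {
    (a * d) / (b * cc)
  }
  or_ha <- ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (cc + 0.5))
  list(p = p, odds_ratio = or, odds_ratio_ha = or_ha)
}

.target_samples <- function(samples, target_class) {
  target_class <- match.arg(target_class, .tissue_levels)
  samples$sample[samples$condition == "tumor" & samples$tissue == target_class]
}

#' Test a bicluster's enrichment for one cancer class
#'
#' Builds the 2x2 table of bicluster membership against target-class
#' membership over all cohort samples (normals included in the "other"
#' margin) and applies [fisher_exact_2x2()].
#'
#' @param bic a [bicluster()].
#' @param samples a [sample_table()] covering all cohort samples.
#' @param target_class `"colon"` or `"endometrium"` (the MSI tumor class).
#' @return A one-row data.frame: `bicluster`, `class`, `a`, `b`, `c`, `d`,
#'   `p`, `odds_ratio`.
#' @export
cancer_enrichment_test <- function(bic, samples, target_class) {
  unknown <- setdiff(bic$samples, samples$sample)
  if (length(unknown)) stop("bicluster sample not in cohort: ", unknown[1])
  tgt <- .target_samples(samples, target_class)
  inb <- samples$sample %in% bic$samples
  int <- samples$sample %in% tgt
  a <- sum(inb & int); b <- sum(inb & !int)
  cc <- sum(!inb & int); d <- sum(!inb & !int)
  ft <- fisher_exact_2x2(c(a, b, cc, d))
  data.frame(bicluster = bic$id, class = target_class,
             a = a, b = b, c = cc, d = d,
             p = ft$p, odds_ratio = ft$odds_ratio)
}

#' Select cancer-specific biclusters
#'
#' Every bicluster is tested against both tumor classes; q-values are BH over
#' the full family of `2 * |set|` tests. A bicluster is cancer-specific when,
#' for at least one class, `q < q_threshold` and the odds ratio exceeds 1; it
#' is labelled with the class of the smaller q (ties broken toward colon).
#'
#' @param set a [bicluster_set()].
#' @param samples a [sample_table()].
#' @param q_threshold strict q-value threshold (default 0.001).
#' @return A [bicluster_set()] of the selected biclusters, each carrying an
#'   `enriched_class` field; the full test table (with q-values and selection
#'   flags) is attached as the `tests` attribute.
#' @export
select_cancer_specific <- function(set, samples, q_threshold = 0.001) {
  stopifnot(inherits(set, "bicluster_set"))
  if (length(set$biclusters) == 0) {
    out <- bicluster_set(list(), source = set$source)
    attr(out, "tests") <- data.frame()
    return(out)
  }
  tests <- do.call(rbind, unlist(lapply(set$biclusters, function(b) {
    lapply(.tissue_levels, function(cl) cancer_enrichment_test(b, samples, cl))
  }), recursive = FALSE))
  tests$q <- bh_adjust(tests$p)
  tests$selected <- tests$q < q_threshold & tests$odds_ratio > 1
  sel <- list()
  for (b in set$biclusters) {
    rows <- tests[tests$bicluster == b$id & tests$selected, , drop = FALSE]
    if (nrow(rows) == 0) next
    rows <- rows[order(rows$q, match(rows$class, .tissue_levels)), , drop = FALSE]
    b$enriched_class <- rows$class[1]
    sel[[length(sel) + 1]] <- b
  }
  out <- bicluster_set(sel, source = set$source)
  attr(out, "tests") <- tests
  out
}
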