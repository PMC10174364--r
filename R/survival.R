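# Survival screening of biclusters: PCA-based two-group stratification of all
# tumor samples of the bicluster's enriched class, Kaplan-Meier estimation
# and the two-group log-rank test. KM and log-rank are computed with the
# survival package; a permutation p-value is available as an independent
# alternative to the chi-square reference distribution.

#' Stratify samples into two groups by PCA
#'
#' PCA on gene-standardized expression (samples as observations). Methods:
#' `"pc1-median"` / `"pc2-median"` split at the median of the given component
#' (values equal to the median go to the `"low"` group); `"kmeans2"` runs
#' k-means with k = 2 on the first two components (10 restarts, seeded), with
#' the cluster containing the lowest-PC1 sample labelled `"low"`.
#'
#' @param expr real matrix of bicluster genes x cohort samples (>= 2 genes,
#'   >= 4 samples).
#' @param method stratification method.
#' @param seed RNG seed for k-means.
#' @return Named character vector of `"low"`/`"high"` labels per sample.
#' @export
pca_stratify <- function(expr, method = c("pc1-median", "pc2-median", "kmeans2"),
                         seed = 1) {
  method <- match.arg(method)
  if (ncol(expr) < 4) stop("need at least 4 samples to stratify")
  if (nrow(expr) < 2) stop("need at least 2 genes")
  sds <- apply(expr, 1, stats::sd)
  if (all(sds < 1e-12)) stop("constant expression matrix; cannot stratify")
  xs <- (expr[sds > 1e-12, , drop = FALSE] - rowMeans(expr[sds > 1e-12, , drop = FALSE])) /
    sds[sds > 1e-12]
  pc <- stats::prcomp(t(xs), center = TRUE, scale. = FALSE)
  scores <- pc$x
  if (method == "pc1-median" || method == "pc2-median") {
    j <- if (method == "pc1-median") 1 else 2
    if (ncol(scores) < j) stop("not enough principal components for ", method)
    v <- scores[, j]
    lab <- ifelse(v <= stats::median(v), "low", "high")
  } else {
    sc2 <- scores[, seq_len(min(2, ncol(scores))), drop = FALSE]
    km <- .with_seed(seed, stats::kmeans(sc2, centers = 2, nstart = 10))
    low_cluster <- km$cluster[which.min(scores[, 1])]
    lab <- ifelse(km$cluster == low_cluster, "low", "high")
  }
  stats::setNames(lab, colnames(expr))
}

#' Kaplan-Meier survival curve
#'
#' Product-limit estimate; censored times reduce the risk set without steps.
#'
#' @param times nonnegative event/censoring times.
#' @param events 0/1 event indicators (1 = death).
#' @return data.frame with `time`, `n_risk`, `n_event`, `survival`, one row
#'   per distinct time.
#' @export
km_curve <- function(times, events) {
  if (length(times) != length(events)) stop("times and events differ in length")
  if (any(!is.finite(times)) || any(times < 0)) stop("times must be finite and nonnegative")
  if (!all(events %in% c(0, 1))) stop("events must be 0/1")
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  data.frame(time = fit$time, n_risk = fit$n.risk,
             n_event = fit$n.event, survival = fit$surv)
}

#' Two-group log-rank test
#'
#' Standard log-rank statistic with hypergeometric variance; the p-value uses
#' the chi-square distribution with 1 df, or a label-permutation reference
#' when `method = "permutation"`. With no events at all the statistic is 0
#' and p = 1.
#'
#' @param times,events as in [km_curve()].
#' @param labels two-level group labels.
#' @param method `"chisq"` or `"permutation"`.
#' @param n_perm number of permutations.
#' @param seed RNG seed for the permutation reference.
#' @return List with `statistic` and `p`.
#' @export
logrank_test <- function(times, events, labels, method = c("chisq", "permutation"),
                         n_perm = 2000, seed = 1) {
  method <- match.arg(method)
  labels <- as.character(labels)
  lv <- unique(labels)
  if (length(lv) != 2 || any(table(labels) == 0)) {
    stop("labels must define two nonempty groups")
  }
  if (sum(events) == 0) return(list(statistic = 0, p = 1))
  chi <- function(lab) {
    sd <- survival::survdiff(survival::Surv(times, events) ~ lab)
    unname(sd$chisq)
  }
  statistic <- chi(labels)
  if (method == "chisq") {
    p <- stats::pchisq(statistic, df = 1, lower.tail = FALSE)
  } else {
    ref <- .with_seed(seed, vapply(seq_len(n_perm), function(i) chi(sample(labels)),
                                   numeric(1)))
    p <- (1 + sum(ref >= statistic - 1e-12)) / (1 + n_perm)
  }
  list(statistic = statistic, p = p)
}

#' Survival screen of one bicluster
#'
#' Restricts expression to the bicluster's genes and to all tumor samples of
#' its enriched cancer class (not only bicluster samples), stratifies them by
#' each of the three PCA methods, and log-rank-tests overall survival for
#' each stratification. The bicluster is flagged significant when any method
#' yields p below `alpha`; all three p-values are reported so other rules can
#' be applied downstream.
#'
#' @param bic a [bicluster()], with an `enriched_class` field or `cohort`
#'   given explicitly.
#' @param matrix real expression matrix (e.g. the log2-normalized layer),
#'   genes x samples.
#' @param samples a [sample_table()] with `os_time` and `os_event`.
#' @param alpha per-method significance level.
#' @param cohort `"colon"` or `"endometrium"`; defaults to the bicluster's
#'   enriched class.
#' @param seed RNG seed (k-means).
#' @return A `survival_result` list: `bicluster`, `cohort`, per-method
#'   p-values, `best_method`, `significant`, group labels and KM curves for
#'   the best method.
#' @export
bicluster_survival_screen <- function(bic, matrix, samples, alpha = 0.05,
                                      cohort = NULL, seed = 1) {
  if (is.null(cohort)) cohort <- bic$enriched_class
  if (is.null(cohort)) stop("bicluster has no enriched class and no cohort was given")
  if (!all(c("os_time", "os_event") %in% names(samples))) {
    stop("sample table lacks survival columns os_time/os_event")
  }
  missing_genes <- setdiff(bic$genes, rownames(matrix))
  if (length(missing_genes)) {
    stop("bicluster gene(s) absent from matrix: ", paste(utils::head(missing_genes, 3), collapse = ", "))
  }
  coh <- samples[samples$condition == "tumor" & samples$tissue == cohort, , drop = FALSE]
  coh <- coh[!is.na(coh$os_time) & !is.na(coh$os_event), , drop = FALSE]
  coh <- coh[coh$sample %in% colnames(matrix), , drop = FALSE]
  if (nrow(coh) < 4) stop("cohort ", cohort, " has fewer than 4 tumor samples with survival data")
  expr <- matrix[bic$genes, coh$sample, drop = FALSE]
  methods <- c("pc1-median", "pc2-median", "kmeans2")
  res <- lapply(methods, function(m) {
    lab <- pca_stratify(expr, m, seed = seed)
    if (length(unique(lab)) < 2) return(list(statistic = 0, p = 1, labels = lab))
    lr <- logrank_test(coh$os_time, coh$os_event, lab)
    c(lr, list(labels = lab))
  })
  names(res) <- methods
  pvals <- vapply(res, `[[`, numeric(1), "p")
  best <- methods[which.min(pvals)]
  best_lab <- res[[best]]$labels
  curves <- lapply(split(coh, best_lab), function(g) km_curve(g$os_time, g$os_event))
  structure(list(
    bicluster = bic$id, cohort = cohort,
    p_values = pvals, best_method = best,
    significant = any(pvals < alpha),
    labels = best_lab, km = curves
  ), class = "survival_result")
}

#' @export
print.survival_result <- function(x, ...) {
  cat("survival screen of ", x$bicluster, " (", x$cohort, " cohort): ",
      if (x$significant) "significant" else "not significant", "\n", sep = "")
  print(round(x$p_values, 4))
  invisible(x)
}
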