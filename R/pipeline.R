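# End-to-end workflow: DEG calling on the tumor and normal contrasts,
# normal-DEG exclusion, biclustering, Fisher-exact cancer-specific selection,
# per-bicluster GO enrichment, childness scoring and selection, and the
# PCA-stratified survival screen, orchestrated from a single config with one
# master seed.

#' Pipeline configuration
#'
#' Inputs are either file paths (`counts`, `samples`, `obo`, `annotation`) or
#' a `simulate` block (a [generator_config()]). All thresholds default to the
#' workflow's standard values: DEG adjusted p 0.001 and |log2FC| 1, bicluster
#' q 0.001, enrichment adjusted p 0.05, term-set childness 0.6, survival
#' alpha 0.05.
#'
#' @param counts,samples,obo,annotation input file paths (ignored when
#'   `simulate` is given).
#' @param simulate a [generator_config()], or `TRUE` for the default one.
#' @param deg_alpha,deg_lfc DEG thresholds.
#' @param bicluster_q cancer-specific selection q threshold.
#' @param enrich_alpha,min_term,max_term GO enrichment parameters.
#' @param childness_threshold strict term-set childness threshold.
#' @param survival_alpha per-method log-rank significance level.
#' @param algorithms biclustering algorithms to run (`"isa"`, `"plaid"`).
#' @param isa,plaid per-algorithm parameter lists (see [run_isa()],
#'   [run_plaid()]).
#' @param seed master seed; all stage seeds are fanned out from it.
#' @param out_dir optional directory for per-stage artifacts.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(counts = NULL, samples = NULL, obo = NULL, annotation = NULL,
                            simulate = NULL,
                            deg_alpha = 0.001, deg_lfc = 1,
                            bicluster_q = 0.001,
                            enrich_alpha = 0.05, min_term = 3, max_term = 2000,
                            childness_threshold = 0.6,
                            survival_alpha = 0.05,
                            algorithms = c("isa", "plaid"),
                            isa = list(), plaid = list(),
                            seed = 1, out_dir = NULL) {
  cfg <- as.list(environment())
  if (isTRUE(cfg$simulate)) cfg$simulate <- generator_config()
  probs <- c(deg_alpha = deg_alpha, bicluster_q = bicluster_q,
             enrich_alpha = enrich_alpha, childness_threshold = childness_threshold,
             survival_alpha = survival_alpha)
  bad <- probs < 0 | probs > 1
  if (any(bad)) {
    stop("threshold out of [0, 1]: ", paste(names(probs)[bad], collapse = ", "))
  }
  if (deg_lfc < 0) stop("deg_lfc must be nonnegative")
  unknown <- setdiff(algorithms, c("isa", "plaid"))
  if (length(unknown)) stop("unknown algorithm(s): ", paste(unknown, collapse = ", "))
  if (is.null(cfg$simulate)) {
    need <- c("counts", "samples", "obo", "annotation")
    miss <- need[vapply(cfg[need], is.null, logical(1))]
    if (length(miss)) {
      stop("either a simulate block or input paths are required; missing: ",
           paste(miss, collapse = ", "))
    }
  }
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Recognized keys mirror the arguments of [pipeline_config()]; a `simulate`
#' mapping is passed to [generator_config()].
#'
#' @param path YAML file path.
#' @return A [pipeline_config()].
#' @export
pipeline_config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$simulate) && is.list(y$simulate)) {
    sim <- y$simulate
    for (nm in c("group_sizes", "modules_per_class")) {
      if (!is.null(sim[[nm]])) sim[[nm]] <- unlist(sim[[nm]])
    }
    y$simulate <- do.call(generator_config, sim)
  }
  do.call(pipeline_config, y)
}

.fan_seed <- function(seed, k) {
  as.integer((as.numeric(seed) %% 100000) * 131 + k * 7919) %% 2147483647L
}

.group_ids <- function(samples, tissue, condition) {
  samples$sample[samples$tissue == tissue & samples$condition == condition]
}

#' Run the full workflow
#'
#' Executes, in order: DEG calling on the tumor contrast (colon vs
#' endometrium MSI tumors) and the normal contrast, normal-DEG exclusion,
#' normalization and biclustering, Fisher-exact cancer-specific selection, GO
#' BP enrichment of the cancer-specific DEG set (the childness reference) and
#' of every bicluster's gene set, term-set childness scoring and selection of
#' functionally relevant biclusters, a survival screen of the cancer-specific
#' biclusters, and a Wilcoxon comparison of childness between cancer-specific
#' and remaining biclusters. Deterministic given `config$seed`.
#'
#' @param config a [pipeline_config()].
#' @return A `funbic_report` object; see the package vignette.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  seed <- config$seed
  # --- inputs -------------------------------------------------------------
  if (!is.null(config$simulate)) {
    sim <- generate_cohort(config$simulate, seed = .fan_seed(seed, 1))
    counts <- sim$counts; samples <- sim$samples
    dag <- sim$ontology$dag; annot <- sim$ontology$annot
    truth <- sim$truth
  } else {
    counts <- read_counts(config$counts)
    samples <- read_sample_table(config$samples)
    dag <- parse_obo(config$obo)
    annot <- read_annotation_tsv(config$annotation)
    truth <- NULL
  }
  miss <- setdiff(samples$sample, colnames(counts))
  if (length(miss)) stop("sample table references samples absent from counts: ", miss[1])

  # --- DEG stage ----------------------------------------------------------
  sf <- size_factors(counts, pseudo_reference = TRUE)
  tumor_tab <- nb_deg_test(counts, .group_ids(samples, "colon", "tumor"),
                           .group_ids(samples, "endometrium", "tumor"), sf = sf)
  normal_tab <- nb_deg_test(counts, .group_ids(samples, "colon", "normal"),
                            .group_ids(samples, "endometrium", "normal"), sf = sf)
  tumor_degs <- select_degs(tumor_tab, config$deg_alpha, config$deg_lfc, label = "tumor")
  normal_degs <- select_degs(normal_tab, config$deg_alpha, config$deg_lfc, label = "normal")
  cs_degs <- cancer_specific_degs(tumor_degs, normal_degs)

  # --- biclustering -------------------------------------------------------
  norm <- normalize_for_biclustering(counts, sf)
  sets <- list()
  if ("isa" %in% config$algorithms) {
    isa_args <- utils::modifyList(
      list(matrix = norm, n_seeds = 200, init = "gene", seed = .fan_seed(seed, 2)),
      config$isa)
    sets$isa <- do.call(run_isa, isa_args)
  }
  if ("plaid" %in% config$algorithms) {
    plaid_args <- utils::modifyList(
      list(matrix = norm, seed = .fan_seed(seed, 3)), config$plaid)
    sets$plaid <- do.call(run_plaid, plaid_args)
  }
  all_bics <- combine_bicluster_sets(unname(sets))

  # --- cancer-specific selection -------------------------------------------
  cs_bics <- select_cancer_specific(all_bics, samples, config$bicluster_q)
  cs_ids <- vapply(cs_bics$biclusters, `[[`, "", "id")
  sel_tests <- attr(cs_bics, "tests")

  # --- enrichment & childness ----------------------------------------------
  annot <- propagate_annotations(dag, annot)
  background <- intersect(rownames(counts), names(annot$map)[lengths(annot$map) > 0])
  ref_terms <- character(0)
  deg_enrichment <- NULL
  cs_genes_in_bg <- intersect(cs_degs$genes, background)
  if (length(cs_genes_in_bg) > 0) {
    deg_enrichment <- enrich_gene_set(cs_genes_in_bg, background, annot, dag,
                                      alpha = config$enrich_alpha,
                                      min_term = config$min_term, max_term = config$max_term)
    ref_terms <- deg_enrichment$term[deg_enrichment$enriched]
  }
  score_bic <- function(b) {
    q <- intersect(b$genes, background)
    if (length(q) == 0) return(list(score = NA_real_, n_terms = 0L))
    et <- enrich_gene_set(q, background, annot, dag, alpha = config$enrich_alpha,
                          min_term = config$min_term, max_term = config$max_term)
    terms <- et$term[et$enriched]
    if (length(terms) == 0) return(list(score = NA_real_, n_terms = 0L))
    s <- if (length(ref_terms) == 0) 0
         else term_set_childness(dag, terms, ref_terms)
    list(score = s, n_terms = length(terms))
  }
  scored <- lapply(all_bics$biclusters, score_bic)
  childness_scores <- stats::setNames(vapply(scored, `[[`, numeric(1), "score"),
                                      vapply(all_bics$biclusters, `[[`, "", "id"))
  cs_scores <- childness_scores[cs_ids]
  functional_ids <- select_functional_biclusters(
    cs_scores[!is.na(cs_scores)], config$childness_threshold)

  # --- Wilcoxon comparison -------------------------------------------------
  grp_cs <- childness_scores[names(childness_scores) %in% cs_ids]
  grp_rest <- childness_scores[!names(childness_scores) %in% cs_ids]
  grp_cs <- grp_cs[!is.na(grp_cs)]; grp_rest <- grp_rest[!is.na(grp_rest)]
  wilcox_p <- if (length(grp_cs) && length(grp_rest)) {
    compare_childness_groups(grp_cs, grp_rest)
  } else NA_real_

  # --- survival screen -----------------------------------------------------
  lognorm <- log2(sweep(counts, 2, sf, "/") + 1)
  surv <- list()
  has_surv <- all(c("os_time", "os_event") %in% names(samples)) &&
    any(!is.na(samples$os_time))
  if (has_surv) {
    for (b in cs_bics$biclusters) {
      surv[[b$id]] <- tryCatch(
        bicluster_survival_screen(b, lognorm, samples, alpha = config$survival_alpha,
                                  seed = .fan_seed(seed, 4)),
        error = function(e) NULL)
    }
  }

  # --- per-bicluster records ----------------------------------------------
  records <- do.call(rbind, lapply(all_bics$biclusters, function(b) {
    st <- sel_tests[sel_tests$bicluster == b$id, , drop = FALSE]
    st <- st[order(st$q), , drop = FALSE]
    sv <- surv[[b$id]]
    data.frame(
      bicluster = b$id, algorithm = b$algorithm,
      n_genes = length(b$genes), n_samples = length(b$samples),
      cancer_specific = b$id %in% cs_ids,
      enriched_class = if (b$id %in% cs_ids) {
        vapply(cs_bics$biclusters[cs_ids == b$id], `[[`, "", "enriched_class")[1]
      } else NA_character_,
      q = st$q[1], odds_ratio = st$odds_ratio[1],
      childness = unname(childness_scores[b$id]),
      functional = b$id %in% functional_ids,
      surv_p_pc1 = if (!is.null(sv)) sv$p_values[["pc1-median"]] else NA_real_,
      surv_p_pc2 = if (!is.null(sv)) sv$p_values[["pc2-median"]] else NA_real_,
      surv_p_kmeans = if (!is.null(sv)) sv$p_values[["kmeans2"]] else NA_real_,
      surv_significant = if (!is.null(sv)) sv$significant else NA,
      stringsAsFactors = FALSE
    )
  }))

  report <- structure(list(
    counts = c(
      tumor_degs = length(tumor_degs$genes),
      normal_degs = length(normal_degs$genes),
      cancer_specific_degs = length(cs_degs$genes),
      biclusters = length(all_bics$biclusters),
      cancer_specific_biclusters = length(cs_bics$biclusters),
      functional_biclusters = length(functional_ids),
      survival_significant = sum(vapply(surv[functional_ids], function(s)
        isTRUE(s$significant), logical(1)))
    ),
    records = records,
    wilcox_p = wilcox_p,
    deg_venn = attr(cs_degs, "venn"),
    deg_tables = list(tumor = tumor_tab, normal = normal_tab),
    gene_sets = list(tumor = tumor_degs, normal = normal_degs, cancer_specific = cs_degs),
    biclusters = all_bics,
    cancer_specific = cs_bics,
    functional_ids = functional_ids,
    ref_terms = ref_terms,
    deg_enrichment = deg_enrichment,
    survival = surv,
    truth = truth,
    seed = seed,
    config = config
  ), class = "funbic_report")

  if (!is.null(config$out_dir)) .write_artifacts(report, config$out_dir)
  report
}

.write_artifacts <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, name) {
    utils::write.table(df, file.path(dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  wt(report$deg_tables$tumor, "deg_tumor.tsv")
  wt(report$deg_tables$normal, "deg_normal.tsv")
  wt(report$records, "bicluster_records.tsv")
  if (!is.null(report$deg_enrichment)) wt(report$deg_enrichment, "deg_enrichment.tsv")
  write_biclusters(report$biclusters, file.path(dir, "biclusters.json"))
  jsonlite::write_json(
    list(counts = as.list(report$counts), wilcox_p = report$wilcox_p,
         seed = report$seed),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @export
print.funbic_report <- function(x, ...) {
  cat("funbic pipeline report (seed ", x$seed, ")\n", sep = "")
  cat("  tumor DEGs:                 ", x$counts[["tumor_degs"]], "\n")
  cat("  normal DEGs:                ", x$counts[["normal_degs"]], "\n")
  cat("  cancer-specific DEGs:       ", x$counts[["cancer_specific_degs"]], "\n")
  cat("  biclusters:                 ", x$counts[["biclusters"]], "\n")
  cat("  cancer-specific biclusters: ", x$counts[["cancer_specific_biclusters"]], "\n")
  cat("  functionally relevant:      ", x$counts[["functional_biclusters"]], "\n")
  cat("  survival-significant:       ", x$counts[["survival_significant"]], "\n")
  cat("  childness Wilcoxon p:       ", format(x$wilcox_p, digits = 3), "\n")
  invisible(x)
}

#' @export
summary.funbic_report <- function(object, ...) {
  print(object)
  cat("\nper-bicluster records (cancer-specific first):\n")
  r <- object$records
  r <- r[order(-r$cancer_specific, r$q), , drop = FALSE]
  print(utils::head(r, 20), row.names = FALSE)
  invisible(object)
}
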