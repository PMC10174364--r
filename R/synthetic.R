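# Synthetic cohort generator. Emulates the statistical structure the
# pipeline assumes: two tissues x tumor/normal groups; tissue-specific DE
# genes shared by tumor and normal; cancer-specific DE genes confined to the
# tumors of one tissue; planted gene x sample expression modules enriched in
# one class; a toy GO DAG in which the planted cancer modules annotate to
# child terms of DEG-enriched terms while normal-tissue modules annotate to a
# disjoint decoy branch; and exponential survival whose hazard is multiplied
# for samples active in a cancer module.

#' Synthetic cohort configuration
#'
#' Defaults are sized for desk-scale runs: 2000 genes, 40 samples per group,
#' planted modules of 30 genes x 15 samples with a +2.5 log2 effect. The toy
#' ontology is a complete tree (depth 4, branching 3) with designated DEG
#' terms at level 2 of a signal branch, cancer-module terms as their level-3
#' children, and decoy branches for tissue biology; most null genes annotate
#' below the signal head so that, as in real GO, general ancestors are not
#' spuriously enriched in small module queries.
#'
#' @param n_genes total genes.
#' @param group_sizes named vector: samples per tissue x condition group.
#' @param base_mean,base_log2_sd lognormal baseline of NB means.
#' @param dispersion NB dispersion (variance `mu + dispersion * mu^2`).
#' @param n_tissue_de tissue-specific DE genes (shared by tumor and normal).
#' @param n_cancer_de cancer-specific DE genes (tumors of one tissue only).
#' @param tissue_lfc,cancer_lfc absolute log2 effects of those gene classes.
#' @param modules_per_class named vector: planted modules per sample group.
#' @param module_genes,module_samples module dimensions.
#' @param module_lfc log2 effect added on module cells.
#' @param module_core_frac fraction of each module's genes annotated directly
#'   to the module's term (the rest scatter to unrelated terms).
#' @param ontology_depth,ontology_branching toy-ontology shape.
#' @param baseline_hazard per-day exponential hazard of tumor samples.
#' @param hazard_multiplier hazard multiplier for cancer-module samples.
#' @param censor_horizon administrative censoring time (days).
#' @return A validated list of class `generator_config`.
#' @export
generator_config <- function(n_genes = 2000,
                             group_sizes = c(colon_normal = 40, colon_tumor = 40,
                                             endometrium_normal = 40, endometrium_tumor = 40),
                             base_mean = 100, base_log2_sd = 1,
                             dispersion = 0.1,
                             n_tissue_de = 200, n_cancer_de = 120,
                             tissue_lfc = 2, cancer_lfc = 2,
                             modules_per_class = c(colon_tumor = 2, endometrium_tumor = 2,
                                                   colon_normal = 2, endometrium_normal = 2),
                             module_genes = 30, module_samples = 15,
                             module_lfc = 2.5, module_core_frac = 0.5,
                             ontology_depth = 4, ontology_branching = 3,
                             baseline_hazard = 5e-4, hazard_multiplier = 4,
                             censor_horizon = 2000) {
  cfg <- as.list(environment())
  groups <- c("colon_normal", "colon_tumor", "endometrium_normal", "endometrium_tumor")
  if (!all(groups %in% names(cfg$group_sizes))) {
    stop("group_sizes must name all four tissue x condition groups")
  }
  if (any(cfg$group_sizes < 2)) stop("every group needs at least 2 samples")
  if (any(names(cfg$modules_per_class) %in% groups == FALSE)) {
    stop("modules_per_class names must be sample groups")
  }
  if (cfg$module_samples > min(cfg$group_sizes[names(cfg$modules_per_class)])) {
    stop("module_samples exceeds the size of a target group")
  }
  if (any(c(cfg$tissue_lfc, cfg$cancer_lfc, cfg$module_lfc) < 0)) {
    stop("effect sizes must be nonnegative")
  }
  if (cfg$ontology_depth < 3 || cfg$ontology_branching < 2) {
    stop("ontology needs depth >= 3 and branching >= 2")
  }
  n_module_genes <- sum(cfg$modules_per_class) * cfg$module_genes
  if (cfg$n_tissue_de + cfg$n_cancer_de + n_module_genes > cfg$n_genes) {
    stop("gene classes exceed n_genes")
  }
  structure(cfg, class = "generator_config")
}

# deterministic partition of gene ids into classes, shared by the ontology
# and cohort generators
.gene_layout <- function(cfg) {
  ids <- sprintf("g%04d", seq_len(cfg$n_genes))
  n_mod <- sum(cfg$modules_per_class) * cfg$module_genes
  cls <- rep("null", cfg$n_genes)
  cls[seq_len(cfg$n_tissue_de)] <- "tissue_de"
  cls[cfg$n_tissue_de + seq_len(cfg$n_cancer_de)] <- "cancer_de"
  cls[cfg$n_tissue_de + cfg$n_cancer_de + seq_len(n_mod)] <- "module"
  mod_classes <- rep(names(cfg$modules_per_class), cfg$modules_per_class)
  mod_start <- cfg$n_tissue_de + cfg$n_cancer_de
  modules <- lapply(seq_along(mod_classes), function(m) {
    list(id = paste0("module_", m),
         class = mod_classes[m],
         genes = ids[mod_start + (m - 1) * cfg$module_genes + seq_len(cfg$module_genes)])
  })
  list(ids = ids, class = cls, modules = modules,
       tissue_de = ids[cls == "tissue_de"],
       cancer_de = ids[cls == "cancer_de"],
       null = ids[cls == "null"])
}

#' Generate the toy ontology and gene annotation
#'
#' Builds a complete rooted tree of the configured depth and branching (edges
#' typed is_a with a sprinkling of part_of; both kinds participate in
#' closures). The root's first child heads the signal branch: its first
#' `branching - 1` children are the designated DEG terms and their level-3
#' children host the planted cancer modules. The second child heads the decoy
#' branch (tissue biology and normal-tissue modules). Remaining branches
#' absorb scattered annotations. Genes are annotated per their class in
#' [.gene_layout()]; most null genes annotate under the signal head's general
#' child so that general ancestors are background-diluted.
#'
#' @param config a [generator_config()].
#' @param seed RNG seed.
#' @return List with `dag` ([ontology_dag()]), `annot` (unpropagated
#'   [term_annotation()]), `deg_terms` (designated DEG term ids) and
#'   `module_terms` (named by module id).
#' @export
generate_ontology <- function(config, seed = 1) {
  cfg <- config
  b <- as.integer(cfg$ontology_branching); d <- as.integer(cfg$ontology_depth)
  n_terms <- as.integer((b^(d + 1) - 1) / (b - 1))
  ids <- sprintf("GO:SIM%04d", seq_len(n_terms))
  # level-order complete tree: children of node i are b*(i-1)+2 .. b*i+1
  parent_idx <- function(i) (i - 2L) %/% b + 1L
  level <- integer(n_terms); level[1] <- 0
  for (i in 2:n_terms) level[i] <- level[parent_idx(i)] + 1
  child_edges <- 2:n_terms
  rel <- ifelse(child_edges %% 4 == 0, "part_of", "is_a")
  edges <- data.frame(child = ids[child_edges],
                      parent = ids[vapply(child_edges, parent_idx, 1L)],
                      relation = rel, stringsAsFactors = FALSE)
  dag <- ontology_dag(ids,
                      name = stats::setNames(paste0("synthetic term ", seq_len(n_terms)), ids),
                      namespace = stats::setNames(rep("biological_process", n_terms), ids),
                      edges = edges)
  children_of <- function(i) (b * (i - 1) + 2):(b * i + 1)
  subtree_of <- function(i) {
    out <- i; frontier <- i
    while (length(frontier)) {
      frontier <- unlist(lapply(frontier, function(x) {
        ch <- children_of(x); ch[ch <= n_terms]
      }))
      out <- c(out, frontier)
    }
    out
  }
  heads <- children_of(1)          # level-1 heads
  sig <- heads[1]; dec <- heads[2]
  other <- if (b >= 3) heads[3:b] else dec
  sig_children <- children_of(sig) # level 2
  n_deg <- max(1, b - 1)
  deg_idx <- sig_children[seq_len(n_deg)]
  general_idx <- setdiff(sig_children, deg_idx)
  lay <- .gene_layout(cfg)
  cancer_mods <- Filter(function(m) grepl("tumor", m$class), lay$modules)
  normal_mods <- Filter(function(m) grepl("normal", m$class), lay$modules)
  cancer_slots <- unlist(lapply(deg_idx, children_of))   # level 3 under DEG terms
  if (length(cancer_mods) > length(cancer_slots)) {
    stop("ontology shape too small to place ", length(cancer_mods), " cancer modules")
  }
  dec_children <- children_of(dec)                        # level-2 decoys (tissue terms)
  normal_slots <- unlist(lapply(dec_children, children_of))
  if (length(normal_mods) > length(normal_slots)) {
    stop("ontology shape too small to place ", length(normal_mods), " normal modules")
  }
  module_terms <- character(0)
  for (k in seq_along(cancer_mods)) module_terms[cancer_mods[[k]]$id] <- ids[cancer_slots[k]]
  for (k in seq_along(normal_mods)) module_terms[normal_mods[[k]]$id] <- ids[normal_slots[k]]
  general_pool <- ids[setdiff(unlist(lapply(general_idx, subtree_of)), integer(0))]
  other_pool <- ids[unique(unlist(lapply(other, subtree_of)))]
  annot_map <- .with_seed(seed, {
    m <- stats::setNames(vector("list", cfg$n_genes), lay$ids)
    for (g in seq_along(lay$tissue_de)) {
      m[[lay$tissue_de[g]]] <- ids[dec_children[(g - 1) %% length(dec_children) + 1]]
    }
    for (g in seq_along(lay$cancer_de)) {
      m[[lay$cancer_de[g]]] <- ids[deg_idx[(g - 1) %% length(deg_idx) + 1]]
    }
    for (mod in lay$modules) {
      n_core <- round(cfg$module_core_frac * length(mod$genes))
      core <- mod$genes[seq_len(n_core)]
      rest <- setdiff(mod$genes, core)
      for (g in core) m[[g]] <- module_terms[[mod$id]]
      # scatter at most one non-core gene per decoy term so that no
      # off-module term can become enriched in the module's gene set
      scat <- sample(other_pool, length(rest), replace = length(rest) > length(other_pool))
      for (gi in seq_along(rest)) m[[rest[gi]]] <- scat[gi]
    }
    n_null <- length(lay$null)
    under_sig <- sample(c(TRUE, FALSE), n_null, replace = TRUE, prob = c(0.65, 0.35))
    for (g in seq_len(n_null)) {
      pool <- if (under_sig[g]) general_pool else other_pool
      m[[lay$null[g]]] <- sample(pool, 1)
    }
    m
  })
  list(dag = dag, annot = term_annotation(annot_map),
       deg_terms = ids[deg_idx], module_terms = module_terms)
}

#' Generate a synthetic two-tissue cohort
#'
#' Counts are negative binomial with `log2 mu` additive in: a lognormal
#' per-gene baseline; a tissue effect (tissue-DE genes, both tumor and
#' normal, alternating direction, colon vs endometrium); a cancer effect
#' (cancer-DE genes, tumors of one tissue only, alternating target tissue);
#' and a module effect on planted gene x sample blocks, each block confined
#' to samples of one group. Tumor survival is exponential with the baseline
#' hazard, multiplied by `hazard_multiplier` for samples active in at least
#' one cancer module, administratively censored at the horizon. Fully
#' reproducible from `seed`.
#'
#' @param config a [generator_config()].
#' @param seed RNG seed.
#' @return List with `counts` (integer matrix), `samples`
#'   ([sample_table()]), `ontology` (the [generate_ontology()] output for the
#'   same config and seed) and `truth` (gene classes, module definitions with
#'   sample sets, per-sample hazard).
#' @export
generate_cohort <- function(config, seed = 1) {
  cfg <- config
  stopifnot(inherits(cfg, "generator_config"))
  lay <- .gene_layout(cfg)
  groups <- rep(names(cfg$group_sizes), cfg$group_sizes)
  sample_ids <- unlist(lapply(names(cfg$group_sizes), function(g) {
    sprintf("%s_%02d", g, seq_len(cfg$group_sizes[[g]]))
  }))
  tissue <- ifelse(grepl("^colon", groups), "colon", "endometrium")
  condition <- ifelse(grepl("tumor$", groups), "tumor", "normal")
  onto <- generate_ontology(cfg, seed)
  res <- .with_seed(seed + 1L, {
    ng <- cfg$n_genes; ns <- length(sample_ids)
    base <- stats::rnorm(ng, log2(cfg$base_mean), cfg$base_log2_sd)
    log2mu <- matrix(base, ng, ns)
    rownames(log2mu) <- lay$ids; colnames(log2mu) <- sample_ids
    # tissue effect: alternating direction, applied to all colon samples
    t_idx <- match(lay$tissue_de, lay$ids)
    t_sign <- rep(c(1, -1), length.out = length(t_idx))
    log2mu[t_idx, tissue == "colon"] <-
      log2mu[t_idx, tissue == "colon"] + t_sign * cfg$tissue_lfc
    # cancer effect: alternating target tissue, tumors only
    c_idx <- match(lay$cancer_de, lay$ids)
    c_colon <- rep(c(TRUE, FALSE), length.out = length(c_idx))
    log2mu[c_idx[c_colon], tissue == "colon" & condition == "tumor"] <-
      log2mu[c_idx[c_colon], tissue == "colon" & condition == "tumor"] + cfg$cancer_lfc
    log2mu[c_idx[!c_colon], tissue == "endometrium" & condition == "tumor"] <-
      log2mu[c_idx[!c_colon], tissue == "endometrium" & condition == "tumor"] + cfg$cancer_lfc
    # planted modules
    modules <- lapply(lay$modules, function(mod) {
      pool <- sample_ids[groups == mod$class]
      mod$samples <- sort(sample(pool, cfg$module_samples))
      mod$lfc <- cfg$module_lfc
      log2mu[mod$genes, mod$samples] <<- log2mu[mod$genes, mod$samples] + cfg$module_lfc
      mod
    })
    counts <- matrix(stats::rnbinom(ng * ns, mu = 2^log2mu, size = 1 / cfg$dispersion),
                     ng, ns, dimnames = list(lay$ids, sample_ids))
    # survival: tumors only; each active cancer module multiplies the
    # sample's hazard (log-additive contribution per expression program)
    n_active <- rowSums(vapply(modules, function(m) {
      if (grepl("tumor", m$class)) sample_ids %in% m$samples else rep(FALSE, ns)
    }, logical(ns)))
    hazard <- ifelse(condition == "tumor",
                     cfg$baseline_hazard * cfg$hazard_multiplier^n_active,
                     NA_real_)
    tt <- rep(NA_real_, ns)
    is_tum <- condition == "tumor"
    tt[is_tum] <- stats::rexp(sum(is_tum), rate = hazard[is_tum])
    os_time <- ifelse(condition == "tumor", pmin(tt, cfg$censor_horizon), NA_real_)
    os_event <- ifelse(condition == "tumor", as.integer(tt <= cfg$censor_horizon), NA_integer_)
    list(counts = counts, modules = modules, hazard = hazard,
         os_time = os_time, os_event = os_event)
  })
  samples <- sample_table(data.frame(
    sample = sample_ids, tissue = tissue, condition = condition,
    msi = condition == "tumor",
    os_time = res$os_time, os_event = res$os_event,
    cohort = "synthetic", stringsAsFactors = FALSE
  ))
  truth <- list(
    gene_class = stats::setNames(lay$class, lay$ids),
    modules = res$modules,
    deg_terms = onto$deg_terms,
    module_terms = onto$module_terms,
    hazard = stats::setNames(res$hazard, sample_ids)
  )
  list(counts = res$counts, samples = samples, ontology = onto, truth = truth)
}
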