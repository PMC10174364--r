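# Childness scores: how deep a query term sits below a reference set of
# DEG-enriched terms in the is_a/part_of-restricted GO DAG. The up (down)
# count of a term is the maximum number of reference terms lying on any
# directed ancestor (descendant) path, the query term itself excluded;
# childness = up / (up + down).

# Longest-weighted-path DP over the relation-restricted DAG. Returns, for
# every term t, max over ancestor paths of the number of deg terms on the
# path (t excluded). direction "up" counts over ancestors, "down" over
# descendants. Exact because the restricted graph is acyclic.
.deg_count_dp <- function(dag, deg_terms, relations = c("is_a", "part_of"),
                          direction = c("up", "down")) {
  direction <- match.arg(direction)
  ord <- .topo_order(dag, relations) # parents before children
  adj <- if (direction == "up") .parent_adj(dag, relations) else .child_adj(dag, relations)
  if (direction == "down") ord <- rev(ord)
  w <- stats::setNames(as.integer(dag$terms %in% deg_terms), dag$terms)
  f <- stats::setNames(integer(length(dag$terms)), dag$terms)
  for (t in ord) {
    nb <- adj[[t]]
    if (length(nb)) f[[t]] <- max(w[nb] + f[nb])
  }
  f
}

#' Maximum count of reference terms on ancestor / descendant paths
#'
#' `max_deg_count_up()` returns the maximum, over all directed child-to-parent
#' paths starting at `term`, of the number of `deg_terms` lying on the path,
#' the query term itself excluded (include it via `count_self`).
#' `max_deg_count_down()` is the mirror over descendant paths. Computed by
#' longest-weighted-path dynamic programming (weight 1 on reference terms),
#' which is exact on the acyclic relation-restricted graph.
#'
#' @param dag an [ontology_dag()].
#' @param term a term id.
#' @param deg_terms character vector of reference (DEG-enriched) term ids.
#' @param relations relation kinds the paths may traverse.
#' @param count_self if `TRUE`, a query term that is itself a reference term
#'   contributes 1 to the count.
#' @return A nonnegative integer.
#' @export
max_deg_count_up <- function(dag, term, deg_terms,
                             relations = c("is_a", "part_of"), count_self = FALSE) {
  term <- .resolve_term(dag, term)
  f <- .deg_count_dp(dag, deg_terms, relations, "up")
  unname(f[[term]] + if (count_self && term %in% deg_terms) 1L else 0L)
}

#' @rdname max_deg_count_up
#' @export
max_deg_count_down <- function(dag, term, deg_terms,
                               relations = c("is_a", "part_of"), count_self = FALSE) {
  term <- .resolve_term(dag, term)
  f <- .deg_count_dp(dag, deg_terms, relations, "down")
  unname(f[[term]] + if (count_self && term %in% deg_terms) 1L else 0L)
}

#' Term childness score
#'
#' `up / (up + down)` where up and down are [max_deg_count_up()] and
#' [max_deg_count_down()]. A term with no reference relative in either
#' direction (up + down = 0) carries no evidence of sitting below the
#' reference functions and scores 0.
#'
#' @inheritParams max_deg_count_up
#' @return A score in \eqn{[0, 1]}.
#' @export
term_childness <- function(dag, term, deg_terms,
                           relations = c("is_a", "part_of"), count_self = FALSE) {
  if (length(deg_terms) == 0) {
    warning("empty reference term set; childness is 0")
    return(0)
  }
  up <- max_deg_count_up(dag, term, deg_terms, relations, count_self)
  down <- max_deg_count_down(dag, term, deg_terms, relations, count_self)
  if (up + down == 0) 0 else up / (up + down)
}

#' Term-set childness score
#'
#' Arithmetic mean of [term_childness()] over a nonempty term set — typically
#' the adjusted-p < 0.05 enriched BP terms of one bicluster. A bicluster with
#' no enriched terms is reported unscored rather than scored 0, so an empty
#' set is an error.
#'
#' @param terms nonempty character vector of term ids.
#' @inheritParams max_deg_count_up
#' @return A score in \eqn{[0, 1]}.
#' @export
term_set_childness <- function(dag, terms, deg_terms,
                               relations = c("is_a", "part_of"), count_self = FALSE) {
  if (length(terms) == 0) stop("empty term set: bicluster has no enriched terms; report unscored")
  if (length(deg_terms) == 0) {
    warning("empty reference term set; childness is 0")
    return(0)
  }
  fu <- .deg_count_dp(dag, deg_terms, relations, "up")
  fd <- .deg_count_dp(dag, deg_terms, relations, "down")
  terms <- vapply(terms, .resolve_term, "", dag = dag)
  self <- if (count_self) as.integer(terms %in% deg_terms) else 0L
  up <- fu[terms] + self
  down <- fd[terms] + self
  sc <- ifelse(up + down == 0, 0, up / (up + down))
  mean(sc)
}

#' Gene childness score
#'
#' Maximum [term_childness()] over a gene's annotated BP terms (annotation
#' should be propagated). Unannotated genes score 0 with a warning; genes
#' whose every term scores 0 score 0.
#'
#' @param annot a propagated [term_annotation()].
#' @param gene a gene id.
#' @inheritParams max_deg_count_up
#' @return A score in \eqn{[0, 1]}.
#' @export
gene_childness <- function(dag, annot, gene, deg_terms,
                           relations = c("is_a", "part_of"), count_self = FALSE) {
  stopifnot(inherits(annot, "term_annotation"))
  ts <- annot$map[[gene]]
  ts <- ts[ts %in% dag$terms]
  if (is.null(ts) || length(ts) == 0) {
    warning("gene ", gene, " has no annotated terms; childness is 0")
    return(0)
  }
  fu <- .deg_count_dp(dag, deg_terms, relations, "up")
  fd <- .deg_count_dp(dag, deg_terms, relations, "down")
  self <- if (count_self) as.integer(ts %in% deg_terms) else 0L
  up <- fu[ts] + self
  down <- fd[ts] + self
  sc <- ifelse(up + down == 0, 0, up / (up + down))
  max(sc)
}

#' Select functionally relevant biclusters by term-set childness
#'
#' Returns the ids whose score strictly exceeds the threshold (default 0.6).
#'
#' @param scores named numeric vector of term-set childness scores.
#' @param threshold strict lower bound.
#' @return Character vector of selected bicluster ids.
#' @export
select_functional_biclusters <- function(scores, threshold = 0.6) {
  stopifnot(is.numeric(scores), threshold >= 0, threshold <= 1)
  names(scores)[scores > threshold]
}

#' Compare childness scores between two bicluster groups
#'
#' Two-sided Wilcoxon rank-sum test: exact when both groups have at most 20
#' observations and there are no ties, normal approximation with continuity
#' correction (and mid-rank tie handling) otherwise.
#'
#' @param scores_a,scores_b nonempty numeric vectors.
#' @return Two-sided p-value.
#' @export
compare_childness_groups <- function(scores_a, scores_b) {
  if (length(scores_a) == 0 || length(scores_b) == 0) {
    stop("both groups must be nonempty")
  }
  ties <- anyDuplicated(c(scores_a, scores_b)) > 0
  exact <- !ties && length(scores_a) <= 20 && length(scores_b) <= 20
  stats::wilcox.test(scores_a, scores_b, exact = exact, correct = TRUE)$p.value
}

#' Per-term childness report
#'
#' Computes up/down counts and childness for a set of query terms against a
#' reference set, as a data.frame suitable for TSV export.
#'
#' @param terms character vector of query term ids.
#' @inheritParams max_deg_count_up
#' @return data.frame with columns `term`, `up`, `down`, `childness`.
#' @export
childness_report <- function(dag, terms, deg_terms,
                             relations = c("is_a", "part_of"), count_self = FALSE) {
  fu <- .deg_count_dp(dag, deg_terms, relations, "up")
  fd <- .deg_count_dp(dag, deg_terms, relations, "down")
  terms <- vapply(terms, .resolve_term, "", dag = dag)
  self <- if (count_self) as.integer(terms %in% deg_terms) else 0L
  up <- unname(fu[terms] + self)
  down <- unname(fd[terms] + self)
  data.frame(term = terms, up = up, down = down,
             childness = ifelse(up + down == 0, 0, up / (up + down)))
}
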