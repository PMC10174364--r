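#' Typed gene-ontology DAG
#'
#' An `ontology_dag` stores non-obsolete terms of one namespace together with
#' typed child-to-parent edges (`is_a`, `part_of`, `regulates`,
#' `positively_regulates`, `negatively_regulates`). Transitive queries
#' ([ancestors()], [descendants()]) and annotation propagation restrict the
#' graph to a chosen relation subset; the default subset (`is_a` + `part_of`)
#' is the one on which the childness scores are defined. Regulates-family
#' edges are parsed and stored but excluded from closures by default.
#'
#' @param terms character vector of unique term ids.
#' @param name named character vector of term names (names are term ids).
#' @param namespace named character vector of term namespaces.
#' @param edges data.frame with columns `child`, `parent`, `relation`.
#' @param alt named character vector mapping alternate ids to primary ids.
#'
#' @return An object of class `ontology_dag`.
#' @export
ontology_dag <- function(terms, name = NULL, namespace = NULL,
                         edges = data.frame(child = character(), parent = character(),
                                            relation = character()),
                         alt = character()) {
  terms <- as.character(terms)
  if (anyDuplicated(terms)) {
    stop("duplicate term ids: ", paste(unique(terms[duplicated(terms)]), collapse = ", "))
  }
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  stopifnot(all(c("child", "parent", "relation") %in% names(edges)))
  bad <- setdiff(unique(c(edges$child, edges$parent)), terms)
  if (length(bad)) {
    stop("edge endpoint not a registered term: ", paste(bad, collapse = ", "))
  }
  if (is.null(name)) name <- stats::setNames(terms, terms)
  if (is.null(namespace)) namespace <- stats::setNames(rep("biological_process", length(terms)), terms)
  dag <- structure(
    list(terms = terms, name = name, namespace = namespace,
         edges = edges, alt = alt),
    class = "ontology_dag"
  )
  .check_acyclic(dag, relations = c("is_a", "part_of"))
  dag
}

#' @export
print.ontology_dag <- function(x, ...) {
  cat("ontology_dag:", length(x$terms), "terms,", nrow(x$edges), "edges (",
      paste(sprintf("%s: %d", names(table(x$edges$relation)), table(x$edges$relation)),
            collapse = ", "), ")\n")
  invisible(x)
}

.relation_kinds <- c("is_a", "part_of", "regulates",
                     "positively_regulates", "negatively_regulates")

# child -> parents adjacency list restricted to a relation subset
.parent_adj <- function(dag, relations) {
  e <- dag$edges[dag$edges$relation %in% relations, , drop = FALSE]
  split(e$parent, factor(e$child, levels = dag$terms))
}

.child_adj <- function(dag, relations) {
  e <- dag$edges[dag$edges$relation %in% relations, , drop = FALSE]
  split(e$child, factor(e$parent, levels = dag$terms))
}

# Kahn topological order over the relation-restricted subgraph; errors on cycle.
.topo_order <- function(dag, relations) {
  e <- dag$edges[dag$edges$relation %in% relations, , drop = FALSE]
  n <- length(dag$terms)
  idx <- stats::setNames(seq_len(n), dag$terms)
  outdeg <- integer(n) # edges child -> parent: process parents first
  kids <- vector("list", n)
  if (nrow(e)) {
    ci <- idx[e$child]; pi <- idx[e$parent]
    outdeg <- tabulate(ci, nbins = n)
    kids <- split(ci, factor(pi, levels = seq_len(n)))
  } else {
    kids <- rep(list(integer()), n)
  }
  queue <- which(outdeg == 0L)
  ord <- integer(0)
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    ord <- c(ord, v)
    for (k in kids[[v]]) {
      outdeg[k] <- outdeg[k] - 1L
      if (outdeg[k] == 0L) queue <- c(queue, k)
    }
  }
  if (length(ord) < n) {
    stop("cycle detected among ", paste(relations, collapse = "/"), " edges")
  }
  dag$terms[ord] # parents before children
}

.check_acyclic <- function(dag, relations) {
  invisible(.topo_order(dag, relations))
}

.resolve_term <- function(dag, term) {
  if (term %in% dag$terms) return(term)
  if (term %in% names(dag$alt)) return(dag$alt[[term]])
  stop("unknown term id: ", term)
}

#' Parse an OBO file into a typed ontology DAG
#'
#' Reads OBO 1.2/1.4 flat files. Non-obsolete `[Term]` stanzas of the requested
#' namespace are retained; `is_a:` and `relationship:` lines become typed
#' edges, `alt_id:` lines populate the alternate-id map. Edges with an
#' endpoint outside the retained namespace are dropped.
#'
#' @param obo path to an OBO file, or a character vector of OBO lines.
#' @param namespace namespace to retain; terms without an explicit
#'   `namespace:` line inherit the header's `default-namespace`, or this
#'   namespace when no header is present.
#' @return An [ontology_dag()].
#' @export
parse_obo <- function(obo, namespace = "biological_process") {
  lines <- if (length(obo) == 1 && !grepl("\n", obo) && file.exists(obo)) {
    readLines(obo, warn = FALSE)
  } else {
    unlist(strsplit(obo, "\n", fixed = TRUE))
  }
  default_ns <- namespace
  m <- grep("^default-namespace:", lines, value = TRUE)
  if (length(m)) default_ns <- trimws(sub("^default-namespace:", "", m[1]))

  stanza_starts <- grep("^\\[", lines)
  term_rec <- list(); edge_child <- edge_parent <- edge_rel <- character()
  alt <- character()
  for (si in seq_along(stanza_starts)) {
    s <- stanza_starts[si]
    if (lines[s] != "[Term]") next
    e <- if (si < length(stanza_starts)) stanza_starts[si + 1] - 1 else length(lines)
    body_idx <- (s + 1):e
    body <- lines[body_idx]
    keep <- nzchar(trimws(body)) & !grepl("^!", body)
    body <- body[keep]; body_idx <- body_idx[keep]
    bad <- !grepl("^[A-Za-z_]+:", body)
    if (any(bad)) {
      stop("malformed OBO stanza line ", body_idx[which(bad)[1]], ": ", body[bad][1])
    }
    key <- sub(":.*$", "", body)
    val <- trimws(sub("^[A-Za-z_]+:", "", body))
    val <- trimws(sub("!.*$", "", val)) # strip trailing comments
    rec <- list(id = val[key == "id"][1],
                name = if (any(key == "name")) val[key == "name"][1] else NA_character_,
                namespace = if (any(key == "namespace")) val[key == "namespace"][1] else default_ns,
                obsolete = any(key == "is_obsolete" & val == "true"),
                alt_id = val[key == "alt_id"],
                is_a = val[key == "is_a"],
                rel = val[key == "relationship"])
    if (is.na(rec$id)) stop("OBO [Term] stanza starting at line ", s, " has no id")
    if (rec$obsolete || rec$namespace != namespace) next
    term_rec[[rec$id]] <- rec
    if (length(rec$is_a)) {
      edge_child <- c(edge_child, rep(rec$id, length(rec$is_a)))
      edge_parent <- c(edge_parent, rec$is_a)
      edge_rel <- c(edge_rel, rep("is_a", length(rec$is_a)))
    }
    for (r in rec$rel) {
      parts <- strsplit(r, "\\s+")[[1]]
      if (length(parts) < 2) stop("malformed relationship line in term ", rec$id, ": ", r)
      if (parts[1] %in% .relation_kinds) {
        edge_child <- c(edge_child, rec$id)
        edge_parent <- c(edge_parent, parts[2])
        edge_rel <- c(edge_rel, parts[1])
      }
    }
    if (length(rec$alt_id)) alt[rec$alt_id] <- rec$id
  }
  ids <- names(term_rec)
  keep <- edge_parent %in% ids & edge_child %in% ids
  ontology_dag(
    terms = ids,
    name = stats::setNames(vapply(term_rec, `[[`, "", "name"), ids),
    namespace = stats::setNames(vapply(term_rec, `[[`, "", "namespace"), ids),
    edges = data.frame(child = edge_child[keep], parent = edge_parent[keep],
                       relation = edge_rel[keep], stringsAsFactors = FALSE),
    alt = alt
  )
}

.reachable <- function(adj, start) {
  seen <- character(0)
  frontier <- adj[[start]]
  while (length(frontier)) {
    frontier <- setdiff(unique(frontier), seen)
    seen <- c(seen, frontier)
    frontier <- unlist(adj[frontier], use.names = FALSE)
  }
  seen
}

#' Transitive ancestors of a term
#'
#' All terms reachable from `term` by repeatedly following child-to-parent
#' edges whose relation kind lies in `relations`; the term itself is excluded.
#'
#' @param dag an [ontology_dag()].
#' @param term a term id (alternate ids are resolved).
#' @param relations relation kinds to traverse.
#' @return Character vector of ancestor term ids (possibly empty).
#' @export
ancestors <- function(dag, term, relations = c("is_a", "part_of")) {
  term <- .resolve_term(dag, term)
  .reachable(.parent_adj(dag, relations), term)
}

#' Transitive descendants of a term
#'
#' Mirror of [ancestors()] with edge direction reversed.
#' @inheritParams ancestors
#' @return Character vector of descendant term ids (possibly empty).
#' @export
descendants <- function(dag, term, relations = c("is_a", "part_of")) {
  term <- .resolve_term(dag, term)
  .reachable(.child_adj(dag, relations), term)
}

# full ancestor closure for every term, computed along a topological order
.ancestor_closure <- function(dag, relations = c("is_a", "part_of")) {
  ord <- .topo_order(dag, relations) # parents before children
  padj <- .parent_adj(dag, relations)
  clo <- stats::setNames(vector("list", length(dag$terms)), dag$terms)
  for (t in ord) {
    ps <- padj[[t]]
    clo[[t]] <- if (length(ps)) unique(c(ps, unlist(clo[ps], use.names = FALSE))) else character(0)
  }
  clo
}

#' Gene-to-term annotation table
#'
#' Maps gene ids to sets of term ids, with a flag recording whether the
#' true-path rule (closure under the ancestor relation) has been applied.
#'
#' @param map named list; each element is a character vector of term ids for
#'   one gene.
#' @param propagated logical flag.
#' @return An object of class `term_annotation`.
#' @export
term_annotation <- function(map, propagated = FALSE) {
  stopifnot(is.list(map), !is.null(names(map)))
  structure(list(map = lapply(map, unique), propagated = propagated),
            class = "term_annotation")
}

#' @export
print.term_annotation <- function(x, ...) {
  cat("term_annotation:", length(x$map), "genes,",
      if (x$propagated) "propagated" else "unpropagated", "\n")
  invisible(x)
}

#' Apply the true-path rule to a gene annotation
#'
#' Each gene's term set is replaced by its union with all `is_a`/`part_of`
#' ancestors. Records referencing terms absent from `dag` are dropped with a
#' warning; the number of dropped records is stored in the `n_dropped`
#' attribute. Idempotent: an already-propagated annotation is returned as is.
#'
#' @param dag an [ontology_dag()].
#' @param annot a [term_annotation()].
#' @param relations relation kinds closed over.
#' @return A propagated [term_annotation()].
#' @export
propagate_annotations <- function(dag, annot, relations = c("is_a", "part_of")) {
  stopifnot(inherits(annot, "term_annotation"))
  if (isTRUE(annot$propagated)) return(annot)
  clo <- .ancestor_closure(dag, relations)
  dropped <- 0L
  map <- lapply(annot$map, function(ts) {
    ts <- vapply(ts, function(t) {
      if (t %in% dag$terms) t
      else if (t %in% names(dag$alt)) dag$alt[[t]]
      else NA_character_
    }, "")
    bad <- is.na(ts)
    dropped <<- dropped + sum(bad)
    ts <- ts[!bad]
    unique(c(ts, unlist(clo[ts], use.names = FALSE)))
  })
  if (dropped > 0) {
    warning(dropped, " annotation record(s) referenced unknown terms and were dropped")
  }
  out <- term_annotation(map, propagated = TRUE)
  attr(out, "n_dropped") <- dropped
  out
}

#' Read gene-to-term annotations
#'
#' `read_annotation_tsv()` reads a two-column `gene<TAB>term` file (no
#' header). `read_gaf()` reads GAF 2.1/2.2, using columns 2 (gene symbol) and
#' 5 (term id) and skipping `!` comment lines. `write_annotation_tsv()` writes
#' the two-column form back.
#'
#' @param path file path.
#' @return A [term_annotation()] (unpropagated).
#' @export
read_annotation_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          colClasses = "character", quote = "", comment.char = "")
  if (ncol(df) < 2) stop("annotation TSV must have two columns: gene<TAB>term")
  term_annotation(split(df[[2]], df[[1]]))
}

#' @rdname read_annotation_tsv
#' @export
read_gaf <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "!") & nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- lengths(fields) < 5
  if (any(short)) stop("GAF line with fewer than 5 columns: ", lines[short][1])
  gene <- vapply(fields, `[[`, "", 2)
  term <- vapply(fields, `[[`, "", 5)
  term_annotation(split(term, gene))
}

#' @rdname read_annotation_tsv
#' @param annot a [term_annotation()].
#' @export
write_annotation_tsv <- function(annot, path) {
  stopifnot(inherits(annot, "term_annotation"))
  df <- data.frame(
    gene = rep(names(annot$map), lengths(annot$map)),
    term = unlist(annot$map, use.names = FALSE)
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
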