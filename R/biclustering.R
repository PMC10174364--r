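# From-scratch ISA and Plaid biclustering plus the pair-based Jaccard
# similarity between biclusters. Both algorithms operate on a normalized
# real-valued matrix (see normalize_for_biclustering) and are deterministic
# given their seed.

#' A single bicluster
#'
#' @param id unique identifier.
#' @param algorithm label of the producing algorithm.
#' @param genes,samples nonempty character vectors of member ids.
#' @return An object of class `bicluster`.
#' @export
bicluster <- function(id, algorithm, genes, samples) {
  genes <- unique(as.character(genes)); samples <- unique(as.character(samples))
  if (length(genes) == 0 || length(samples) == 0) {
    stop("bicluster ", id, " must have nonempty gene and sample sets")
  }
  structure(list(id = as.character(id), algorithm = as.character(algorithm),
                 genes = genes, samples = samples),
            class = "bicluster")
}

#' @export
print.bicluster <- function(x, ...) {
  cat("bicluster ", x$id, " [", x$algorithm, "]: ",
      length(x$genes), " genes x ", length(x$samples), " samples\n", sep = "")
  invisible(x)
}

#' An ordered collection of biclusters
#'
#' Overlaps between member biclusters are permitted; ids must be unique.
#'
#' @param biclusters list of [bicluster()] objects.
#' @param source optional list with `genes` and `samples` id vectors of the
#'   source matrix; membership is validated against it when given.
#' @return An object of class `bicluster_set`.
#' @export
bicluster_set <- function(biclusters, source = NULL) {
  stopifnot(is.list(biclusters))
  ids <- vapply(biclusters, `[[`, "", "id")
  if (anyDuplicated(ids)) stop("duplicate bicluster ids: ", ids[duplicated(ids)][1])
  if (!is.null(source)) {
    for (b in biclusters) {
      badg <- setdiff(b$genes, source$genes); bads <- setdiff(b$samples, source$samples)
      if (length(badg) || length(bads)) {
        stop("bicluster ", b$id, " references ids absent from the source matrix: ",
             paste(utils::head(c(badg, bads), 3), collapse = ", "))
      }
    }
  }
  structure(list(biclusters = biclusters, source = source), class = "bicluster_set")
}

#' @export
print.bicluster_set <- function(x, ...) {
  algs <- table(vapply(x$biclusters, `[[`, "", "algorithm"))
  cat("bicluster_set:", length(x$biclusters), "biclusters (",
      paste(sprintf("%s: %d", names(algs), algs), collapse = ", "), ")\n")
  invisible(x)
}

#' @export
length.bicluster_set <- function(x) length(x$biclusters)

.source_sig <- function(m) list(genes = rownames(m), samples = colnames(m))

# run code with a temporary RNG state seeded from `seed`
.with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  force(code)
}

#' Normalize a count matrix for biclustering
#'
#' `log2(count / size_factor + 1)`, then per-gene z-scoring. Genes constant
#' across samples are dropped (their ids are recorded in the `dropped`
#' attribute).
#'
#' @param counts integer matrix, genes x samples.
#' @param factors per-sample size factors (see [size_factors()]).
#' @return Real matrix with row means 0 and row standard deviations 1.
#' @export
normalize_for_biclustering <- function(counts, factors) {
  if (ncol(counts) < 2) stop("need at least 2 samples to standardize genes")
  stopifnot(length(factors) == ncol(counts))
  lg <- log2(sweep(counts, 2, factors, "/") + 1)
  sds <- apply(lg, 1, stats::sd)
  const <- sds == 0 | !is.finite(sds)
  if (any(const)) {
    message("dropping ", sum(const), " constant gene(s) before z-scoring")
  }
  lg <- lg[!const, , drop = FALSE]
  out <- (lg - rowMeans(lg)) / apply(lg, 1, stats::sd)
  out
}

# Threshold a score vector: a robust z-score floor (median + thr * mad, with
# the sd as fallback scale) gates the candidate region, and the cut is then
# snapped to the widest gap in the sorted scores above the floor, which
# places the boundary at the strongest density break instead of inside
# secondary structure. Returns the selected indices.
.threshold_cut <- function(x, thr) {
  med <- stats::median(x); s <- stats::sd(x); m <- stats::mad(x)
  if (!is.finite(s) || s < 1e-12) return(integer(0))
  if (!is.finite(m) || m < 1e-12) m <- s
  floorv <- med + thr * min(m, s)
  if (!any(x > floorv)) return(integer(0))
  anchor <- if (any(x <= floorv)) max(x[x <= floorv]) else floorv
  v <- c(anchor, sort(x[x > floorv]))
  gaps <- diff(v)
  k <- which.max(gaps)
  cut <- (v[k] + v[k + 1]) / 2
  which(x > cut)
}

.row_zscore <- function(m) {
  s <- apply(m, 1, stats::sd)
  s[s < 1e-12] <- 1
  (m - rowMeans(m)) / s
}

#' Iterative signature algorithm (ISA)
#'
#' From each random initial gene set, sample scores (column means over the
#' row-standardized matrix) and gene scores (row means over the
#' column-standardized matrix) are alternately z-score-thresholded until the
#' membership reaches a fixed point or `max_iter` iterations. Non-converged
#' seeds are discarded and duplicate fixed points merged. Module directions
#' are detected as coherently elevated blocks; to search for coherently
#' depressed blocks, negate the matrix.
#'
#' @param matrix normalized real matrix, genes x samples, with dimnames.
#' @param gene_threshold,sample_threshold positive z-score thresholds.
#' @param n_seeds number of random initializations.
#' @param seed RNG seed; the run is deterministic given it.
#' @param init `"random"`: initial gene sets of size `init_size`;
#'   `"gene"`: each seed starts from one random gene's expression profile
#'   (better coverage of small modules in large matrices).
#' @param init_size initial gene-set size for `init = "random"`.
#' @param max_iter iteration cap per seed.
#' @return A [bicluster_set()] with algorithm label `"isa"`.
#' @export
run_isa <- function(matrix, gene_threshold = 2, sample_threshold = 2,
                    n_seeds = 100, seed = 1, init = c("random", "gene"),
                    init_size = 20, max_iter = 100) {
  init <- match.arg(init)
  if (nrow(matrix) < 2 || ncol(matrix) < 2) stop("matrix must have at least 2 genes and 2 samples")
  stopifnot(gene_threshold > 0, sample_threshold > 0)
  if (is.null(rownames(matrix))) rownames(matrix) <- paste0("g", seq_len(nrow(matrix)))
  if (is.null(colnames(matrix))) colnames(matrix) <- paste0("s", seq_len(ncol(matrix)))
  Er <- .row_zscore(matrix)
  Ec <- t(.row_zscore(t(matrix)))
  ng <- nrow(matrix)
  fixed <- list()
  .with_seed(seed, {
    for (sd_i in seq_len(n_seeds)) {
      if (init == "random") {
        G <- sample.int(ng, min(init_size, ng))
      } else {
        G <- sample.int(ng, 1)
      }
      sc <- colMeans(Er[G, , drop = FALSE])
      prevG <- integer(0); prevS <- integer(0); conv <- FALSE
      for (it in seq_len(max_iter)) {
        S <- .threshold_cut(sc, sample_threshold)
        if (length(S) == 0) break
        G2 <- .threshold_cut(rowMeans(Ec[, S, drop = FALSE]), gene_threshold)
        if (length(G2) == 0) break
        if (identical(G2, prevG) && identical(S, prevS)) {
          conv <- TRUE; G <- G2; break
        }
        prevG <- G2; prevS <- S; G <- G2
        sc <- colMeans(Er[G, , drop = FALSE])
      }
      if (conv) fixed[[length(fixed) + 1]] <- list(G = sort(G), S = sort(S))
    }
  })
  fixed <- unique(fixed)
  bics <- lapply(seq_along(fixed), function(i) {
    bicluster(paste0("isa_", i), "isa",
              rownames(matrix)[fixed[[i]]$G], colnames(matrix)[fixed[[i]]$S])
  })
  bicluster_set(bics, source = .source_sig(matrix))
}

# leading singular pair by power iteration (deterministic given RNG state)
.leading_pair <- function(Z, iters = 40) {
  v <- stats::rnorm(ncol(Z))
  v <- v / sqrt(sum(v^2))
  for (i in seq_len(iters)) {
    v <- crossprod(Z, Z %*% v)
    nv <- sqrt(sum(v^2))
    if (nv < 1e-30) return(NULL)
    v <- as.numeric(v / nv)
  }
  u <- as.numeric(Z %*% v)
  list(u = u, v = v)
}

# one plaid layer on residual Z: SVD-seeded membership, then alternating
# pruning/release by explained sum of squares. Returns NULL when no layer.
.plaid_layer <- function(Z, release, thr = 2, max_iter = 20) {
  pair <- .leading_pair(Z)
  if (is.null(pair)) return(NULL)
  # rows are seeded from one sign of the leading left singular vector (an
  # additive layer cannot hold coherently-up and coherently-down rows at
  # once); both orientations are tried and the stronger layer kept
  best <- NULL
  for (sgn in c(1, -1)) {
    lay <- .plaid_layer_oriented(Z, sgn * pair$u, release, thr, max_iter)
    if (!is.null(lay) && (is.null(best) || lay$ss > best$ss)) best <- lay
  }
  best
}

.plaid_layer_oriented <- function(Z, u, release, thr, max_iter) {
  R <- .threshold_cut(u, thr)
  # start from all columns: the release rule prunes the unexplained ones, and
  # row-centered data can carry coherent +/- patterns across every column
  C <- seq_len(ncol(Z))
  if (length(R) < 2) return(NULL)
  for (it in seq_len(max_iter)) {
    blk <- Z[R, C, drop = FALSE]
    mu <- mean(blk)
    alpha <- rowMeans(Z[, C, drop = FALSE]) - mu          # refit for every row
    beta <- colMeans(Z[R, , drop = FALSE]) - mu           # refit for every col
    # row membership: fraction of the row's SS over C explained by mu+alpha+beta
    fitC <- outer(alpha, beta[C], "+") + mu
    residR <- rowSums((Z[, C, drop = FALSE] - fitC)^2)
    totR <- rowSums(Z[, C, drop = FALSE]^2)
    R2 <- which(totR > 1e-12 & 1 - residR / totR >= release)
    if (length(R2) < 2) return(NULL)
    blk <- Z[R2, C, drop = FALSE]
    mu <- mean(blk)
    alpha <- rowMeans(blk) - mu
    beta <- colMeans(Z[R2, , drop = FALSE]) - mu          # refit for every col
    fitR <- outer(alpha, beta, "+") + mu
    residC <- colSums((Z[R2, , drop = FALSE] - fitR)^2)
    totC <- colSums(Z[R2, , drop = FALSE]^2)
    C2 <- which(totC > 1e-12 & 1 - residC / totC >= release)
    if (length(C2) < 2) return(NULL)
    if (identical(R2, R) && identical(C2, C)) { R <- R2; C <- C2; break }
    R <- R2; C <- C2
  }
  blk <- Z[R, C, drop = FALSE]
  mu <- mean(blk)
  alpha <- rowMeans(blk) - mu
  beta <- colMeans(blk) - mu
  theta <- outer(alpha, beta, "+") + mu
  list(R = R, C = C, theta = theta, ss = sum(theta^2))
}

#' Plaid-model biclustering
#'
#' Iteratively fits additive layers `mu + alpha_i + beta_j` to the residual
#' matrix. Each layer's membership is seeded from the leading singular pair
#' and refined by pruning and release: a row (column) is retained while the
#' layer explains at least `release` of its sum of squares over the layer's
#' columns (rows). A layer is kept only if its sum of squares exceeds the
#' 95th percentile of layers fitted to row-permuted copies of the residual;
#' fitting stops at the first rejected layer. Deterministic given `seed`.
#'
#' @param matrix normalized real matrix, genes x samples, with dimnames.
#' @param max_layers maximum number of layers.
#' @param seed RNG seed.
#' @param n_perm permutations for the significance gate.
#' @param release explained-sum-of-squares retention threshold.
#' @param max_iter membership iterations per layer.
#' @return A [bicluster_set()] with algorithm label `"plaid"`.
#' @export
run_plaid <- function(matrix, max_layers = 10, seed = 1, n_perm = 20,
                      release = 0.7, max_iter = 20) {
  if (nrow(matrix) < 2 || ncol(matrix) < 2) stop("matrix must have at least 2 genes and 2 samples")
  if (is.null(rownames(matrix))) rownames(matrix) <- paste0("g", seq_len(nrow(matrix)))
  if (is.null(colnames(matrix))) colnames(matrix) <- paste0("s", seq_len(ncol(matrix)))
  Z <- matrix
  layers <- list()
  .with_seed(seed, {
    for (l in seq_len(max_layers)) {
      lay <- .plaid_layer(Z, release, max_iter = max_iter)
      if (is.null(lay)) break
      perm_ss <- vapply(seq_len(n_perm), function(b) {
        Zp <- t(apply(Z, 1, sample))
        pl <- .plaid_layer(Zp, release, max_iter = 8)
        if (is.null(pl)) 0 else pl$ss
      }, numeric(1))
      gate <- stats::quantile(perm_ss, 0.95, type = 1, names = FALSE)
      if (lay$ss <= gate) break
      layers[[l]] <- lay
      Z[lay$R, lay$C] <- Z[lay$R, lay$C] - lay$theta
    }
  })
  bics <- lapply(seq_along(layers), function(i) {
    bicluster(paste0("plaid_", i), "plaid",
              rownames(matrix)[layers[[i]]$R], colnames(matrix)[layers[[i]]$C])
  })
  bicluster_set(bics, source = .source_sig(matrix))
}

#' Combine bicluster sets from several algorithms
#'
#' Concatenation with fresh unique ids (`bc_1`, `bc_2`, ...) and preserved
#' algorithm labels. No deduplication is performed across algorithms.
#'
#' @param sets list of [bicluster_set()]s over the same source matrix.
#' @return A combined [bicluster_set()].
#' @export
combine_bicluster_sets <- function(sets) {
  stopifnot(length(sets) >= 1)
  srcs <- Filter(Negate(is.null), lapply(sets, `[[`, "source"))
  if (length(srcs) > 1) {
    for (s in srcs[-1]) {
      if (!identical(s, srcs[[1]])) stop("bicluster sets come from different source matrices")
    }
  }
  all_b <- unlist(lapply(sets, `[[`, "biclusters"), recursive = FALSE)
  all_b <- lapply(seq_along(all_b), function(i) {
    b <- all_b[[i]]; b$id <- paste0("bc_", i); b
  })
  bicluster_set(all_b, source = if (length(srcs)) srcs[[1]] else NULL)
}

#' Pair-based Jaccard similarity between two biclusters
#'
#' A bicluster is viewed as the set of (gene, sample) pairs it covers. In
#' `"literal"` mode the union is the product of the gene union and sample
#' union sizes, so
#' `J = (|Ga n Gb| * |Sa n Sb|) / (|Ga u Gb| * |Sa u Sb|)`; in
#' `"rectangles"` mode the union is the union of the two rectangles,
#' `|A| + |B| - |A n B|`.
#'
#' @param a,b [bicluster()]s over the same matrix.
#' @param mode `"literal"` (default) or `"rectangles"`.
#' @return A similarity in \eqn{[0, 1]}.
#' @export
bicluster_jaccard <- function(a, b, mode = c("literal", "rectangles")) {
  mode <- match.arg(mode)
  gi <- length(intersect(a$genes, b$genes))
  si <- length(intersect(a$samples, b$samples))
  inter <- gi * si
  if (mode == "literal") {
    gu <- length(union(a$genes, b$genes))
    su <- length(union(a$samples, b$samples))
    uni <- gu * su
  } else {
    uni <- length(a$genes) * length(a$samples) +
      length(b$genes) * length(b$samples) - inter
  }
  if (uni == 0) return(0)
  inter / uni
}

#' Pairwise Jaccard matrix of a bicluster set
#'
#' Symmetric with unit diagonal, rows/columns in input order. An
#' average-linkage ordering for display is attached as the `order` attribute.
#'
#' @param set a [bicluster_set()] with at least 2 members.
#' @inheritParams bicluster_jaccard
#' @return Numeric matrix in \eqn{[0, 1]}.
#' @export
jaccard_matrix <- function(set, mode = c("literal", "rectangles")) {
  mode <- match.arg(mode)
  n <- length(set$biclusters)
  if (n < 2) stop("need at least 2 biclusters")
  ids <- vapply(set$biclusters, `[[`, "", "id")
  J <- diag(1, n)
  dimnames(J) <- list(ids, ids)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      J[i, j] <- J[j, i] <- bicluster_jaccard(set$biclusters[[i]], set$biclusters[[j]], mode)
    }
  }
  hc <- stats::hclust(stats::as.dist(1 - J), method = "average")
  attr(J, "order") <- ids[hc$order]
  J
}
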