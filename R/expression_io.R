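# Readers and writers for the expression matrix, the sample metadata table,
# and the bicluster interchange JSON. All readers validate rather than
# coerce: ids must be unique, counts must be nonnegative integers, category
# levels must be known.

#' Read a raw count matrix
#'
#' TSV: header row of sample ids, first column gene ids, integer counts.
#' MatrixMarket: coordinate triplet file plus two sidecar files holding the
#' row (gene) and column (sample) ids, one per line.
#'
#' @param path path to the TSV or `.mtx` file.
#' @param format `"tsv"` or `"mtx"`.
#' @param row_ids,col_ids sidecar paths for `format = "mtx"`; default
#'   `<path>.rows` / `<path>.cols`.
#' @return Integer matrix, genes in rows, samples in columns.
#' @export
read_counts <- function(path, format = c("tsv", "mtx"),
                        row_ids = paste0(path, ".rows"),
                        col_ids = paste0(path, ".cols")) {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                            quote = "", comment.char = "", colClasses = "character")
    genes <- df[[1]]
    if (anyDuplicated(genes)) {
      stop("duplicated gene id: ", genes[duplicated(genes)][1])
    }
    vals <- as.matrix(df[, -1, drop = FALSE])
    num <- suppressWarnings(matrix(as.numeric(vals), nrow(vals), ncol(vals)))
    bad <- which(is.na(num) | num < 0 | num != round(num), arr.ind = TRUE)
    if (nrow(bad)) {
      stop("non-integer or negative count at gene '", genes[bad[1, 1]],
           "', sample '", colnames(vals)[bad[1, 2]], "': ", vals[bad[1, , drop = FALSE]])
    }
    m <- matrix(as.integer(num), nrow(num), ncol(num),
                dimnames = list(genes, colnames(vals)))
    return(m)
  }
  if (!file.exists(row_ids)) stop("missing row-id sidecar: ", row_ids)
  if (!file.exists(col_ids)) stop("missing column-id sidecar: ", col_ids)
  mm <- as.matrix(Matrix::readMM(path))
  genes <- readLines(row_ids, warn = FALSE)
  samples <- readLines(col_ids, warn = FALSE)
  if (anyDuplicated(genes)) stop("duplicated gene id: ", genes[duplicated(genes)][1])
  if (nrow(mm) != length(genes) || ncol(mm) != length(samples)) {
    stop("MatrixMarket dimensions (", nrow(mm), "x", ncol(mm),
         ") do not match sidecar id counts (", length(genes), "x", length(samples), ")")
  }
  if (any(mm < 0) || any(mm != round(mm))) {
    stop("non-integer or negative count in MatrixMarket file")
  }
  matrix(as.integer(mm), nrow(mm), ncol(mm), dimnames = list(genes, samples))
}

#' Write a count matrix as TSV
#'
#' @param counts integer matrix with dimnames.
#' @param path output path.
#' @export
write_counts <- function(counts, path) {
  df <- data.frame(gene = rownames(counts), counts, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.tissue_levels <- c("colon", "endometrium")
.condition_levels <- c("tumor", "normal")

#' Validate a sample metadata table
#'
#' Required columns: `sample`, `tissue` (colon | endometrium), `condition`
#' (tumor | normal). Optional: `msi` (logical), `os_time` (days, nonnegative),
#' `os_event` (0/1), `cohort`. Survival fields may be missing only for normal
#' samples; an event flag without a time is an error.
#'
#' @param df a data.frame.
#' @return The validated table with class `sample_table`.
#' @export
sample_table <- function(df) {
  req <- c("sample", "tissue", "condition")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("sample table missing required column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample)) stop("duplicated sample id: ", df$sample[duplicated(df$sample)][1])
  bad <- setdiff(unique(df$tissue), .tissue_levels)
  if (length(bad)) stop("unknown tissue level: ", paste(bad, collapse = ", "))
  bad <- setdiff(unique(df$condition), .condition_levels)
  if (length(bad)) stop("unknown condition level: ", paste(bad, collapse = ", "))
  if ("os_event" %in% names(df)) {
    ev <- df$os_event[!is.na(df$os_event)]
    if (!all(ev %in% c(0, 1))) stop("os_event must be 0/1")
    if (!"os_time" %in% names(df)) stop("os_event present without os_time")
    orphan <- !is.na(df$os_event) & df$os_event == 1 & is.na(df$os_time)
    if (any(orphan)) {
      stop("sample with an event but no survival time: ", df$sample[orphan][1])
    }
  }
  if ("os_time" %in% names(df)) {
    if (any(df$os_time < 0, na.rm = TRUE)) stop("negative survival time")
    tum_na <- df$condition == "tumor" & is.na(df$os_time)
    if (any(tum_na)) {
      stop("survival time missing for tumor sample: ", df$sample[tum_na][1])
    }
  }
  class(df) <- c("sample_table", "data.frame")
  df
}

#' Read a sample metadata TSV
#'
#' @param path TSV with a header row; see [sample_table()] for the schema.
#' @return A `sample_table`.
#' @export
read_sample_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          quote = "", comment.char = "", stringsAsFactors = FALSE)
  sample_table(df)
}

#' @export
print.sample_table <- function(x, ...) {
  cat("sample_table:", nrow(x), "samples\n")
  print(table(tissue = x$tissue, condition = x$condition))
  invisible(x)
}

#' Write / read bicluster sets as JSON
#'
#' The interchange format is a JSON list of
#' `{id, algorithm, genes[], samples[]}` objects; write-then-read is the
#' identity. `read_biclusters()` can optionally validate membership against a
#' count matrix.
#'
#' @param set a [bicluster_set()].
#' @param path file path.
#' @export
write_biclusters <- function(set, path) {
  stopifnot(inherits(set, "bicluster_set"))
  recs <- lapply(set$biclusters, function(b) {
    list(id = b$id, algorithm = b$algorithm,
         genes = as.list(b$genes), samples = as.list(b$samples))
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_biclusters
#' @param matrix optional count matrix; when given, every gene and sample id
#'   must be present in its dimnames.
#' @return `read_biclusters()` returns a [bicluster_set()].
#' @export
read_biclusters <- function(path, matrix = NULL) {
  recs <- jsonlite::read_json(path)
  bics <- lapply(recs, function(r) {
    bicluster(id = r$id, algorithm = r$algorithm,
              genes = unlist(r$genes), samples = unlist(r$samples))
  })
  set <- bicluster_set(bics)
  if (!is.null(matrix)) {
    for (b in set$biclusters) {
      badg <- setdiff(b$genes, rownames(matrix))
      bads <- setdiff(b$samples, colnames(matrix))
      if (length(badg) || length(bads)) {
        stop("bicluster ", b$id, " references unknown ids: ",
             paste(c(badg, bads), collapse = ", "))
      }
    }
  }
  set
}
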