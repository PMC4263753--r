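#' Quantification-cycle (Cq) table
#'
#' The universal input container of the package: a samples-by-genes matrix of
#' quantification cycles together with per-sample design annotations
#' (condition, time, replicate) and per-gene role annotations
#' (candidate reference vs target).
#'
#' Cq values must be finite and inside (0, 45); values outside the typical
#' instrument range 5--40 trigger a warning but are kept. Under the default
#' `"strict"` missing-data policy any missing cell is an error naming the
#' offending sample and gene; under `"drop-sample"` every sample (row) with a
#' missing cell is removed with a warning.
#'
#' @param values numeric matrix of Cq values, rows = samples, columns = genes.
#'   Row and column names are the sample and gene identifiers and must be
#'   unique; at least 2 samples and 2 genes are required.
#' @param sample_meta optional data frame with columns `sample_id`,
#'   `condition`, `time_hours`, `replicate`, one row per sample (matched to
#'   `rownames(values)` by `sample_id`). Missing columns are filled with `NA`.
#' @param gene_meta optional data frame with columns `gene_id` and `role`
#'   (`"candidate_reference"` or `"target"`). By default every gene is a
#'   candidate reference.
#' @param missing missing-data policy, `"strict"` (default) or
#'   `"drop-sample"`.
#'
#' @return an object of class `cq_table`: a list with elements `cq` (the
#'   matrix), `samples` and `genes` (the two annotation data frames).
#' @export
#' @examples
#' m <- matrix(c(20, 21, 22, 23, 24, 25), nrow = 3,
#'             dimnames = list(paste0("s", 1:3), c("gA", "gB")))
#' cq_table(m)
cq_table <- function(values, sample_meta = NULL, gene_meta = NULL,
                     missing = c("strict", "drop-sample")) {
  missing <- match.arg(missing)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must have sample row names and gene column names")

  if (anyNA(values)) {
    bad <- which(is.na(values), arr.ind = TRUE)
    if (missing == "strict") {
      stop(sprintf(
        "missing Cq for sample '%s', gene '%s' (strict missing-data policy)",
        rownames(values)[bad[1L, 1L]], colnames(values)[bad[1L, 2L]]))
    }
    drop <- unique(bad[, 1L])
    warning(sprintf("dropping %d sample(s) with missing Cq: %s",
                    length(drop),
                    paste(rownames(values)[drop], collapse = ", ")))
    values <- values[-drop, , drop = FALSE]
  }

  if (anyDuplicated(rownames(values)))
    stop("duplicated sample identifiers")
  if (anyDuplicated(colnames(values)))
    stop("duplicated gene identifiers")
  if (nrow(values) < 2L || ncol(values) < 2L)
    stop("a cq_table needs at least 2 samples and 2 genes")
  if (any(!is.finite(values)))
    stop("all Cq values must be finite")
  if (any(values <= 0 | values >= 45))
    stop("Cq values must lie strictly between 0 and 45 cycles")
  if (any(values < 5 | values > 40))
    warning("Cq values outside the usual 5-40 cycle range")

  sample_meta <- normalize_sample_meta(sample_meta, rownames(values))
  gene_meta <- normalize_gene_meta(gene_meta, colnames(values))

  structure(list(cq = values, samples = sample_meta, genes = gene_meta),
            class = "cq_table")
}

normalize_sample_meta <- function(meta, ids) {
  if (is.null(meta)) {
    meta <- data.frame(sample_id = ids, condition = NA_character_,
                       time_hours = NA_real_, replicate = NA_integer_,
                       stringsAsFactors = FALSE)
  } else {
    meta <- as.data.frame(meta)
    if (!"sample_id" %in% names(meta))
      stop("sample_meta must have a 'sample_id' column")
    for (col in c("condition", "time_hours", "replicate"))
      if (!col %in% names(meta)) meta[[col]] <- NA
    miss <- setdiff(ids, meta$sample_id)
    if (length(miss))
      stop("sample_meta missing entries for: ", paste(miss, collapse = ", "))
    meta <- meta[match(ids, meta$sample_id),
                 c("sample_id", "condition", "time_hours", "replicate")]
  }
  rownames(meta) <- NULL
  meta
}

normalize_gene_meta <- function(meta, ids) {
  if (is.null(meta)) {
    meta <- data.frame(gene_id = ids, role = "candidate_reference",
                       stringsAsFactors = FALSE)
  } else {
    meta <- as.data.frame(meta)
    if (!"gene_id" %in% names(meta))
      stop("gene_meta must have a 'gene_id' column")
    if (!"role" %in% names(meta)) meta$role <- "candidate_reference"
    bad <- setdiff(unique(meta$role), c("candidate_reference", "target"))
    if (length(bad))
      stop("unknown gene role(s): ", paste(bad, collapse = ", "))
    miss <- setdiff(ids, meta$gene_id)
    if (length(miss))
      stop("gene_meta missing entries for: ", paste(miss, collapse = ", "))
    meta <- meta[match(ids, meta$gene_id), c("gene_id", "role")]
  }
  rownames(meta) <- NULL
  meta
}

#' @export
print.cq_table <- function(x, ...) {
  cat(sprintf("cq_table: %d samples x %d genes (%d candidate reference, %d target)\n",
              nrow(x$cq), ncol(x$cq),
              sum(x$genes$role == "candidate_reference"),
              sum(x$genes$role == "target")))
  cat(sprintf("Cq range: %.2f - %.2f cycles\n", min(x$cq), max(x$cq)))
  invisible(x)
}

#' Extract the Cq matrix from a cq_table
#'
#' @param x a [cq_table()] (a plain matrix is passed through).
#' @param genes optional character vector restricting the columns.
#' @return numeric matrix, rows = samples, columns = genes.
#' @export
cq_values <- function(x, genes = NULL) {
  m <- if (inherits(x, "cq_table")) x$cq else as.matrix(x)
  if (!is.null(genes)) {
    miss <- setdiff(genes, colnames(m))
    if (length(miss))
      stop("gene(s) not in table: ", paste(miss, collapse = ", "))
    m <- m[, genes, drop = FALSE]
  }
  m
}

#' @rdname cq_values
#' @export
sample_info <- function(x) {
  stopifnot(inherits(x, "cq_table"))
  x$samples
}

#' @rdname cq_values
#' @export
gene_info <- function(x) {
  stopifnot(inherits(x, "cq_table"))
  x$genes
}

#' Genes of a given role
#'
#' @param x a [cq_table()].
#' @return character vector of gene identifiers.
#' @export
candidate_genes <- function(x) {
  gene_info(x)$gene_id[gene_info(x)$role == "candidate_reference"]
}

#' @rdname candidate_genes
#' @export
target_genes <- function(x) {
  gene_info(x)$gene_id[gene_info(x)$role == "target"]
}
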