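#' Read a Cq table from delimited text
#'
#' Two layouts are supported. `wide` (the canonical layout, matching
#' spreadsheet exports of qPCR instruments): one row per sample, a
#' `sample_id` column, optional design columns (`condition`, `time_hours`,
#' `replicate`), and one numeric column per gene. `long`: one row per
#' (sample, gene) measurement with columns named by `sample_col`, `gene_col`
#' and `cq_col`, plus optional design columns; long input is converted to the
#' wide matrix on read.
#'
#' Duplicate (sample, gene) pairs in long layout are an error unless
#' `average_technical_reps = TRUE`, in which case duplicates are collapsed to
#' their arithmetic mean Cq (technical-replicate averaging is opt-in; the
#' default assumes pre-averaged input).
#'
#' @param path file path of a TSV/CSV file.
#' @param layout `"wide"` or `"long"`.
#' @param sep field separator (default tab).
#' @param sample_col,gene_col,cq_col column names used by the long layout.
#' @param gene_roles optional named character vector `gene_id -> role` used to
#'   mark target genes.
#' @param average_technical_reps collapse duplicate (sample, gene) rows in
#'   long layout by arithmetic mean.
#' @param missing missing-data policy passed to [cq_table()].
#' @return a [cq_table()].
#' @export
read_cq_table <- function(path, layout = c("wide", "long"), sep = "\t",
                          sample_col = "sample_id", gene_col = "gene_id",
                          cq_col = "cq", gene_roles = NULL,
                          average_technical_reps = FALSE,
                          missing = "strict") {
  layout <- match.arg(layout)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.delim(path, sep = sep, stringsAsFactors = FALSE,
                   check.names = FALSE)
  design_cols <- c("condition", "time_hours", "replicate")

  if (layout == "wide") {
    if (!sample_col %in% names(df))
      stop("wide layout needs a '", sample_col, "' column")
    ids <- as.character(df[[sample_col]])
    gene_cols <- setdiff(names(df), c(sample_col, design_cols))
    m <- as.matrix(df[, gene_cols, drop = FALSE])
    storage.mode(m) <- "double"
    rownames(m) <- ids
    meta <- data.frame(sample_id = ids, stringsAsFactors = FALSE)
    for (col in design_cols)
      meta[[col]] <- if (col %in% names(df)) df[[col]] else NA
  } else {
    need <- c(sample_col, gene_col, cq_col)
    miss <- setdiff(need, names(df))
    if (length(miss))
      stop("long layout needs column(s): ", paste(miss, collapse = ", "))
    key <- paste(df[[sample_col]], df[[gene_col]], sep = "\r")
    if (anyDuplicated(key)) {
      if (!average_technical_reps) {
        dup <- key[duplicated(key)][1L]
        stop("duplicated (sample, gene) pair: ",
             gsub("\r", " / ", dup),
             " (use average_technical_reps = TRUE to average)")
      }
      cqm <- tapply(as.numeric(df[[cq_col]]), key, mean)
      first <- !duplicated(key)
      df <- df[first, , drop = FALSE]
      df[[cq_col]] <- as.numeric(cqm[key[first]])
    }
    ids <- unique(as.character(df[[sample_col]]))
    gene_ids <- unique(as.character(df[[gene_col]]))
    m <- matrix(NA_real_, length(ids), length(gene_ids),
                dimnames = list(ids, gene_ids))
    m[cbind(as.character(df[[sample_col]]), as.character(df[[gene_col]]))] <-
      as.numeric(df[[cq_col]])
    meta <- df[!duplicated(df[[sample_col]]),
               intersect(c(sample_col, design_cols), names(df)),
               drop = FALSE]
    names(meta)[names(meta) == sample_col] <- "sample_id"
    for (col in design_cols)
      if (!col %in% names(meta)) meta[[col]] <- NA
    meta <- meta[match(ids, meta$sample_id), ]
  }

  gmeta <- NULL
  if (!is.null(gene_roles)) {
    gmeta <- data.frame(gene_id = colnames(m),
                        role = ifelse(colnames(m) %in% names(gene_roles),
                                      gene_roles[colnames(m)],
                                      "candidate_reference"),
                        stringsAsFactors = FALSE)
  }
  cq_table(m, sample_meta = meta, gene_meta = gmeta, missing = missing)
}

#' Write a Cq table to wide delimited text
#'
#' Writes the sample identifier, any non-missing design columns, and one
#' column per gene. [read_cq_table()] on the result restores the table.
#'
#' @param x a [cq_table()].
#' @param path output path.
#' @param sep field separator.
#' @export
write_cq_table <- function(x, path, sep = "\t") {
  stopifnot(inherits(x, "cq_table"))
  meta <- x$samples
  keep <- c("sample_id",
            names(meta)[-1L][colSums(!is.na(meta[-1L])) > 0L])
  df <- cbind(meta[, keep, drop = FALSE], as.data.frame(x$cq))
  write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an analysis result table
#'
#' Writes any result data frame as TSV (floats rendered at a configurable
#' precision, default 3 decimals) or as JSON (full precision, suitable for
#' lossless round-tripping with [read_report()]).
#'
#' @param x a data frame.
#' @param path output path.
#' @param format `"tsv"` or `"json"`.
#' @param digits decimal places for numeric columns in TSV output; `NA`
#'   writes full precision. Ignored for JSON.
#' @export
write_report <- function(x, path, format = c("tsv", "json"), digits = 3) {
  format <- match.arg(format)
  x <- as.data.frame(x)
  if (format == "tsv") {
    out <- x
    if (!is.na(digits))
      for (j in seq_along(out))
        if (is.double(out[[j]])) out[[j]] <- round(out[[j]], digits)
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    jsonlite::write_json(x, path, digits = NA, dataframe = "columns",
                         na = "null")
  }
  invisible(path)
}

#' @rdname write_report
#' @return `read_report()` returns the data frame.
#' @export
read_report <- function(path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv") {
    read.delim(path, stringsAsFactors = FALSE)
  } else {
    as.data.frame(jsonlite::fromJSON(path))
  }
}
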