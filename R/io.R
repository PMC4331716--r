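#' Read a delimited expression matrix
#'
#' Expects a header row of sample identifiers, one row per gene with the
#' gene/probe identifier in the first column, and a numeric body of
#' normalized log-scale intensities.  Values must be complete: any
#' missing or non-numeric cell is a parse error naming the offending
#' gene and sample.
#'
#' @param path file path.
#' @param delimiter field delimiter (default tab; use "," for CSV).
#' @return numeric genes x samples matrix with gene ids as row names and
#'   sample ids as column names, in file order.
#' @export
read_expression_table <- function(path, delimiter = "\t") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = delimiter,
                          check.names = FALSE, colClasses = "character",
                          quote = "\"", comment.char = "")
  if (ncol(df) < 2L)
    stop("expression table needs a gene-id column plus >= 1 sample column",
         call. = FALSE)
  gene_ids <- df[[1L]]
  if (anyDuplicated(gene_ids))
    stop("duplicate gene id(s): ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "),
         call. = FALSE)
  body <- as.matrix(df[-1L])
  values <- suppressWarnings(array(as.numeric(body), dim = dim(body)))
  if (anyNA(values)) {
    bad <- which(is.na(values), arr.ind = TRUE)[1L, ]
    stop("non-numeric value '", body[bad[1L], bad[2L]], "' at gene '",
         gene_ids[bad[1L]], "', sample '", colnames(df)[-1L][bad[2L]], "'",
         call. = FALSE)
  }
  dimnames(values) <- list(gene_ids, colnames(df)[-1L])
  values
}

#' Write an expression matrix as delimited text
#'
#' Inverse of [read_expression_table()]; the first column is named
#' `gene_id`.
#'
#' @param x numeric matrix with gene row names and sample column names.
#' @inheritParams read_expression_table
#' @export
write_expression_table <- function(x, path, delimiter = "\t") {
  df <- data.frame(gene_id = rownames(x), x, check.names = FALSE)
  write.table(df, path, sep = delimiter, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample-to-stage labels
#'
#' Two-column delimited file with a header: sample id, stage label.  The
#' stage order defaults to first appearance in the file; pass
#' `stage_order` to override (e.g. when the file lists stages
#' interleaved).
#'
#' @inheritParams read_expression_table
#' @param stage_order optional character vector of stage labels in
#'   biological order.
#' @return a [stage_design()].
#' @export
read_stage_labels <- function(path, delimiter = "\t", stage_order = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = delimiter,
                          check.names = FALSE, colClasses = "character")
  if (ncol(df) < 2L)
    stop("label file needs two columns: sample id, stage", call. = FALSE)
  stage_design(stats::setNames(df[[2L]], df[[1L]]),
               stage_order = stage_order)
}

#' @rdname read_stage_labels
#' @param design a [stage_design()] to serialize.
#' @export
write_stage_labels <- function(design, path, delimiter = "\t") {
  df <- data.frame(sample_id = design$sample_ids,
                   stage = design$stage_labels[design$stage])
  write.table(df, path, sep = delimiter, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a ranked gene table
#'
#' Tab-delimited, one header row, the ten ranked-record columns in fixed
#' order (`rank`, `gene_id`, `direction`, `de_total`, `level_errors`,
#' `distinct_lines`, `p`, `q`, `svde`, `degenerate`), floating point
#' values at 6 significant digits.  Deterministic: identical input
#' reproduces the file byte for byte.
#'
#' @param records data frame from [rank_and_filter()].
#' @inheritParams read_expression_table
#' @export
write_ranked_table <- function(records, path, delimiter = "\t") {
  cols <- c("rank", "gene_id", "direction", "de_total", "level_errors",
            "distinct_lines", "p", "q", "svde", "degenerate")
  stopifnot(all(cols %in% names(records)))
  out <- records[cols]
  for (col in c("p", "q", "svde"))
    out[[col]] <- ifelse(is.na(out[[col]]), "NA",
                         format(signif(out[[col]], 6), trim = TRUE))
  write.table(out, path, sep = delimiter, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a synthetic dataset to delimited files
#'
#' Emits `<prefix>_matrix.tsv`, `<prefix>_labels.tsv` and
#' `<prefix>_truth.tsv` (gene id, archetype), the same formats the
#' readers consume.
#'
#' @param dataset a [make_dataset()] result.
#' @param prefix output path prefix.
#' @return character vector of the three paths written.
#' @export
write_dataset <- function(dataset, prefix) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  paths <- paste0(prefix, c("_matrix.tsv", "_labels.tsv", "_truth.tsv"))
  write_expression_table(dataset$x, paths[1L])
  write_stage_labels(dataset$design, paths[2L])
  write.table(dataset$truth, paths[3L], sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(paths)
}
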