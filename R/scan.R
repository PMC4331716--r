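#' Candidate discriminating errors at one level
#'
#' At level `k` the union of stages 1..k (the lower group, in canonical
#' order) is separated from stages k+1..N.  Every lower-group sample --
#' including samples already masked at earlier levels -- defines a
#' candidate discriminating line at its own expression value.  For an
#' ascending gene a candidate's error counts the unmasked lower-group
#' samples strictly above the line plus the unmasked upper-group samples
#' strictly below it; for a descending gene the inequalities are reversed.
#' Samples whose value equals the line contribute no error.
#'
#' @param values numeric vector of expression values, one per sample, in
#'   the design's input sample order (or named by sample id).
#' @param design a [stage_design()].
#' @param level integer level k in 1..N-1.
#' @param direction `"ascending"` or `"descending"`.
#' @param masked integer vector of canonical sample numbers excluded from
#'   error counting (samples charged at earlier levels).
#' @return data frame with one row per candidate in canonical order:
#'   `sample_number`, `sample_id`, `stage`, `error`.
#' @seealso [select_line()], [scan_gene()]
#' @export
candidate_errors <- function(values, design, level,
                             direction = c("ascending", "descending"),
                             masked = integer()) {
  design <- check_design(design)
  direction <- match_direction(direction)
  if (length(level) != 1L || !is.finite(level) || level < 1L ||
      level > design$n_stages - 1L)
    stop("`level` must be a single integer in 1..N-1", call. = FALSE)
  values <- check_values(values, design)
  v <- values[design$canonical]
  st <- canonical_stage(design)
  S <- design$n_samples
  if (length(masked) && (any(masked < 1L) || any(masked > S)))
    stop("`masked` must hold canonical sample numbers in 1..S",
         call. = FALSE)
  lower <- st <= level
  unmasked <- !seq_len(S) %in% masked
  asc <- direction == "ascending"
  err <- vapply(which(lower), function(c) {
    if (asc)
      sum(unmasked & lower & v > v[c]) + sum(unmasked & !lower & v < v[c])
    else
      sum(unmasked & lower & v < v[c]) + sum(unmasked & !lower & v > v[c])
  }, integer(1))
  data.frame(sample_number = which(lower),
             sample_id = design$sample_ids[design$canonical][lower],
             stage = st[lower],
             error = err)
}

#' Select the discriminating line among level candidates
#'
#' The line with the fewest discriminating errors wins.  When several
#' candidates tie at the minimum: candidates from the same stage are
#' resolved to the lowest canonical sample number; candidates from
#' different stages give priority to the highest stage, then the lowest
#' sample number within it.
#'
#' @param candidates data frame with columns `sample_number`, `stage`,
#'   `error`, as returned by [candidate_errors()].
#' @return list with `sample_number`, `stage`, `error` of the selected
#'   line.
#' @export
select_line <- function(candidates) {
  if (!NROW(candidates))
    stop("no candidates to select from", call. = FALSE)
  stopifnot(all(c("sample_number", "stage", "error") %in% names(candidates)))
  min_err <- min(candidates$error)
  tied <- candidates[candidates$error == min_err, , drop = FALSE]
  tied <- tied[tied$stage == max(tied$stage), , drop = FALSE]
  pick <- tied[which.min(tied$sample_number), , drop = FALSE]
  list(sample_number = pick$sample_number[[1L]],
       stage = pick$stage[[1L]],
       error = pick$error[[1L]])
}

#' Run one full level process: scan, select, mask
#'
#' Convenience around [candidate_errors()] and [select_line()] that also
#' reports `new_error_samples`, the canonical numbers of the unmasked
#' samples on the wrong side of the selected line -- exactly the samples
#' a full scan would add to the mask before the next level.
#'
#' @inheritParams candidate_errors
#' @return list with `candidates` (the [candidate_errors()] table),
#'   `selected` (the [select_line()] result) and `new_error_samples`.
#' @export
level_scan <- function(values, design, level,
                       direction = c("ascending", "descending"),
                       masked = integer()) {
  design <- check_design(design)
  direction <- match_direction(direction)
  cand <- candidate_errors(values, design, level, direction, masked)
  sel <- select_line(cand)
  values <- check_values(values, design)
  v <- values[design$canonical]
  st <- canonical_stage(design)
  lower <- st <= level
  unmasked <- !seq_len(design$n_samples) %in% masked
  vl <- v[sel$sample_number]
  wrong <- if (direction == "ascending")
    (lower & v > vl) | (!lower & v < vl)
  else
    (lower & v < vl) | (!lower & v > vl)
  list(candidates = cand, selected = sel,
       new_error_samples = which(unmasked & wrong))
}

#' Score one gene by its total discriminating error
#'
#' Runs the N-1 level processes for a single gene: at each level the
#' discriminating line with the fewest errors is selected (ties broken by
#' stage then sample number, see [select_line()]), the samples on the
#' wrong side of the selected line are masked for all later levels (each
#' sample is charged at most once), and `DE_total` is the sum of the
#' selected errors.  A gene whose expression is constant across all
#' samples is flagged `degenerate`: its DE_total of 0 is an artifact of
#' the equality rule, not evidence of monotonicity, and degenerate genes
#' are excluded from ranking.
#'
#' @inheritParams candidate_errors
#' @param gene_id optional identifier attached to the result.
#' @return An object of class `monotone_score`: list with `gene_id`,
#'   `direction`, `de_total`, `level_errors` (length N-1),
#'   `line_numbers` (canonical sample numbers of the selected lines),
#'   `line_samples` (their sample ids), `distinct_lines`, `masked`
#'   (canonical numbers of all charged samples), `degenerate`.
#' @examples
#' ex <- example_profile()
#' scan_gene(ex$values, ex$design)  # DE_total = 3, levels 2,0,1,0
#' @export
scan_gene <- function(values, design,
                      direction = c("ascending", "descending"),
                      gene_id = NULL) {
  design <- check_design(design)
  direction <- match_direction(direction)
  values <- check_values(values, design)
  v <- values[design$canonical]
  res <- .scan_gene_cpp(v, canonical_stage(design), design$n_stages,
                        direction == "ascending")
  ids_can <- design$sample_ids[design$canonical]
  structure(
    list(gene_id = gene_id,
         direction = direction,
         de_total = res$de_total,
         level_errors = res$level_errors,
         line_numbers = res$line_numbers,
         line_samples = ids_can[res$line_numbers],
         distinct_lines = length(unique(res$line_numbers)),
         masked = which(res$masked),
         degenerate = all(values == values[[1L]])),
    class = "monotone_score")
}

#' @export
print.monotone_score <- function(x, ...) {
  cat("Monotone score", if (!is.null(x$gene_id)) paste0("[", x$gene_id, "]"),
      "(", x$direction, ")\n")
  cat("  DE_total:", x$de_total,
      " level errors:", paste(x$level_errors, collapse = "+"),
      " distinct lines:", x$distinct_lines,
      if (x$degenerate) " [degenerate]", "\n")
  invisible(x)
}

#' Score every gene of an expression matrix
#'
#' Applies [scan_gene()] to each row of a genes x samples matrix for the
#' requested direction(s), preserving gene order.
#'
#' @param x numeric genes x samples matrix; column names (if present) must
#'   match the design's sample ids, and rows are genes.
#' @param design a [stage_design()].
#' @param directions character vector, subset of
#'   `c("ascending", "descending")`.
#' @return data frame with one row per gene per direction: `gene_id`,
#'   `direction`, `de_total`, `level_errors` (comma-separated string),
#'   `line_numbers` (comma-separated canonical numbers),
#'   `distinct_lines`, `degenerate`.
#' @export
score_matrix <- function(x, design,
                         directions = c("ascending", "descending")) {
  design <- check_design(design)
  directions <- match.arg(directions, .directions, several.ok = TRUE)
  x <- check_matrix(x, design)
  xc <- x[, design$canonical, drop = FALSE]
  st <- canonical_stage(design)
  degenerate <- apply(x, 1L, function(r) all(r == r[[1L]]))
  out <- lapply(directions, function(dir) {
    res <- .scan_matrix_cpp(xc, st, design$n_stages, dir == "ascending")
    data.frame(
      gene_id = rownames(x),
      direction = dir,
      de_total = res$de_total,
      level_errors = apply(res$level_errors, 1L, paste, collapse = ","),
      line_numbers = apply(res$line_numbers, 1L, paste, collapse = ","),
      distinct_lines = apply(res$line_numbers, 1L,
                             function(r) length(unique(r))),
      degenerate = degenerate,
      row.names = NULL)
  })
  do.call(rbind, out)
}

check_matrix <- function(x, design) {
  if (!is.matrix(x) || !is.numeric(x))
    stop("`x` must be a numeric genes x samples matrix", call. = FALSE)
  if (any(!is.finite(x)))
    stop("expression matrix contains missing or non-finite values",
         call. = FALSE)
  if (ncol(x) != design$n_samples)
    stop("matrix has ", ncol(x), " samples but the design has ",
         design$n_samples, call. = FALSE)
  if (!is.null(colnames(x))) {
    if (!setequal(colnames(x), design$sample_ids))
      stop("matrix column names do not match the design's sample ids",
           call. = FALSE)
    x <- x[, design$sample_ids, drop = FALSE]
  }
  if (is.null(rownames(x)))
    rownames(x) <- paste0("g", seq_len(nrow(x)))
  if (anyDuplicated(rownames(x)))
    stop("duplicate gene ids: ",
         paste(unique(rownames(x)[duplicated(rownames(x))]), collapse = ", "),
         call. = FALSE)
  x
}
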