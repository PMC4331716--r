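#' Build a stage design with canonical sample numbering
#'
#' A stage design fixes the ordered stages (Stage One first), assigns every
#' sample to exactly one stage, and numbers the samples 1..S in canonical,
#' stage-major order: all Stage One samples first, then Stage Two, and so
#' on, preserving the input order within a stage.  The canonical sample
#' number is the identity used everywhere downstream -- discriminating
#' lines are reported by it and ties between candidate lines are broken
#' by it.
#'
#' @param assignment named character vector or list mapping each sample id
#'   to its stage label; names are the sample ids.
#' @param stage_order character vector giving the stages in biological
#'   order (earliest first).  Defaults to the order in which stages first
#'   appear in `assignment`.
#' @param sample_order character vector fixing the input order of the
#'   samples.  Defaults to the order of `assignment`.
#' @return An object of class `stage_design`: a list with elements
#'   `stage_labels`, `sample_ids` (input order), `stage` (integer stage
#'   index per sample, input order), `canonical` (input positions in
#'   canonical order), `sample_number` (canonical number per input
#'   position), `stage_sizes`, `n_stages`, `n_samples`.
#' @examples
#' d <- stage_design(c(s1 = "A", s2 = "B", s3 = "A", s4 = "B"),
#'                   stage_order = c("A", "B"))
#' d$sample_number  # both A samples numbered before both B samples
#' @export
stage_design <- function(assignment, stage_order = NULL, sample_order = NULL) {
  assignment <- unlist(assignment)
  if (is.null(names(assignment)) || any(!nzchar(names(assignment))))
    stop("`assignment` must be named by sample id", call. = FALSE)
  if (anyDuplicated(names(assignment)))
    stop("duplicate sample ids in assignment: ",
         paste(unique(names(assignment)[duplicated(names(assignment))]),
               collapse = ", "), call. = FALSE)
  if (is.null(sample_order)) sample_order <- names(assignment)
  missing_samples <- setdiff(sample_order, names(assignment))
  if (length(missing_samples))
    stop("samples without a stage label: ",
         paste(missing_samples, collapse = ", "), call. = FALSE)
  assignment <- assignment[sample_order]
  if (is.null(stage_order)) stage_order <- unique(unname(assignment))
  unknown <- setdiff(unique(assignment), stage_order)
  if (length(unknown))
    stop("stage label(s) not in `stage_order`: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  stage <- match(unname(assignment), stage_order)
  sizes <- tabulate(stage, nbins = length(stage_order))
  if (any(sizes == 0L))
    stop("empty stage(s): ",
         paste(stage_order[sizes == 0L], collapse = ", "), call. = FALSE)
  if (length(stage_order) < 2L)
    stop("a stage design needs at least 2 stages", call. = FALSE)
  canonical <- order(stage)            # stable: input order kept within stage
  sample_number <- integer(length(stage))
  sample_number[canonical] <- seq_along(stage)
  structure(
    list(stage_labels = stage_order,
         sample_ids = sample_order,
         stage = stage,
         canonical = canonical,
         sample_number = sample_number,
         stage_sizes = sizes,
         n_stages = length(stage_order),
         n_samples = length(stage)),
    class = "stage_design")
}

#' @export
print.stage_design <- function(x, ...) {
  cat("Stage design:", x$n_samples, "samples in", x$n_stages, "stages\n")
  cat(paste0(x$stage_labels, " (n=", x$stage_sizes, ")", collapse = " < "),
      "\n")
  invisible(x)
}

# stage index vector in canonical order (non-decreasing 1..N)
canonical_stage <- function(design) design$stage[design$canonical]

check_design <- function(design) {
  if (!inherits(design, "stage_design"))
    stop("`design` must be a `stage_design` object", call. = FALSE)
  design
}

check_values <- function(values, design) {
  if (length(values) != design$n_samples)
    stop("`values` must have one entry per sample (",
         design$n_samples, ")", call. = FALSE)
  if (!is.numeric(values) || any(!is.finite(values)))
    stop("`values` must be finite numeric expression intensities",
         call. = FALSE)
  nm <- names(values)
  if (!is.null(nm)) {
    if (!setequal(nm, design$sample_ids))
      stop("names of `values` do not match the design's sample ids",
           call. = FALSE)
    values <- values[design$sample_ids]
  }
  unname(values)
}
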