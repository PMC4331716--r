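#' A small worked-example profile
#'
#' A 20-sample, 5-stage ascending profile (stage sizes 3, 3, 6, 4, 4) with
#' two planted anomalies: the 1st sample (Stage One) is displaced upward
#' into the Stage Three range, and the 14th sample (Stage Four) is
#' displaced downward into the Stage One range.  Scanned ascending it
#' yields candidate errors (7, 2, 2) at Level One, (3, 3, 4, 0, 2, 1) at
#' Level Two after masking, (3, 9, 10, 6, 8, 7, 2, 4, 5, 1, 3, 1) at
#' Level Three, selected lines at samples 2, 4, 10 and 16, per-level
#' errors (2, 0, 1, 0) and DE_total = 3 -- each displaced sample is
#' charged exactly once even though it stays on the wrong side of later
#' lines.
#'
#' @return list with `values` (named numeric vector of 20 expression
#'   values) and `design` (the matching [stage_design()]).
#' @examples
#' ex <- example_profile()
#' scan_gene(ex$values, ex$design)
#' @export
example_profile <- function() {
  values <- c(3.2, 1.2, 1.0,            # Stage One (1st displaced high)
              2.2, 1.8, 2.0,            # Stage Two
              3.4, 2.9, 2.8, 3.9, 3.0, 3.6,  # Stage Three
              3.7, 1.1, 4.5, 4.8,       # Stage Four (14th displaced low)
              5.2, 5.5, 5.8, 6.0)       # Stage Five
  ids <- sprintf("s%02d", seq_along(values))
  names(values) <- ids
  stages <- rep(c("S1", "S2", "S3", "S4", "S5"), c(3, 3, 6, 4, 4))
  design <- stage_design(stats::setNames(stages, ids),
                         stage_order = c("S1", "S2", "S3", "S4", "S5"))
  list(values = values, design = design)
}
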