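#' Run the full monotone-gene selection pipeline
#'
#' Convenience wrapper tying the pieces together: scores every gene in
#' the requested direction(s) ([score_matrix()]), builds one shared
#' permutation null pool ([build_null_pool()]), converts the observed
#' DE_total values to permutation p- and q-values, computes SVDE for
#' every non-degenerate gene ([svde_matrix()]), and ranks and filters
#' ([rank_and_filter()]).  All randomness (label permutations, SVDE
#' noise) is drawn from the RNG stream seeded by `seed`, so identical
#' inputs and seed give identical output.
#'
#' @inheritParams score_matrix
#' @param B number of label permutations (default 500).
#' @param M number of SVDE noise replicates (default 100).
#' @inheritParams rank_and_filter
#' @param seed optional integer seed.
#' @param verbose emit progress messages to the message stream.
#' @return An object of class `mfselector_result`: list with `ranked`
#'   (the filtered, ranked record table), `scores` (all genes' scores
#'   with `p`, `q` and `svde` attached) and the call parameters.
#' @examples
#' ds <- make_dataset("ascending", seed = 1)
#' res <- mfselect(ds$x, ds$design, "ascending", B = 50, M = 20, seed = 1,
#'                 de_max = NULL, p_max = NULL, require_distinct = FALSE)
#' head(res$ranked)
#' @export
mfselect <- function(x, design,
                     directions = c("ascending", "descending"),
                     B = 500L, M = 100L, de_max = 7, p_max = 1e-5,
                     require_distinct = TRUE, seed = NULL,
                     verbose = FALSE) {
  design <- check_design(design)
  directions <- match.arg(directions, .directions, several.ok = TRUE)
  x <- check_matrix(x, design)
  if (!is.null(seed)) set.seed(seed)
  say <- function(...) if (verbose) message(...)
  say("scoring ", nrow(x), " genes, directions: ",
      paste(directions, collapse = ", "))
  scores <- score_matrix(x, design, directions)
  say("building null pool: B = ", B)
  pool <- build_null_pool(x, design, B)
  parts <- lapply(directions, function(dir) {
    sc <- scores[scores$direction == dir, , drop = FALSE]
    sc$p <- de_p_value(sc$de_total, pool, dir)
    sc$q <- de_q_value(sc$de_total, pool, dir)
    say("SVDE (", dir, "): M = ", M)
    sc$svde <- unname(svde_matrix(x, design, dir, M = M))
    sc
  })
  scored <- do.call(rbind, parts)
  ranked <- rank_and_filter(scored, p = scored$p, q = scored$q,
                            svde = scored$svde, de_max = de_max,
                            p_max = p_max,
                            require_distinct = require_distinct)
  say("retained ", nrow(ranked), " of ", nrow(scored), " gene records")
  structure(list(ranked = ranked, scores = scored,
                 params = list(B = B, M = M, de_max = de_max,
                               p_max = p_max,
                               require_distinct = require_distinct,
                               seed = seed)),
            class = "mfselector_result")
}

#' @export
print.mfselector_result <- function(x, ...) {
  cat("Monotone gene selection:", nrow(x$ranked), "records retained",
      "(B =", x$params$B, ", M =", x$params$M, ")\n")
  print(utils::head(x$ranked, 10L))
  if (nrow(x$ranked) > 10L) cat("...", nrow(x$ranked) - 10L, "more rows\n")
  invisible(x)
}
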