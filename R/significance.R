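#' Permutation null pool of DE_total values
#'
#' Permutes the stage labels of the whole design `B` times; within one
#' permutation the same shuffled labels are applied to every gene and both
#' the ascending and the descending DE_total are computed, so the two
#' nulls are coupled exactly as the observed statistics are.  The pooled
#' G x B null values are the reference distribution for [de_p_value()]
#' and [de_q_value()].
#'
#' @inheritParams score_matrix
#' @param B number of label permutations (default 500).
#' @param seed optional integer seed for the permutation stream.
#' @return An object of class `null_pool`: list with `ascending` and
#'   `descending` (G x B integer matrices of null DE_total values),
#'   `B`, `G`, `gene_ids`.
#' @export
build_null_pool <- function(x, design, B = 500L, seed = NULL) {
  design <- check_design(design)
  if (length(B) != 1L || !is.finite(B) || B < 1L)
    stop("`B` must be a positive integer", call. = FALSE)
  B <- as.integer(B)
  x <- check_matrix(x, design)
  if (!is.null(seed)) set.seed(seed)
  S <- design$n_samples
  st_can <- canonical_stage(design)   # stage sizes are permutation-invariant
  asc <- matrix(NA_integer_, nrow(x), B)
  des <- matrix(NA_integer_, nrow(x), B)
  for (b in seq_len(B)) {
    stage_b <- design$stage[sample.int(S)]   # permuted class labels
    ord <- order(stage_b)                    # canonical order under them
    xb <- x[, ord, drop = FALSE]
    asc[, b] <- .scan_de_cpp(xb, st_can, design$n_stages, TRUE)
    des[, b] <- .scan_de_cpp(xb, st_can, design$n_stages, FALSE)
  }
  structure(list(ascending = asc, descending = des, B = B, G = nrow(x),
                 gene_ids = rownames(x)),
            class = "null_pool")
}

#' @export
print.null_pool <- function(x, ...) {
  cat("Permutation null pool:", x$G, "genes x", x$B, "permutations\n")
  invisible(x)
}

pool_values <- function(pool, direction) {
  if (!inherits(pool, "null_pool"))
    stop("`pool` must come from build_null_pool()", call. = FALSE)
  as.vector(pool[[match_direction(direction)]])
}

#' Permutation p-value of an observed DE_total
#'
#' `p = #\{null DE_total <= observed\} / (G * B)`, pooling the null values
#' across all genes and all permutations.  The smallest attainable
#' non-zero p is `1 / (G * B)`; an observed value below every pooled null
#' is reported as exactly 0 (the printed granularity of the permutation
#' scheme, no pseudocount is added).
#'
#' @param observed numeric vector of observed DE_total values.
#' @param pool a [build_null_pool()] result over the same genes.
#' @param direction `"ascending"` or `"descending"`.
#' @return numeric vector of p-values in `[0, 1]`.
#' @export
de_p_value <- function(observed, pool, direction = "ascending") {
  nulls <- sort(pool_values(pool, direction))
  findInterval(observed, nulls) / length(nulls)
}

#' Permutation q-value of the observed DE_total values
#'
#' For gene g, `q_g = #\{null <= obs_g\} / (#\{observed <= obs_g\} * B)`,
#' capped at 1.  The whole observed vector must be supplied because the
#' denominator counts observed values at least as extreme as gene g's.
#' No step-up monotonicity adjustment is applied; the raw capped ratio is
#' returned.
#'
#' @param observed numeric vector of ALL genes' observed DE_total values
#'   (same gene order as the pool).
#' @inheritParams de_p_value
#' @return numeric vector of q-values in `[0, 1]`.
#' @export
de_q_value <- function(observed, pool, direction = "ascending") {
  if (length(observed) != pool$G)
    stop("`observed` must hold all ", pool$G, " genes' values",
         call. = FALSE)
  nulls <- sort(pool_values(pool, direction))
  num <- findInterval(observed, nulls)
  den <- findInterval(observed, sort(observed)) * pool$B
  pmin(num / den, 1)
}

#' Sample variance for discriminating error (SVDE)
#'
#' Perturbation-stability index used to order genes that share the same
#' DE_total.  The gene's standard deviation sigma is computed across all
#' samples, i.i.d. normal noise with mean 0 and sd sigma/10 is added to
#' every sample value, and DE_total is recomputed from scratch (fresh
#' masks).  Over `M` such replicates,
#' `SVDE = mean((DE_i - DE_org)^2)` -- the spread of the perturbed
#' DE_total values around the *original* value, not around their own
#' mean.  A gene whose stages are separated by wide gaps relative to its
#' overall spread keeps its DE_total under noise (small SVDE); a gene
#' with near-touching stages flips often (large SVDE).  Constant genes
#' are refused: sigma = 0 would make SVDE trivially 0.
#'
#' @inheritParams scan_gene
#' @param M number of noise replicates (default 100).
#' @param seed optional integer seed for the noise stream.
#' @return An object of class `svde_result`: list with `gene_id`,
#'   `direction`, `de_org`, `perturbed` (the M replicate DE_total
#'   values), `svde`, `noise_sd`, `M`.
#' @export
svde <- function(values, design, direction = c("ascending", "descending"),
                 M = 100L, seed = NULL, gene_id = NULL) {
  design <- check_design(design)
  direction <- match_direction(direction)
  values <- check_values(values, design)
  if (length(M) != 1L || !is.finite(M) || M < 1L)
    stop("`M` must be a positive integer", call. = FALSE)
  M <- as.integer(M)
  if (all(values == values[[1L]]))
    stop("degenerate gene: zero variance, SVDE is undefined",
         call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  S <- design$n_samples
  noise_sd <- sd(values) / 10
  de_org <- scan_gene(values, design, direction)$de_total
  noise <- matrix(rnorm(M * S, mean = 0, sd = noise_sd), nrow = M)
  perturbed <- sweep(noise, 2L, values, `+`)
  de_i <- .scan_de_cpp(perturbed[, design$canonical, drop = FALSE],
                       canonical_stage(design), design$n_stages,
                       direction == "ascending")
  structure(list(gene_id = gene_id, direction = direction,
                 de_org = de_org, perturbed = de_i,
                 svde = mean((de_i - de_org)^2),
                 noise_sd = noise_sd, M = M),
            class = "svde_result")
}

#' @export
print.svde_result <- function(x, ...) {
  cat("SVDE", if (!is.null(x$gene_id)) paste0("[", x$gene_id, "]"),
      "(", x$direction, "): ", format(x$svde),
      " (DE_org ", x$de_org, ", M = ", x$M, ")\n", sep = "")
  invisible(x)
}

#' SVDE for every gene of a matrix
#'
#' Applies [svde()] row-wise.  When `seed` is given, gene g uses its own
#' seed `seed + g - 1`, so one gene's noise stream does not depend on how
#' many replicates earlier genes consumed.  Degenerate (constant) genes
#' get `NA`.
#'
#' @inheritParams score_matrix
#' @inheritParams svde
#' @param direction a single direction.
#' @return numeric vector of SVDE values (NA for degenerate genes), named
#'   by gene id.
#' @export
svde_matrix <- function(x, design, direction = c("ascending", "descending"),
                        M = 100L, seed = NULL) {
  design <- check_design(design)
  direction <- match_direction(direction)
  x <- check_matrix(x, design)
  out <- rep(NA_real_, nrow(x))
  for (g in seq_len(nrow(x))) {
    if (all(x[g, ] == x[g, 1L])) next
    out[g] <- svde(x[g, ], design, direction, M = M,
                   seed = if (is.null(seed)) NULL else seed + g - 1L)$svde
  }
  names(out) <- rownames(x)
  out
}

#' Rank and filter monotone genes
#'
#' Degenerate genes are dropped, then the filters are applied:
#' `de_total <= de_max`, permutation `p < p_max`, and (optionally) all
#' N-1 selected discriminating lines distinct -- the filter that rejects
#' partially ordered profiles.  Survivors are sorted by DE_total
#' (ascending), then SVDE (ascending), then original gene order, and
#' given dense ranks 1..K within each direction.
#'
#' @param scores data frame from [score_matrix()] (one or both
#'   directions).
#' @param p,q optional numeric vectors aligned with the rows of `scores`
#'   (recycled per direction if `scores` holds both directions and the
#'   vectors are per-gene).
#' @param svde optional numeric vector of SVDE values aligned like `p`.
#' @param de_max maximum DE_total kept (default 7); `NULL` disables.
#' @param p_max keep genes with `p < p_max` (default 1e-5); `NULL`
#'   disables (also disabled when no p-values are supplied).
#' @param require_distinct require N-1 distinct discriminating lines
#'   (default `TRUE`).
#' @return data frame of ranked records with columns `rank`, `gene_id`,
#'   `direction`, `de_total`, `level_errors`, `distinct_lines`, `p`, `q`,
#'   `svde`, `degenerate`.
#' @export
rank_and_filter <- function(scores, p = NULL, q = NULL, svde = NULL,
                            de_max = 7, p_max = 1e-5,
                            require_distinct = TRUE) {
  need <- c("gene_id", "direction", "de_total", "level_errors",
            "distinct_lines", "degenerate")
  stopifnot(all(need %in% names(scores)))
  align <- function(val, what) {
    if (is.null(val)) return(rep(NA_real_, nrow(scores)))
    if (length(val) == nrow(scores)) return(unname(val))
    # per-gene vector with both directions present: recycle by gene id
    if (!is.null(names(val)) && all(scores$gene_id %in% names(val)))
      return(unname(val[scores$gene_id]))
    stop("`", what, "` cannot be aligned with `scores`", call. = FALSE)
  }
  tab <- data.frame(scores[need[1:5]],
                    p = align(p, "p"), q = align(q, "q"),
                    svde = align(svde, "svde"),
                    degenerate = scores$degenerate,
                    .order = seq_len(nrow(scores)))
  n_levels <- lengths(strsplit(tab$level_errors, ","))
  keep <- !tab$degenerate
  if (!is.null(de_max)) keep <- keep & tab$de_total <= de_max
  if (!is.null(p_max) && !is.null(p)) keep <- keep & tab$p < p_max
  if (require_distinct) keep <- keep & tab$distinct_lines == n_levels
  tab <- tab[keep, , drop = FALSE]
  cols <- c("rank", "gene_id", "direction", "de_total", "level_errors",
            "distinct_lines", "p", "q", "svde", "degenerate")
  if (!nrow(tab)) {
    tab$rank <- integer()
    return(tab[cols])
  }
  out <- lapply(split(tab, factor(tab$direction, unique(tab$direction))),
                function(d) {
    svde_key <- ifelse(is.na(d$svde), Inf, d$svde)  # missing SVDE sorts last
    d <- d[order(d$de_total, svde_key, d$.order), , drop = FALSE]
    d$rank <- seq_len(nrow(d))
    d
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[cols]
}
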