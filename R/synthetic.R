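#' Archetype defaults for the synthetic benchmark
#'
#' The benchmark distinguishes nine archetypes of (near-)monotone genes.
#' `good_distinct` and `good_close` are strictly ordered with wide
#' resp. narrow gaps between stages; `slightly`, `moderately` and
#' `severely` have increasing inter-stage overlap; `outliers_slight` and
#' `outliers_severe` are good-type genes with at most 6% of samples
#' displaced a little or across several stages; `partial_close` and
#' `partial_far` have one whole stage displaced out of the stage order,
#' near or far.  The defaults below are the generator's stated world: the
#' archetypes are described only qualitatively in the literature, so the
#' within-stage standard deviations (as multiples of the inter-stage mean
#' step) are fixed once so that the described overlap ordering holds.
#'
#' @param base_step inter-stage mean increment (expression units,
#'   log scale; default 2).
#' @return data frame with columns `archetype`, `n_genes` (counts of the
#'   standard 120-gene dataset) and `within_sd`.
#' @export
archetype_defaults <- function(base_step = 2) {
  data.frame(
    archetype = c("good_distinct", "good_close", "slightly",
                  "outliers_slight", "outliers_severe", "moderately",
                  "severely", "partial_close", "partial_far"),
    n_genes   = c(10L, 10L, 20L, 10L, 10L, 20L, 20L, 10L, 10L),
    within_sd = base_step *
      c(0.15, 0.35, 0.55, 0.15, 0.15, 0.85, 1.30, 0.15, 0.15))
}

outlier_budget <- function(n_samples) floor(0.06 * n_samples)

#' Generate one synthetic staged-expression gene
#'
#' Draws one sample per design position around its stage mean
#' (`mean = stage * base_step`, reversed for descending genes) with the
#' archetype's within-stage standard deviation, then applies the
#' archetype's distortion: outlier archetypes displace up to
#' `floor(0.06 * S)` randomly chosen samples by 1.5 steps
#' (`outliers_slight`) or 4 steps (`outliers_severe`) with random sign;
#' partial archetypes move one whole stage's mean out of the stage order,
#' overshooting the adjacent stage's mean by 0.7 steps (`partial_close`)
#' or 3 steps (`partial_far`).  Randomness comes from the current RNG
#' state; seed with `set.seed()` for reproducibility.
#'
#' @param archetype one of the nine archetype names, see
#'   [archetype_defaults()].
#' @param direction `"ascending"` or `"descending"`.
#' @param stage_sizes integer vector of per-stage sample counts
#'   (default 5 stages of 10).
#' @param base_step inter-stage mean increment; must be non-zero.
#' @param within_sd within-stage standard deviation; default per
#'   archetype from [archetype_defaults()].
#' @param outlier_indices sample positions to displace (outlier
#'   archetypes); default: 1..budget positions drawn at random.  More
#'   than `floor(0.06 * S)` positions is an error.
#' @param displaced_stage stage index to displace (partial archetypes);
#'   default: drawn at random.
#' @return numeric vector of `sum(stage_sizes)` expression values in
#'   stage-major order, with attributes `outlier_indices` or
#'   `displaced_stage` recording the applied distortion.
#' @export
make_gene <- function(archetype, direction = c("ascending", "descending"),
                      stage_sizes = rep(10L, 5L), base_step = 2,
                      within_sd = NULL, outlier_indices = NULL,
                      displaced_stage = NULL) {
  defaults <- archetype_defaults(base_step)
  archetype <- match.arg(archetype, defaults$archetype)
  direction <- match_direction(direction)
  if (!is.numeric(base_step) || base_step == 0)
    stop("`base_step` must be non-zero: equal stage means realize no ",
         "archetype", call. = FALSE)
  if (any(stage_sizes < 1L) || length(stage_sizes) < 2L)
    stop("`stage_sizes` must be >= 1 for at least 2 stages", call. = FALSE)
  N <- length(stage_sizes)
  S <- sum(stage_sizes)
  if (is.null(within_sd))
    within_sd <- defaults$within_sd[defaults$archetype == archetype]
  mu <- seq_len(N) * base_step
  if (direction == "descending") mu <- rev(mu)
  step_sign <- sign(mu[2L] - mu[1L])
  stage_of <- rep(seq_len(N), stage_sizes)

  out_attr <- list()
  if (archetype %in% c("partial_close", "partial_far")) {
    if (is.null(displaced_stage)) displaced_stage <- sample.int(N, 1L)
    if (displaced_stage < 1L || displaced_stage > N)
      stop("`displaced_stage` out of range", call. = FALSE)
    overshoot <- if (archetype == "partial_close") 0.7 else 3
    side <- if (displaced_stage == 1L) "after"
            else if (displaced_stage == N) "before"
            else sample(c("before", "after"), 1L)
    mu[displaced_stage] <- if (side == "after")
      mu[displaced_stage + 1L] + step_sign * overshoot * base_step
    else
      mu[displaced_stage - 1L] - step_sign * overshoot * base_step
    out_attr$displaced_stage <- displaced_stage
  }

  values <- rnorm(S, mean = mu[stage_of], sd = within_sd)

  if (archetype %in% c("outliers_slight", "outliers_severe")) {
    budget <- outlier_budget(S)
    if (budget < 1L)
      stop("design too small for outlier archetypes (budget 0)",
           call. = FALSE)
    if (is.null(outlier_indices))
      outlier_indices <- sample.int(S, sample.int(budget, 1L))
    if (length(outlier_indices) > budget)
      stop("outlier budget exceeded: ", length(outlier_indices), " > ",
           budget, " (less than 6% of ", S, " samples)", call. = FALSE)
    if (any(outlier_indices < 1L | outlier_indices > S))
      stop("`outlier_indices` out of range", call. = FALSE)
    disp <- if (archetype == "outliers_slight") 1.5 else 4
    signs <- sample(c(-1, 1), length(outlier_indices), replace = TRUE)
    values[outlier_indices] <- mu[stage_of[outlier_indices]] +
      signs * disp * base_step +
      rnorm(length(outlier_indices), sd = within_sd)
    out_attr$outlier_indices <- sort(outlier_indices)
  }

  attributes(values) <- c(attributes(values), out_attr)
  values
}

#' Generate the 120-gene synthetic benchmark dataset
#'
#' Builds the standard benchmark: 50 samples in 5 equal stages and 120
#' genes covering the nine archetypes with fixed counts (20 each of
#' `slightly`, `moderately`, `severely`; 10 of each of the other six),
#' laid out in blocks: genes 1-10 `good_distinct`, 11-20 `good_close`,
#' 21-40 `slightly`, 41-50 `outliers_slight`, 51-60 `outliers_severe`,
#' 61-80 `moderately`, 81-100 `severely`, 101-110 `partial_close`,
#' 111-120 `partial_far`.  The ascending and descending variants are the
#' conventional `s50_Asc` / `s50_Des` designs.
#'
#' @inheritParams make_gene
#' @param seed optional integer seed; a fixed seed reproduces the dataset
#'   exactly.
#' @return An object of class `synthetic_dataset`: list with `x` (genes x
#'   samples matrix, dimnames `g1..g120` / `s1..s50`), `design` (a
#'   [stage_design()] with stages `S1..S5`), `truth` (data frame
#'   `gene_id`, `archetype`) and `direction`.
#' @examples
#' ds <- make_dataset("ascending", seed = 1)
#' table(ds$truth$archetype)
#' @export
make_dataset <- function(direction = c("ascending", "descending"),
                         seed = NULL, stage_sizes = rep(10L, 5L),
                         base_step = 2) {
  direction <- match_direction(direction)
  if (!is.null(seed)) set.seed(seed)
  defaults <- archetype_defaults(base_step)
  archetypes <- rep(defaults$archetype, defaults$n_genes)
  S <- sum(stage_sizes)
  x <- t(vapply(archetypes, function(a)
    as.numeric(make_gene(a, direction, stage_sizes, base_step)),
    numeric(S)))
  rownames(x) <- paste0("g", seq_along(archetypes))
  colnames(x) <- paste0("s", seq_len(S))
  stages <- paste0("S", rep(seq_along(stage_sizes), stage_sizes))
  design <- stage_design(stats::setNames(stages, colnames(x)),
                         stage_order = paste0("S", seq_along(stage_sizes)))
  structure(list(x = x, design = design,
                 truth = data.frame(gene_id = rownames(x),
                                    archetype = archetypes,
                                    row.names = NULL),
                 direction = direction),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("Synthetic staged-expression dataset (", x$direction, "): ",
      nrow(x$x), " genes x ", ncol(x$x), " samples, ",
      x$design$n_stages, " stages\n", sep = "")
  print(table(x$truth$archetype))
  invisible(x)
}
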