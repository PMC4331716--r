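#' Stage weights for the Cuzick trend test
#'
#' Ascending trends use weights `w_i = i` (Stage One lightest); descending
#' trends use the reversed weights `w_i = N - i + 1`, so that a gene
#' following the probed trend always produces a large weighted rank sum
#' and a positive z-score.
#'
#' @param direction `"ascending"` or `"descending"`.
#' @param n_stages number of ordered stages N (>= 2).
#' @return integer vector of N stage weights.
#' @export
cuzick_weights <- function(direction = c("ascending", "descending"),
                           n_stages) {
  direction <- match_direction(direction)
  if (length(n_stages) != 1L || !is.finite(n_stages) || n_stages < 2L)
    stop("`n_stages` must be a single integer >= 2", call. = FALSE)
  n_stages <- as.integer(n_stages)
  if (direction == "ascending") seq_len(n_stages) else rev(seq_len(n_stages))
}

#' Cuzick rank test for trend across ordered stages
#'
#' Wilcoxon-type comparator for the discriminating-error scan.  Every
#' sample gets the rank `r_i` of its expression value among all `n`
#' samples (midranks for ties) and the weight `z_i` of its stage.  The
#' statistic is the weighted rank sum `T = sum(z_i * r_i)` with
#' `E(T) = n(n+1)/2 * sum(w_j p_j)` and
#' `Var(T) = n^2 (n+1)/12 * (sum(w_j^2 p_j) - (sum(w_j p_j))^2)`,
#' where `p_j` is the proportion of samples in stage j; the z-score
#' `(T - E(T)) / sqrt(Var(T))` is referred to the standard normal.  The
#' variance is the no-ties form; heavy ties make the test conservative.
#'
#' @inheritParams scan_gene
#' @param alternative `"greater"` (one-sided in the probed trend
#'   direction, the default) or `"two.sided"`.
#' @return An object of class `htest` with the z-score as `statistic`,
#'   the p-value, and `estimate` holding T, E(T) and Var(T).
#' @examples
#' ex <- example_profile()
#' cuzick_test(ex$values, ex$design, "ascending")
#' @export
cuzick_test <- function(values, design,
                        direction = c("ascending", "descending"),
                        alternative = c("greater", "two.sided")) {
  design <- check_design(design)
  direction <- match_direction(direction)
  alternative <- match.arg(alternative)
  values <- check_values(values, design)
  n <- design$n_samples
  N <- design$n_stages
  w <- cuzick_weights(direction, N)
  p_j <- design$stage_sizes / n
  if (max(p_j) == 1)
    stop("all samples in one stage: Var(T) is undefined", call. = FALSE)
  r <- rank(values)                       # midranks for ties
  z_i <- w[design$stage]
  T_stat <- sum(z_i * r)
  ET <- n * (n + 1) / 2 * sum(w * p_j)
  VarT <- n^2 * (n + 1) / 12 * (sum(w^2 * p_j) - sum(w * p_j)^2)
  z <- (T_stat - ET) / sqrt(VarT)
  p <- switch(alternative,
              greater = pnorm(z, lower.tail = FALSE),
              two.sided = 2 * pnorm(abs(z), lower.tail = FALSE))
  structure(
    list(statistic = c(z = z),
         p.value = p,
         estimate = c(T = T_stat, `E(T)` = ET, `Var(T)` = VarT),
         alternative = alternative,
         method = paste("Cuzick trend test,", direction, "weights"),
         data.name = paste(n, "samples in", N, "ordered stages")),
    class = "htest")
}

#' Cuzick test for every gene of a matrix
#'
#' @inheritParams score_matrix
#' @inheritParams cuzick_test
#' @param direction a single direction.
#' @return data frame with one row per gene: `gene_id`, `direction`,
#'   `T`, `z`, `p`.
#' @export
cuzick_matrix <- function(x, design,
                          direction = c("ascending", "descending"),
                          alternative = c("greater", "two.sided")) {
  design <- check_design(design)
  direction <- match_direction(direction)
  alternative <- match.arg(alternative)
  x <- check_matrix(x, design)
  res <- apply(x, 1L, function(v) {
    h <- cuzick_test(v, design, direction, alternative)
    c(h$estimate[["T"]], h$statistic[["z"]], h$p.value)
  })
  data.frame(gene_id = rownames(x), direction = direction,
             T = res[1L, ], z = res[2L, ], p = res[3L, ], row.names = NULL)
}
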