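# Independent brute-force reference for the level scan.  Deliberately
# written without any shared code with the package internals: explicit
# per-candidate double loops, id-set mask, literal tie rules.

oracle_errors <- function(v, stage, k, ascending, mask_idx) {
  lower_idx <- which(stage <= k)
  errs <- integer(length(lower_idx))
  for (ci in seq_along(lower_idx)) {
    line <- v[lower_idx[ci]]
    e <- 0L
    for (s in seq_along(v)) {
      if (s %in% mask_idx) next
      if (stage[s] <= k) {       # lower group: must not exceed the line
        if (ascending && v[s] > line) e <- e + 1L
        if (!ascending && v[s] < line) e <- e + 1L
      } else {                   # upper group: must not undercut it
        if (ascending && v[s] < line) e <- e + 1L
        if (!ascending && v[s] > line) e <- e + 1L
      }
    }
    errs[ci] <- e
  }
  errs
}

# full scan with naive per-level recount; v/stage in canonical order
oracle_scan <- function(v, stage, N, ascending = TRUE) {
  mask_idx <- integer()
  level_errors <- integer(N - 1)
  lines <- integer(N - 1)
  for (k in seq_len(N - 1)) {
    cand_idx <- which(stage <= k)
    errs <- oracle_errors(v, stage, k, ascending, mask_idx)
    best <- 1L
    for (ci in seq_along(cand_idx)) {
      if (errs[ci] < errs[best]) best <- ci
      else if (errs[ci] == errs[best] &&
               stage[cand_idx[ci]] > stage[cand_idx[best]]) best <- ci
      # equal error, equal stage: keep the earlier (lower sample number)
    }
    line <- v[cand_idx[best]]
    for (s in seq_along(v)) {
      if (s %in% mask_idx) next
      wrong <- if (stage[s] <= k) {
        if (ascending) v[s] > line else v[s] < line
      } else {
        if (ascending) v[s] < line else v[s] > line
      }
      if (wrong) mask_idx <- c(mask_idx, s)
    }
    level_errors[k] <- errs[best]
    lines[k] <- cand_idx[best]
  }
  list(level_errors = level_errors, lines = lines,
       de_total = sum(level_errors))
}

# random small instance; returns values (input order), design, and the
# canonical-order view used by the oracle
random_instance <- function(S_max = 15L, N_choices = 3:5) {
  N <- if (length(N_choices) == 1L) N_choices else sample(N_choices, 1L)
  repeat {
    sizes <- as.vector(stats::rmultinom(1L, sample(N:S_max, 1L),
                                        rep(1, N)))
    if (all(sizes >= 1L)) break
  }
  S <- sum(sizes)
  ids <- paste0("s", seq_len(S))
  stages <- paste0("T", rep(seq_len(N), sizes))
  perm <- sample.int(S)           # scramble the input sample order
  design <- stage_design(stats::setNames(stages[perm], ids),
                         stage_order = paste0("T", seq_len(N)))
  # duplicate values now and then to exercise the equality rule
  vals <- round(stats::rnorm(S, rep(seq_len(N), sizes)), 1)
  values <- stats::setNames(vals[perm], ids)
  list(values = values, design = design, N = N, S = S)
}

# canonical-order view of an instance, as the oracle expects it
canonical_view <- function(inst) {
  list(v = unname(inst$values)[inst$design$canonical],
       stage = inst$design$stage[inst$design$canonical])
}
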