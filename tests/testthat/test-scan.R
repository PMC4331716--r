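# The worked example fixture: 5 stages (3/3/6/4/4), one Stage One sample
# displaced high, one Stage Four sample displaced low.

test_that("worked example reproduces all level-wise candidate arrays", {
  ex <- example_profile()

  l1 <- level_scan(ex$values, ex$design, 1)
  expect_equal(l1$candidates$error, c(7L, 2L, 2L))
  expect_equal(l1$selected$sample_number, 2L)   # lowest number among ties
  expect_equal(l1$selected$error, 2L)
  expect_setequal(l1$new_error_samples, c(1L, 14L))

  l2 <- level_scan(ex$values, ex$design, 2, masked = l1$new_error_samples)
  expect_equal(l2$candidates$error, c(3L, 3L, 4L, 0L, 2L, 1L))
  expect_equal(l2$selected$sample_number, 4L)
  expect_equal(l2$selected$error, 0L)
  expect_length(l2$new_error_samples, 0L)

  l3 <- level_scan(ex$values, ex$design, 3, masked = l1$new_error_samples)
  expect_equal(l3$candidates$error,
               c(3L, 9L, 10L, 6L, 8L, 7L, 2L, 4L, 5L, 1L, 3L, 1L))
  expect_equal(min(l3$candidates$error), 1L)
  expect_equal(l3$selected$sample_number, 10L)  # ties at 10 and 12

  s <- scan_gene(ex$values, ex$design, "ascending")
  expect_equal(s$level_errors, c(2L, 0L, 1L, 0L))
  expect_equal(s$line_numbers, c(2L, 4L, 10L, 16L))
  expect_equal(s$de_total, 3L)
  expect_equal(s$distinct_lines, 4L)
  expect_false(s$degenerate)
})

test_that("select_line applies the stage-then-number tie rules", {
  # same stage: lowest sample number
  cand <- data.frame(sample_number = 1:3, stage = c(1L, 1L, 1L),
                     error = c(7L, 2L, 2L))
  expect_equal(select_line(cand)$sample_number, 2L)
  # different stages: highest stage wins
  cand2 <- data.frame(sample_number = c(1L, 5L), stage = c(1L, 2L),
                      error = c(1L, 1L))
  expect_equal(select_line(cand2)$sample_number, 5L)
  # highest stage, then lowest number within it
  cand3 <- data.frame(sample_number = c(2L, 4L, 6L), stage = c(1L, 2L, 2L),
                      error = c(3L, 3L, 3L))
  expect_equal(select_line(cand3)$sample_number, 4L)
  # single candidate is itself
  expect_equal(select_line(data.frame(sample_number = 9L, stage = 1L,
                                      error = 5L))$sample_number, 9L)
  expect_error(select_line(data.frame()), "no candidates")
})

test_that("values equal to the line contribute no error", {
  d <- stage_design(c(s1 = "A", s2 = "A", s3 = "B", s4 = "B"),
                    stage_order = c("A", "B"))
  # lower-group duplicate of the line and an upper-group tie both free
  ce <- candidate_errors(c(2, 2, 2, 3), d, 1, "ascending")
  expect_equal(ce$error, c(0L, 0L))
})

test_that("perfectly separated stage blocks give DE_total 0", {
  d <- stage_design(setNames(paste0("T", rep(1:3, each = 4)),
                             paste0("s", 1:12)))
  s <- scan_gene(seq_len(12), d, "ascending")
  expect_equal(s$de_total, 0L)
  expect_equal(s$distinct_lines, 2L)  # N-1 distinct lines
  # one-candidate perfect split
  d2 <- stage_design(setNames(c("A", rep("B", 4)), paste0("s", 1:5)))
  expect_equal(candidate_errors(c(1, 2, 3, 4, 5), d2, 1)$error, 0L)
})

test_that("constant genes are flagged degenerate", {
  d <- stage_design(setNames(paste0("T", rep(1:2, each = 3)),
                             paste0("s", 1:6)))
  s <- scan_gene(rep(1.5, 6), d)
  expect_true(s$degenerate)
  expect_error(scan_gene(c(1, 2, NA, 4, 5, 6), d), "finite")
})

test_that("scan matches the brute-force oracle on random instances", {
  set.seed(101)
  for (i in 1:60) {
    inst <- random_instance()
    cv <- canonical_view(inst)
    for (asc in c(TRUE, FALSE)) {
      dir <- if (asc) "ascending" else "descending"
      got <- scan_gene(inst$values, inst$design, dir)
      want <- oracle_scan(cv$v, cv$stage, inst$N, asc)
      expect_identical(got$de_total, want$de_total)
      expect_identical(got$level_errors, want$level_errors)
      expect_identical(got$line_numbers, want$lines)
    }
  }
})

test_that("candidate_errors matches a per-candidate double-loop count", {
  set.seed(202)
  for (i in 1:25) {
    inst <- random_instance(S_max = 10L, N_choices = 3L)
    cv <- canonical_view(inst)
    mask <- sample(inst$S, sample(0:2, 1L))
    k <- sample(inst$N - 1L, 1L)
    got <- candidate_errors(inst$values, inst$design, k, "ascending", mask)
    expect_equal(got$error,
                 oracle_errors(cv$v, cv$stage, k, TRUE, mask))
  }
})

test_that("scan invariants hold: bounds, mirror symmetry, degradation", {
  set.seed(303)
  for (i in 1:40) {
    inst <- random_instance()
    s_asc <- scan_gene(inst$values, inst$design, "ascending")
    # 0 <= DE_total <= S: each sample charged at most once
    expect_gte(s_asc$de_total, 0L)
    expect_lte(s_asc$de_total, inst$S)
    expect_equal(s_asc$de_total, sum(s_asc$level_errors))
    expect_equal(length(s_asc$masked), s_asc$de_total)
    # mirror symmetry: ascending on v == descending on -v
    s_mir <- scan_gene(-inst$values, inst$design, "descending")
    expect_identical(s_mir$de_total, s_asc$de_total)
    expect_identical(s_mir$level_errors, s_asc$level_errors)
  }
  # monotone degradation: swapping a correctly ordered low-stage /
  # high-stage pair never decreases DE_total
  set.seed(404)
  for (i in 1:40) {
    inst <- random_instance()
    st <- inst$design$stage
    lo <- which(st == 1L)
    hi <- which(st == inst$N)
    pair <- expand.grid(lo = lo, hi = hi)
    pair <- pair[inst$values[pair$lo] <= inst$values[pair$hi], ]
    if (!nrow(pair)) next
    pick <- pair[sample(nrow(pair), 1L), ]
    v2 <- inst$values
    v2[c(pick$lo, pick$hi)] <- v2[c(pick$hi, pick$lo)]
    expect_gte(scan_gene(v2, inst$design)$de_total,
               scan_gene(inst$values, inst$design)$de_total)
  }
})

test_that("score_matrix scores per gene and direction, preserving order", {
  d <- stage_design(setNames(paste0("T", rep(1:3, each = 2)),
                             paste0("s", 1:6)))
  x <- rbind(g_up = 1:6, g_flat = rep(2, 6), g_down = 6:1)
  colnames(x) <- paste0("s", 1:6)
  sc <- score_matrix(x, d)
  expect_equal(nrow(sc), 6L)
  expect_equal(unique(sc$gene_id), c("g_up", "g_flat", "g_down"))
  expect_true(all(sc$degenerate[sc$gene_id == "g_flat"]))
  asc <- sc[sc$direction == "ascending", ]
  expect_equal(asc$de_total[asc$gene_id == "g_up"], 0L)
  des <- sc[sc$direction == "descending", ]
  expect_equal(des$de_total[des$gene_id == "g_down"], 0L)
  # column-name mismatch is an input error
  x2 <- x; colnames(x2) <- paste0("z", 1:6)
  expect_error(score_matrix(x2, d), "do not match")
  # scan_gene agrees with the matrix path
  s1 <- scan_gene(x["g_up", ], d, "ascending")
  expect_equal(asc$de_total[1L], s1$de_total)
})
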