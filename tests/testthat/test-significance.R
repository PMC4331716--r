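toy_design <- function(sizes = c(3L, 3L, 3L)) {
  stage_design(setNames(paste0("T", rep(seq_along(sizes), sizes)),
                        paste0("s", seq_len(sum(sizes)))))
}

fake_pool <- function(asc, desc = asc, B) {
  structure(list(ascending = asc, descending = desc, B = B,
                 G = nrow(asc), gene_ids = paste0("g", seq_len(nrow(asc)))),
            class = "null_pool")
}

test_that("null pool has G x B values per direction and is seed-stable", {
  d <- toy_design()
  set.seed(1)
  x <- matrix(rnorm(3 * 9), 3, 9,
              dimnames = list(paste0("g", 1:3), paste0("s", 1:9)))
  pool <- build_null_pool(x, d, B = 2, seed = 11)
  expect_equal(dim(pool$ascending), c(3L, 2L))
  expect_equal(dim(pool$descending), c(3L, 2L))
  pool2 <- build_null_pool(x, d, B = 2, seed = 11)
  expect_identical(pool, pool2)
  expect_error(build_null_pool(x, d, B = 0), "positive")
  # permuted-label nulls of an ordered gene are mostly > 0
  xo <- matrix(seq_len(9), 1, dimnames = list("g1", paste0("s", 1:9)))
  po <- build_null_pool(xo, d, B = 200, seed = 3)
  expect_true(all(po$ascending >= 0))
  expect_gt(mean(po$ascending > 0), 0.8)
})

test_that("p-values match hand-enumerated pooled counts", {
  pool <- fake_pool(matrix(c(1L, 3L, 4L, 6L), 2, 2), B = 2)  # G=2, B=2
  expect_equal(de_p_value(3, pool), 2 / 4)
  expect_equal(de_p_value(0, pool), 0)    # below every null
  expect_equal(de_p_value(6, pool), 1)    # at or above every null
  expect_equal(de_p_value(c(0, 3, 6), pool), c(0, 0.5, 1))
})

test_that("q-values match hand-enumerated counts and are capped", {
  # G=3, B=2; pooled nulls {0,2,2,4,5,7}
  pool <- fake_pool(matrix(c(0L, 2L, 2L, 4L, 5L, 7L), 3, 2), B = 2)
  obs <- c(1, 4, 4)
  # gene 1: nulls<=1 -> 1; obs<=1 -> 1; q = 1/(1*2)
  # genes 2,3: nulls<=4 -> 4; obs<=4 -> 3; q = 4/(3*2)
  expect_equal(de_q_value(obs, pool), c(1 / 2, 4 / 6, 4 / 6))
  # unique best observed value: q = k/B
  expect_equal(de_q_value(c(0, 9, 9), pool)[1L], 1 / 2)  # k=1 null <= 0
  # cap at 1
  expect_equal(de_q_value(c(9, 9, 0), pool)[1L], 1)
  expect_error(de_q_value(c(1, 2), pool), "all 3 genes")
  # all observed equal: q == p for every gene
  obs_eq <- c(4, 4, 4)
  expect_equal(de_q_value(obs_eq, pool), de_p_value(obs_eq, pool))
})

test_that("p and q are monotone in the observed value", {
  d <- toy_design()
  set.seed(5)
  x <- matrix(rnorm(20 * 9), 20, 9,
              dimnames = list(paste0("g", 1:20), paste0("s", 1:9)))
  pool <- build_null_pool(x, d, B = 30, seed = 6)
  obs <- score_matrix(x, d, "ascending")$de_total
  p <- de_p_value(obs, pool)
  q <- de_q_value(obs, pool)
  o <- order(obs)
  expect_true(all(diff(p[o]) >= 0))
  expect_true(all(q <= 1) && all(q >= 0))
  expect_true(all(p >= 0) && all(p <= 1))
})

test_that("svde follows its defining identity and refuses degenerate genes", {
  d <- toy_design(c(2L, 2L, 2L))
  v <- c(1, 1.1, 5, 5.1, 9, 9.2)       # gaps huge relative to sd/10
  r <- svde(v, d, "ascending", M = 100, seed = 42)
  expect_equal(r$de_org, 0L)
  expect_equal(r$svde, mean((r$perturbed - r$de_org)^2))
  expect_equal(r$svde, 0)              # >10-sd excursions would be needed
  expect_equal(r$noise_sd, sd(v) / 10)
  expect_error(svde(rep(2, 6), d), "degenerate")
  expect_error(svde(v, d, M = 0), "positive")
  # M = 1 with an unchanged replicate gives exactly 0
  r1 <- svde(v, d, M = 1, seed = 1)
  expect_equal(r1$svde, (r1$perturbed - r1$de_org)^2)
})

test_that("svde is invariant under shifting and scaling the gene", {
  d <- toy_design(c(3L, 3L, 3L))
  set.seed(8)
  v <- rnorm(9, rep(c(0, 1, 2), each = 3), 0.4)
  a <- svde(v, d, M = 50, seed = 99)$svde
  b <- svde(v + 100, d, M = 50, seed = 99)$svde
  expect_identical(a, b)               # same sigma, same noise stream
  # scaling: sigma' scales with the data, same seed gives same flips
  cc <- svde(v * 3, d, M = 50, seed = 99)$svde
  expect_identical(a, cc)
})

test_that("svde separates wide from narrow stage gaps", {
  d <- toy_design(c(4L, 4L, 4L))
  mu <- rep(c(0, 2, 4), each = 4)
  set.seed(77)
  wide <- rnorm(12, mu, 0.05)
  narrow <- rnorm(12, mu, 0.45)
  # both perfectly monotone so DE_total ties; SVDE must break the tie
  expect_equal(scan_gene(wide, d)$de_total, 0L)
  expect_equal(scan_gene(narrow, d)$de_total, 0L)
  expect_lt(svde(wide, d, M = 100, seed = 1)$svde,
            svde(narrow, d, M = 100, seed = 1)$svde)
})

test_that("rank_and_filter applies filters and the DE-then-SVDE sort", {
  sc <- data.frame(
    gene_id = paste0("g", 1:6),
    direction = "ascending",
    de_total = c(0L, 0L, 3L, 1L, 0L, 5L),
    level_errors = c("0,0,0,0", "0,0,0,0", "1,1,1,0", "1,0,0,0",
                     "0,0,0,0", "2,1,1,1"),
    distinct_lines = c(4L, 4L, 3L, 4L, 4L, 4L),
    degenerate = c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE))
  r <- rank_and_filter(sc, svde = c(1.5, 0.2, 0.1, 0.5, 0, 2),
                       de_max = NULL, p_max = NULL,
                       require_distinct = TRUE)
  # degenerate g5 dropped, g3 fails the distinct-lines filter
  expect_equal(r$gene_id, c("g2", "g1", "g4", "g6"))  # svde breaks DE tie
  expect_equal(r$rank, 1:4)
  expect_equal(names(r), c("rank", "gene_id", "direction", "de_total",
                           "level_errors", "distinct_lines", "p", "q",
                           "svde", "degenerate"))
  # de_max and p filters
  r2 <- rank_and_filter(sc, p = c(1e-6, 0.5, 1e-6, 1e-6, 1e-6, 1e-6),
                        svde = rep(0, 6), de_max = 3, p_max = 1e-5,
                        require_distinct = FALSE)
  expect_equal(sort(r2$gene_id), c("g1", "g3", "g4"))
})
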