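test_that("null-like selection includes the boundary and enforces its contract", {
  expect_identical(select_null_like(c(0.05, 0.10, 0.50)), c(2L, 3L))
  expect_identical(select_null_like(c(0.2, 0.3), cutoff = 0), c(1L, 2L))
  expect_error(select_null_like(c(0.01, 0.05)), "null-like")
  expect_error(select_null_like(c(0.5, 1.5)), "\\[0, 1\\]")
})

test_that("permutation enumeration matches combinatorial closed forms", {
  p44 <- enumerate_permutations(4, 4)
  expect_equal(p44$M, choose(8, 4) / 2 - 1)  # 34
  expect_true(p44$exhaustive)
  # every partition contains sample 1 (canonical form) and none is observed
  expect_true(all(vapply(p44$perms, function(s) 1L %in% s, logical(1))))
  expect_false(any(vapply(p44$perms, identical, logical(1), y = 1:4)))

  p23 <- enumerate_permutations(2, 3)
  expect_equal(p23$M, choose(5, 2) - 1)  # 9

  s1 <- enumerate_permutations(6, 6, max_permutations = 5, seed = 3)
  s2 <- enumerate_permutations(6, 6, max_permutations = 5, seed = 3)
  expect_identical(s1$perms, s2$perms)
  expect_equal(s1$M, 5)
  expect_false(s1$exhaustive)

  expect_error(enumerate_permutations(1, 1), "at least 2")
})

test_that("empirical p-values follow the add-one counting convention", {
  null <- structure(list(values = c(1, 2, 3, 4), M = 1L, n_null_like = 4L,
                         cutoff = 0.1, n_failed = 0L), class = "perm_null")
  expect_equal(empirical_pvalue(2.5, null), (1 + 2) / 5)
  expect_equal(empirical_pvalue(2, null), (1 + 3) / 5)   # ties count
  expect_equal(empirical_pvalue(-Inf, null), 1)
  big <- structure(list(values = seq_len(99), M = 1L, n_null_like = 99L,
                        cutoff = 0.1, n_failed = 0L), class = "perm_null")
  expect_equal(empirical_pvalue(1000, big), 1 / 100)
  # vectorized fast path agrees with direct counting
  set.seed(6)
  pool <- rnorm(500)
  null2 <- structure(list(values = pool, M = 1L, n_null_like = 500L,
                          cutoff = 0.1, n_failed = 0L), class = "perm_null")
  x <- c(rnorm(50), pool[1:5])
  direct <- sapply(x, function(v) (1 + sum(pool >= v)) / 501)
  expect_equal(empirical_pvalue(x, null2), direct)
})

test_that("the pooled null is exact bookkeeping, deterministic, and degenerate data give zero statistics", {
  # constant genes: no relabeling can generate signal
  m <- matrix(rep(c(5, 9, 14, 3, 20, 7, 11, 2, 6, 13, 4, 17), each = 8),
              ncol = 8, byrow = TRUE)
  rownames(m) <- paste0("g", 1:12)
  colnames(m) <- paste0("s", 1:8)
  cm <- desyn_counts(m, rep(1:2, each = 4), normalized = TRUE)
  perms <- enumerate_permutations(4, 4, max_permutations = 3, seed = 1)
  nl <- seq_len(12)
  pn <- expect_no_warning(build_null(cm, nl, perms))
  expect_equal(pn$values, rep(0, 3 * 12), tolerance = 1e-8)

  set.seed(10)
  m2 <- matrix(rnbinom(50 * 8, mu = 40, size = 5), 50, 8,
               dimnames = list(paste0("g", 1:50), paste0("s", 1:8)))
  cm2 <- desyn_counts(m2, rep(1:2, each = 4), normalized = TRUE)
  nl2 <- 1:30
  pn2 <- build_null(cm2, nl2, perms)
  expect_length(pn2$values, 3 * 30)
  expect_equal(pn2$n_failed, 0)
  pn3 <- build_null(cm2, nl2, perms)
  expect_identical(pn2$values, pn3$values)
})

test_that("Storey q-values match the formula transcription and are monotone", {
  expect_equal(storey_qvalues(rep(1, 5)), rep(1, 5))

  p <- c(0.01, 0.02, 0.8, 0.9)
  expect_equal(storey_qvalues(p), oracle_storey(p))
  expect_equal(storey_qvalues(p), c(0.04, 0.04, 0.9, 0.9))

  set.seed(14)
  for (i in 1:20) {
    p <- runif(sample(5:50, 1))
    q <- storey_qvalues(p)
    expect_equal(q, oracle_storey(p))
    expect_true(all(diff(q[order(p)]) >= -1e-12))
    expect_true(all(q >= 0 & q <= 1))
  }
  # NA p-values are excluded from G and returned as NA
  qna <- storey_qvalues(c(0.01, NA, 0.5))
  expect_true(is.na(qna[2]))
  expect_equal(qna[-2], storey_qvalues(c(0.01, 0.5)))
  expect_error(storey_qvalues(numeric(0)), "empty")
})

test_that("permutation p-values are approximately uniform on a single fully-null dataset", {
  pool <- build_parameter_pool("synthetic", seed = 61)
  sim <- simulate_null(400, 4, pool, seed = 62)
  core <- desyn_core(sim$counts, seed = 62)
  p <- core$results$p_perm
  p <- p[!is.na(p)]
  ks <- suppressWarnings(stats::ks.test(p, "punif")$statistic)
  expect_lt(ks, 0.1)
  expect_gte(min(p), 1 / (length(core$null$values) + 1))
})
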