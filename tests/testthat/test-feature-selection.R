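# Staged marker selection

mat_from_groups <- function(a, b, feature = "f1") {
  x <- matrix(c(a, b), ncol = 1, dimnames = list(NULL, feature))
  list(x = x, labels = c(rep("HC", length(a)), rep("ESCC", length(b))))
}

test_that("Wilcoxon filter applies exact small-sample p-values", {
  d <- mat_from_groups(c(1, 2, 3), c(10, 11, 12))
  res_tight <- wilcoxon_filter(d$x, d$labels, p_threshold = 0.001)
  res_loose <- wilcoxon_filter(d$x, d$labels, p_threshold = 0.2)
  expect_equal(res_tight$table$p, 0.1)  # exact p for full separation, 3v3
  expect_length(res_tight$retained, 0L)
  expect_identical(res_loose$retained, "f1")

  # identical groups: p = 1, dropped
  d2 <- mat_from_groups(c(1, 2, 3), c(1, 2, 3))
  res2 <- wilcoxon_filter(d2$x, d2$labels, p_threshold = 0.999)
  expect_equal(res2$table$p, 1)
  expect_length(res2$retained, 0L)

  # fully separated 12 vs 12: exact tail p = 2 / C(24, 12)
  d3 <- mat_from_groups(1:12, 101:112)
  res3 <- wilcoxon_filter(d3$x, d3$labels, p_threshold = 0.001)
  expect_equal(res3$table$p, 2 / choose(24, 12), tolerance = 1e-12)
  expect_identical(res3$retained, "f1")

  # constant feature: p = 1
  d4 <- mat_from_groups(rep(5, 4), rep(5, 4))
  expect_equal(wilcoxon_filter(d4$x, d4$labels, 0.5)$table$p, 1)
})

test_that("exact Wilcoxon matches enumeration for combined n <= 12", {
  set.seed(21)
  for (i in 1:20) {
    n1 <- sample(3:6, 1); n2 <- sample(3:6, 1)
    a <- rnorm(n1); b <- rnorm(n2, mean = sample(c(0, 2), 1))
    d <- mat_from_groups(a, b)
    got <- wilcoxon_filter(d$x, d$labels, 0.5)$table$p
    expect_equal(got, oracle_wilcoxon_p(a, b), tolerance = 1e-12)
  }
})

test_that("zero-fraction filter uses a strict 'more than' rule", {
  x <- cbind(z3 = c(rep(0, 3), rnorm(17)),
             z1 = c(0, rnorm(19)),
             z2 = c(0, 0, rnorm(18)))
  res <- zero_fraction_filter(x, max_zero_frac = 0.10)
  expect_false("z3" %in% res$retained)  # 15% zeros: dropped
  expect_true("z1" %in% res$retained)   # 5%: kept
  expect_true("z2" %in% res$retained)   # exactly 10%: kept (strict >)
})

test_that("LASSO eliminates under full shrinkage and drops constants", {
  set.seed(5)
  x <- cbind(matrix(rnorm(40 * 5), 40), const = rep(2, 40))
  colnames(x) <- paste0("f", 1:6)
  labels <- rep(c("HC", "ESCC"), each = 20)
  res_inf <- lasso_select(x, labels, penalty = 1e6)
  expect_length(res_inf$retained, 0L)
  res <- lasso_select(x, labels, seed = 2)
  expect_equal(res$table$weight[6], 0)
  expect_false("f6" %in% res$retained)
})

test_that("LASSO retains informative features across seeds", {
  hits <- 0L
  for (s in 1:20) {
    set.seed(1000 + s)
    n <- 60
    inf <- rbind(matrix(rnorm(n * 2), n), matrix(rnorm(n * 2, 2), n))
    noise <- matrix(rnorm(2 * n * 50), 2 * n)
    x <- cbind(inf, noise)
    colnames(x) <- c("inf1", "inf2", paste0("n", 1:50))
    labels <- rep(c("HC", "ESCC"), each = n)
    res <- lasso_select(x, labels, seed = s)
    hits <- hits + all(c("inf1", "inf2") %in% res$retained)
  }
  expect_gte(hits, 18L)  # >= 90% of seeds
})

test_that("rank-based filters are invariant to sample order", {
  set.seed(9)
  x <- matrix(rnorm(30 * 8), 30, dimnames = list(NULL, paste0("f", 1:8)))
  x[1:4, 3] <- 0
  labels <- rep(c("HC", "ESCC"), 15)
  perm <- sample.int(30)
  w1 <- wilcoxon_filter(x, labels, 0.3)
  w2 <- wilcoxon_filter(x[perm, ], labels[perm], 0.3)
  expect_identical(w1$retained, w2$retained)
  expect_equal(w1$table$p, w2$table$p)
  expect_identical(zero_fraction_filter(x)$retained,
                   zero_fraction_filter(x[perm, ])$retained)
})

test_that("seeded selection is reproducible and order-stable", {
  set.seed(31)
  n <- 40
  x <- cbind(matrix(rnorm(n * 2, rep(c(0, 1.5), each = n / 2)), n),
             matrix(rnorm(n * 10), n))
  colnames(x) <- paste0("f", 1:12)
  rownames(x) <- sprintf("s%02d", 1:n)
  labels <- rep(c("HC", "ESCC"), each = n / 2)
  r1 <- lasso_select(x, labels, seed = 7)
  r2 <- lasso_select(x, labels, seed = 7)
  expect_identical(r1$retained, r2$retained)
  # row order does not change the seeded fold assignment (ids sorted)
  perm <- sample.int(n)
  r3 <- lasso_select(x[perm, ], labels[perm], seed = 7)
  expect_identical(sort(r1$retained), sort(r3$retained))
  r4 <- rfe_cv(x, labels, seed = 7)
  r5 <- rfe_cv(x, labels, seed = 7)
  expect_identical(r4$retained, r5$retained)
})

test_that("RFE-CV keeps informative features, never scores below full", {
  set.seed(12)
  keep_hits <- 0L
  for (s in 1:10) {
    set.seed(2000 + s)
    n <- 30
    inf <- rbind(matrix(rnorm(n * 2), n), matrix(rnorm(n * 2, 2), n))
    noise <- matrix(rnorm(2 * n * 20), 2 * n)
    x <- cbind(inf, noise)
    colnames(x) <- c("inf1", "inf2", paste0("n", 1:20))
    labels <- rep(c("HC", "ESCC"), each = n)
    res <- rfe_cv(x, labels, seed = s)
    full_score <- res$table$cv_score[1]
    expect_gte(res$params$best_cv, full_score - 0.02)
    keep_hits <- keep_hits + all(c("inf1", "inf2") %in% res$retained)
  }
  expect_gte(keep_hits, 9L)
  # single feature: returned as-is
  x1 <- matrix(rnorm(20), 20, dimnames = list(NULL, "only"))
  expect_identical(rfe_cv(x1, rep(c("HC", "ESCC"), 10))$retained, "only")
})

test_that("analyte pipelines compose the stages in the documented order", {
  set.seed(8)
  n <- 30
  x <- cbind(matrix(rnorm(n * 2, rep(c(0, 2), each = n / 2)), n),
             matrix(rnorm(n * 8), n))
  colnames(x) <- paste0("f", 1:10)
  rownames(x) <- sprintf("s%02d", 1:n)
  labels <- rep(c("HC", "ESCC"), each = n / 2)
  expect_identical(
    names(select_markers(x, labels, "motif")$params$stages),
    c("wilcoxon", "lasso"))
  expect_identical(
    names(select_markers(x, labels, "nf")$params$stages),
    c("zero_fraction", "wilcoxon", "lasso"))
  expect_identical(
    names(select_markers(x, labels, "fragment")$params$stages),
    "lasso")
  expect_identical(
    names(select_markers(x, labels, "hmc")$params$stages),
    c("wilcoxon", "rfe_cv"))
})

test_that("selection on a signal-free cohort falls back instead of dying", {
  set.seed(44)
  x <- matrix(rnorm(40 * 20), 40, dimnames = list(NULL, paste0("f", 1:20)))
  rownames(x) <- sprintf("s%02d", 1:40)
  labels <- rep(c("HC", "ESCC"), each = 20)
  res <- NULL
  warns <- capture_warnings(res <- select_markers(x, labels, "nf", seed = 3))
  expect_true(any(grepl("best-ranked|LASSO", warns)))
  expect_gte(length(res$retained), 1L)
})
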