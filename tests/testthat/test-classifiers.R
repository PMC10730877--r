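# SVM heads, cutoff selection, logistic integration, ROC

test_that("cohort split is stratified, disjoint, exhaustive, seeded", {
  ids <- sprintf("s%03d", 1:171)
  labels <- c(rep("HC", 71), rep("ESCC", 100))
  stage <- c(rep(NA, 71), rep(c("0", "I", "II", "III", "IV"),
                              c(27, 23, 26, 20, 4)))
  sp <- split_cohort(ids, labels, stage, seed = 9)
  expect_length(intersect(sp$train, sp$test), 0L)
  expect_setequal(c(sp$train, sp$test), ids)
  # 2/3 split with per-stratum rounding (6 strata)
  expect_lte(abs(length(sp$train) - 114), 6)
  sp2 <- split_cohort(ids, labels, stage, seed = 9)
  expect_identical(sp, sp2)
  expect_false(identical(sp, split_cohort(ids, labels, stage, seed = 10)))
  # tiny stratum is merged with a warning
  expect_warning(
    split_cohort(ids[1:20], rep(c("HC", "ESCC"), 10),
                 c(rep(NA, 19), "IV"), seed = 1),
    "merging")
})

test_that("cutoff selection maximizes the rule over midpoints", {
  sc <- c(0.1, 0.2, 0.8, 0.9)
  lb <- c("HC", "HC", "ESCC", "ESCC")
  ct <- choose_cutoff(sc, lb, rule = "accuracy")
  expect_gt(ct, 0.2); expect_lt(ct, 0.8)
  expect_equal(mean((sc >= ct) == (lb == "ESCC")), 1)
  ct_y <- choose_cutoff(sc, lb, rule = "youden")
  expect_gt(ct_y, 0.2); expect_lt(ct_y, 0.8)

  # exhaustive-scan oracle on random instances
  set.seed(14)
  for (i in 1:10) {
    scores <- round(runif(20), 2)
    labels <- sample(c("HC", "ESCC"), 20, TRUE)
    if (length(unique(labels)) < 2) next
    for (rule in c("accuracy", "youden")) {
      ct <- choose_cutoff(scores, labels, rule = rule)
      y <- labels == "ESCC"
      obj <- function(c0) {
        sens <- sum(scores >= c0 & y) / sum(y)
        spec <- sum(scores < c0 & !y) / sum(!y)
        if (rule == "accuracy") mean((scores >= c0) == y) else sens + spec
      }
      s <- sort(unique(scores))
      cands <- (s[-1] + s[-length(s)]) / 2
      expect_equal(obj(ct), max(vapply(cands, obj, numeric(1))),
                   tolerance = 1e-12)
    }
  }
  expect_error(choose_cutoff(1:3, rep("HC", 3)), "class")
})

test_that("SVM training separates a separable toy exactly", {
  set.seed(2)
  n <- 40
  x <- rbind(matrix(rnorm(n, 0), n / 2, 2), matrix(rnorm(n, 6), n / 2, 2))
  colnames(x) <- c("a", "b")
  rownames(x) <- sprintf("t%02d", 1:n)
  labels <- rep(c("HC", "ESCC"), each = n / 2)
  m <- train_omic_svm(x, labels, seed = 4)
  expect_equal(max(m$cv_report$cv_accuracy), 1)
  xt <- rbind(matrix(rnorm(20, 0), 10, 2), matrix(rnorm(20, 6), 10, 2))
  colnames(xt) <- c("a", "b")
  pred <- predict(m, xt) >= m$cutoff
  expect_equal(mean(pred == rep(c(FALSE, TRUE), each = 10)), 1)
  # determinism: identical parameters and cutoff under the same seed
  m2 <- train_omic_svm(x, labels, seed = 4)
  expect_identical(m$params, m2$params)
  expect_identical(m$cutoff, m2$cutoff)
  expect_identical(predict(m, xt), predict(m2, xt))
  # non-finite features refuse to fit
  x_bad <- x; x_bad[1, 1] <- NA
  expect_error(train_omic_svm(x_bad, labels), "non-finite")
})

test_that("label-permuted training yields chance-level CV accuracy", {
  set.seed(6)
  n <- 40
  x <- rbind(matrix(rnorm(n, 0), n / 2, 2), matrix(rnorm(n, 3), n / 2, 2))
  colnames(x) <- c("a", "b")
  rownames(x) <- sprintf("t%02d", 1:n)
  accs <- vapply(1:20, function(s) {
    labels <- withr::with_seed(500 + s,
                               sample(rep(c("HC", "ESCC"), each = n / 2)))
    m <- train_omic_svm(x, labels, seed = s)
    max(m$cv_report$cv_accuracy)
  }, numeric(1))
  expect_gte(mean(accs), 0.35)
  expect_lte(mean(accs), 0.65)
})

test_that("fixed-coefficient integration matches direct arithmetic", {
  # independent arithmetic: p = 1 / (1 + exp(-Z))
  expect_equal(integrate_logistic(0, 0, 0, 0),
               1 / (1 + exp(2.57)), tolerance = 1e-12)
  expect_equal(integrate_logistic(1, 1, 1, 1),
               1 / (1 + exp(-(-2.57 + 3.35 + 0.05 + 0.75 + 1.74))),
               tolerance = 1e-12)
  expect_equal(integrate_logistic(2.57 / 3.35, 0, 0, 0), 0.5,
               tolerance = 1e-12)
  expect_equal(integrate_logistic(0, 0, 0, 0), 0.0711, tolerance = 1e-3)
  expect_equal(integrate_logistic(1, 1, 1, 1), 0.9651, tolerance = 1e-3)
})

test_that("integration is strictly increasing in every analyte score", {
  g <- seq(0, 1, by = 0.1)
  base <- c(nf = 0.3, fragment = 0.5, motif = 0.4, hmc = 0.6)
  for (v in names(base)) {
    args <- lapply(names(base), function(nm)
      if (nm == v) g else rep(base[[nm]], length(g)))
    names(args) <- names(base)
    p <- do.call(integrate_logistic, args)
    expect_true(all(diff(p) > 0))
  }
})

test_that("refit recovers the generating integration model at large n", {
  beta <- c(-2.57, 3.35, 0.05, 0.75, 1.74)
  d <- withr::with_seed(1, {
    s <- matrix(stats::rbeta(10000 * 4, 0.3, 0.3), ncol = 4,
                dimnames = list(NULL, c("nf", "fragment", "motif", "hmc")))
    z <- beta[1] + as.numeric(s %*% beta[-1])
    y <- ifelse(stats::rbinom(10000, 1, stats::plogis(z)) == 1,
                "ESCC", "HC")
    list(s = as.data.frame(s), y = y)
  })
  m <- refit_integration(d$s, d$y)
  expect_identical(m$mode, "refit")
  cf <- m$coefficients
  expect_lt(abs(cf["intercept"] - beta[1]), 0.4)
  for (j in 2:5) expect_lt(abs(cf[j] - beta[j]), 0.25)
  # the dominant analytes keep their ordering
  expect_gt(cf["nf"], cf["hmc"])
  expect_gt(cf["hmc"], cf["fragment"])
})

test_that("null refits produce slope CIs covering zero", {
  cover <- 0L
  for (s in 1:20) {
    d <- withr::with_seed(700 + s, {
      sm <- matrix(runif(200 * 4), ncol = 4,
                   dimnames = list(NULL, c("nf", "fragment", "motif",
                                           "hmc")))
      list(s = as.data.frame(sm),
           y = sample(rep(c("HC", "ESCC"), each = 100)))
    })
    m <- refit_integration(d$s, d$y)
    ci <- suppressMessages(stats::confint.default(attr(m, "fit")))[-1, ]
    cover <- cover + sum(ci[, 1] <= 0 & ci[, 2] >= 0)
  }
  expect_gte(cover / 80, 0.9)  # 20 seeds x 4 slopes
})

test_that("perfect separation falls back to a penalized fit", {
  s <- data.frame(nf = c(runif(15, 0, 0.3), runif(15, 0.7, 1)),
                  fragment = runif(30), motif = runif(30),
                  hmc = runif(30))
  y <- rep(c("HC", "ESCC"), each = 15)
  expect_warning(m <- refit_integration(s, y), "separation")
  expect_identical(m$mode, "refit")
  expect_true(all(is.finite(m$coefficients)))
})

test_that("rank AUC matches the exhaustive pair-counting oracle", {
  expect_equal(roc_auc(c(0, 0, 1, 1), c("HC", "HC", "ESCC", "ESCC"))$auc, 1)
  expect_equal(roc_auc(rep(0.4, 6), rep(c("HC", "ESCC"), 3))$auc, 0.5)
  set.seed(17)
  for (i in 1:40) {
    n <- sample(4:10, 1)
    y <- rep(FALSE, n)
    y[sample(n, sample(seq_len(n - 1), 1))] <- TRUE
    scores <- sample(1:4, n, replace = TRUE) +
      ifelse(runif(n) < 0.5, 0, 0.5)  # force frequent ties
    labels <- ifelse(y, "ESCC", "HC")
    r <- roc_auc(scores, labels)
    expect_equal(r$auc, oracle_auc(scores, y), tolerance = 1e-12)
    # complement identity and CI containment
    r_neg <- roc_auc(-scores, labels)
    expect_equal(r$auc + r_neg$auc, 1, tolerance = 1e-12)
    expect_gte(r$auc, r$ci[1]); expect_lte(r$auc, r$ci[2])
  }
  expect_error(roc_auc(1:3, rep("ESCC", 3)), "class")
})

test_that("operating-point metrics at a supplied cutoff are correct", {
  scores <- c(0.1, 0.3, 0.6, 0.7, 0.2, 0.9)
  labels <- c("HC", "HC", "ESCC", "ESCC", "ESCC", "ESCC")
  r <- roc_auc(scores, labels, cutoff = 0.5)
  expect_equal(r$sensitivity, 3 / 4)
  expect_equal(r$specificity, 1)
  expect_equal(r$accuracy, 5 / 6)
  rb <- roc_auc(scores, labels, cutoff = 0.5, ci_method = "bootstrap",
                n_boot = 200, seed = 3)
  expect_gte(rb$auc, rb$ci[1]); expect_lte(rb$auc, rb$ci[2])
})
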