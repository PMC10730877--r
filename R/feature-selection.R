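# Staged marker selection. All operations take a samples x features numeric
# matrix plus a two-class label vector, return a `selection_result`, are
# permutation-invariant over sample order, and are reproducible given `seed`.

selection_result <- function(retained, table, method, params) {
  structure(list(retained = retained, table = table, method = method,
                 params = params),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat("<selection_result> ", x$method, ": ", length(x$retained), " of ",
      nrow(x$table), " features retained\n", sep = "")
  invisible(x)
}

check_two_class <- function(labels, n) {
  labels <- as.character(labels)
  if (length(labels) != n)
    stop("`labels` length must match the number of samples", call. = FALSE)
  if (length(unique(labels)) != 2L)
    stop("`labels` must contain exactly two classes", call. = FALSE)
  labels
}

#' Univariate Wilcoxon rank-sum filter
#'
#' Two-sided rank-sum p-value per feature between the two classes; features
#' with `p < p_threshold` (strict) are retained. The exact distribution is
#' used when the combined sample size is at most `exact_max_n` and the
#' feature has no ties; otherwise the normal approximation with tie and
#' continuity correction. Constant features get p = 1 and are dropped.
#' No multiplicity correction is applied by default (raw-p thresholds are
#' the convention this selection stage follows); `adjust = "BH"` is
#' available.
#'
#' @param x samples x features numeric matrix with column names.
#' @param labels two-class vector, one entry per row of `x`.
#' @param p_threshold strict retention threshold on p.
#' @param exact_max_n switchover from exact to approximate p.
#' @param adjust `"none"` (default) or `"BH"`.
#' @return a `selection_result`; its `table` has `feature`, `p`, `retained`.
#' @export
wilcoxon_filter <- function(x, labels, p_threshold = 0.001,
                            exact_max_n = 25L, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  labels <- check_two_class(labels, nrow(x))
  cls <- sort(unique(labels))
  g1 <- labels == cls[1]
  if (sum(g1) < 2L || sum(!g1) < 2L)
    stop("both classes need at least 2 samples", call. = FALSE)
  p <- apply(x, 2L, function(v) {
    if (stats::sd(v) == 0) return(1)
    use_exact <- length(v) <= exact_max_n && !any(duplicated(v))
    stats::wilcox.test(v[g1], v[!g1], exact = use_exact,
                       correct = TRUE)$p.value
  })
  if (adjust == "BH") p <- stats::p.adjust(p, "BH")
  keep <- p < p_threshold
  selection_result(colnames(x)[keep],
                   data.frame(feature = colnames(x), p = unname(p),
                              retained = unname(keep)),
                   "wilcoxon",
                   list(p_threshold = p_threshold,
                        exact_max_n = exact_max_n, adjust = adjust))
}

#' Zero-fraction filter
#'
#' Drops features for which strictly more than `max_zero_frac` of the
#' samples have an exactly-zero value (used for NF scores, where a zero
#' means no usable coverage contrast at that gene).
#'
#' @inheritParams wilcoxon_filter
#' @param max_zero_frac maximum tolerated fraction of zeros (strict ">").
#' @return a `selection_result`.
#' @export
zero_fraction_filter <- function(x, max_zero_frac = 0.10) {
  zf <- colMeans(x == 0)
  keep <- !(zf > max_zero_frac)
  selection_result(colnames(x)[keep],
                   data.frame(feature = colnames(x), zero_frac = unname(zf),
                              retained = unname(keep)),
                   "zero_fraction", list(max_zero_frac = max_zero_frac))
}

# Seeded fold assignment, stratified by class. When sample ids are given,
# folds are assigned in id-sorted order, so the assignment (and everything
# seeded on it) is invariant to the order samples arrive in.
stratified_folds <- function(labels, k, seed, ids = NULL) {
  n <- length(labels)
  ord <- if (!is.null(ids)) order(ids) else seq_len(n)
  withr::with_seed(seed, {
    fold_s <- integer(n)
    lab_s <- labels[ord]
    for (cl in sort(unique(lab_s))) {
      idx <- which(lab_s == cl)
      fold_s[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
    fold <- integer(n)
    fold[ord] <- fold_s
    fold
  })
}

#' LASSO feature elimination
#'
#' L1-penalized logistic regression on internally standardized features;
#' the penalty is chosen by seeded k-fold cross-validation
#' ([glmnet::cv.glmnet], `lambda.min`) unless `penalty` is supplied.
#' Features with a coefficient of exactly zero at the selected penalty are
#' eliminated.
#'
#' @inheritParams wilcoxon_filter
#' @param k_folds CV folds for the penalty choice.
#' @param penalty optional fixed penalty (lambda), bypassing CV.
#' @param seed RNG seed for fold assignment.
#' @return a `selection_result`; its `table` has `feature`, `weight`,
#'   `retained`.
#' @export
lasso_select <- function(x, labels, k_folds = 10L, penalty = NULL,
                         seed = 1L) {
  labels <- check_two_class(labels, nrow(x))
  y <- as.integer(labels == sort(unique(labels))[2])
  cv_selected <- is.null(penalty)
  if (cv_selected) {
    foldid <- stratified_folds(labels, k_folds, seed, ids = rownames(x))
    cv <- glmnet::cv.glmnet(x, y, family = "binomial", alpha = 1,
                            foldid = foldid, standardize = TRUE)
    penalty <- cv$lambda.min
    fit <- cv$glmnet.fit
  } else {
    fit <- glmnet::glmnet(x, y, family = "binomial", alpha = 1,
                          standardize = TRUE)
  }
  w <- as.numeric(stats::coef(fit, s = penalty))[-1L]
  fallback <- NULL
  if (cv_selected && !any(w != 0) && any(fit$df > 0)) {
    # nothing survives the selected penalty (e.g. no real signal): back off
    # to the largest penalty on the path retaining at least one feature
    fallback <- max(fit$lambda[fit$df > 0])
    warning("LASSO retained no feature at the selected penalty; ",
            "using the largest penalty keeping at least one", call. = FALSE)
    penalty <- fallback
    w <- as.numeric(stats::coef(fit, s = penalty))[-1L]
  }
  keep <- w != 0
  selection_result(colnames(x)[keep],
                   data.frame(feature = colnames(x), weight = w,
                              retained = keep),
                   "lasso", list(penalty = penalty, k_folds = k_folds,
                                 seed = seed, fallback = fallback))
}

# |weight| per feature from a linear-kernel SVM (internally standardized)
svm_linear_weights <- function(x, y01, cost = 1) {
  sds <- apply(x, 2L, stats::sd)
  sds[sds == 0] <- 1
  xs <- scale(x, center = TRUE, scale = sds)
  fit <- e1071::svm(xs, factor(y01), kernel = "linear", cost = cost,
                    scale = FALSE)
  w <- t(fit$coefs) %*% fit$SV
  abs(as.numeric(w))
}

cv_accuracy_svm <- function(x, y01, fold, cost = 1) {
  acc <- vapply(sort(unique(fold)), function(k) {
    tr <- fold != k
    sds <- apply(x[tr, , drop = FALSE], 2L, stats::sd)
    sds[sds == 0] <- 1
    mu <- colMeans(x[tr, , drop = FALSE])
    xtr <- scale(x[tr, , drop = FALSE], mu, sds)
    xte <- scale(x[!tr, , drop = FALSE], mu, sds)
    fit <- e1071::svm(xtr, factor(y01[tr], levels = c(0, 1)),
                      kernel = "linear", cost = cost, scale = FALSE)
    mean(as.integer(as.character(stats::predict(fit, xte))) == y01[!tr])
  }, numeric(1))
  mean(acc)
}

#' Recursive feature elimination with cross-validation (RFE-CV)
#'
#' Starting from the full feature set, repeatedly (i) scores the current
#' subset by seeded stratified k-fold CV accuracy of a linear-kernel SVM,
#' (ii) ranks features by the absolute SVM weight from a fit on all
#' samples, and (iii) drops the lowest-ranked `step` fraction (at least
#' one). The subset with the highest CV score is returned; ties go to the
#' smaller subset. Fold assignment is fixed once per call so subset scores
#' are comparable.
#'
#' @inheritParams wilcoxon_filter
#' @param k_folds CV folds.
#' @param step fraction of remaining features dropped per round.
#' @param cost SVM cost parameter.
#' @param seed RNG seed.
#' @return a `selection_result`; its `table` records the per-round subset
#'   size and CV score.
#' @export
rfe_cv <- function(x, labels, k_folds = 5L, step = 0.1, cost = 1,
                   seed = 1L) {
  labels <- check_two_class(labels, nrow(x))
  y01 <- as.integer(labels == sort(unique(labels))[2])
  if (ncol(x) < 1L) stop("need at least one feature", call. = FALSE)
  if (ncol(x) == 1L)
    return(selection_result(colnames(x),
                            data.frame(n_features = 1L, cv_score = NA_real_),
                            "rfe_cv", list(k_folds = k_folds, step = step,
                                           seed = seed)))
  fold <- stratified_folds(labels, k_folds, seed, ids = rownames(x))
  current <- colnames(x)
  history <- list()
  subsets <- list()
  while (length(current) >= 1L) {
    sc <- cv_accuracy_svm(x[, current, drop = FALSE], y01, fold, cost)
    history[[length(history) + 1L]] <-
      data.frame(n_features = length(current), cv_score = sc)
    subsets[[length(subsets) + 1L]] <- current
    if (length(current) == 1L) break
    w <- svm_linear_weights(x[, current, drop = FALSE], y01, cost)
    drop_n <- max(1L, floor(step * length(current)))
    current <- current[order(w, decreasing = TRUE)]
    current <- current[seq_len(length(current) - drop_n)]
  }
  tab <- do.call(rbind, history)
  # best CV score; among ties prefer the smallest subset
  best <- which(tab$cv_score == max(tab$cv_score))
  best <- best[which.min(tab$n_features[best])]
  selection_result(subsets[[best]], tab, "rfe_cv",
                   list(k_folds = k_folds, step = step, cost = cost,
                        seed = seed, best_cv = tab$cv_score[best]))
}

#' Analyte-specific marker-selection pipelines
#'
#' Composes the selection stages in the order each analyte uses:
#' \describe{
#'   \item{motif}{Wilcoxon (p < 0.05) then LASSO.}
#'   \item{nf}{zero-fraction (> 10% zeros dropped), Wilcoxon (p < 0.001),
#'     then LASSO.}
#'   \item{fragment}{LASSO only.}
#'   \item{hmc}{Wilcoxon (p < 0.001) then RFE-CV.}
#' }
#'
#' When a univariate stage would eliminate every feature (as happens on a
#' cohort without signal), the `min_features` best-ranked features are
#' carried forward instead, with a warning, so the downstream classifier
#' can still be trained and honestly report chance-level performance.
#'
#' @inheritParams wilcoxon_filter
#' @param analyte one of `"motif"`, `"nf"`, `"fragment"`, `"hmc"`.
#' @param seed RNG seed passed to the seeded stages.
#' @param min_features features carried forward when a stage retains none.
#' @return a `selection_result` whose `retained` is the final marker set
#'   and whose `params$stages` records each stage's result.
#' @export
select_markers <- function(x, labels, analyte = c("motif", "nf", "fragment",
                                                  "hmc"), seed = 1L,
                           min_features = 5L) {
  analyte <- match.arg(analyte)
  stages <- list()
  cur <- x
  run <- function(res) {
    stages[[res$method]] <<- res
    if (!length(res$retained)) {
      warning("selection for analyte `", analyte,
              "` eliminated every feature at stage `", res$method,
              "`; keeping the ", min_features, " best-ranked",
              call. = FALSE)
      rank_by <- if (!is.null(res$table$p)) order(res$table$p)
      else if (!is.null(res$table$zero_frac)) order(res$table$zero_frac)
      else seq_len(nrow(res$table))
      keep <- res$table$feature[rank_by][
        seq_len(min(min_features, nrow(res$table)))]
      return(cur[, keep, drop = FALSE])
    }
    cur[, res$retained, drop = FALSE]
  }
  cur <- switch(analyte,
    motif = {
      cur <- run(wilcoxon_filter(cur, labels, p_threshold = 0.05))
      run(lasso_select(cur, labels, seed = seed))
    },
    nf = {
      cur <- run(zero_fraction_filter(cur, max_zero_frac = 0.10))
      cur <- run(wilcoxon_filter(cur, labels, p_threshold = 0.001))
      run(lasso_select(cur, labels, seed = seed))
    },
    fragment = run(lasso_select(cur, labels, seed = seed)),
    hmc = {
      cur <- run(wilcoxon_filter(cur, labels, p_threshold = 0.001))
      run(rfe_cv(cur, labels, seed = seed))
    })
  selection_result(colnames(cur),
                   data.frame(feature = colnames(cur),
                              retained = TRUE),
                   paste0("select_markers:", analyte),
                   list(analyte = analyte, seed = seed, stages = stages))
}
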