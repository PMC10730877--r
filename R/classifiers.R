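# Per-analyte SVM classifiers, cutoff selection, the logistic integration
# of the four analyte scores, and rank-based ROC evaluation.

positive_class <- function(labels, positive = NULL) {
  labels <- as.character(labels)
  cls <- sort(unique(labels))
  if (length(cls) != 2L)
    stop("`labels` must contain exactly two classes", call. = FALSE)
  if (is.null(positive))
    positive <- if ("ESCC" %in% cls) "ESCC" else cls[2]
  if (!positive %in% cls)
    stop("positive class `", positive, "` not present in labels",
         call. = FALSE)
  positive
}

#' Stratified train/test split
#'
#' Splits samples into disjoint, exhaustive train and test sets, stratified
#' by class label and (when given) stage, so both sets preserve the cohort
#' composition. Strata with fewer than 2 samples are merged into their
#' class-level stratum with a warning. Deterministic given `seed`.
#'
#' @param sample_ids character vector of sample identifiers.
#' @param labels class label per sample.
#' @param stage optional stage per sample (NA allowed, e.g. for controls).
#' @param train_frac fraction assigned to training (default 2/3).
#' @param seed RNG seed.
#' @return list with character vectors `train` and `test`.
#' @export
split_cohort <- function(sample_ids, labels, stage = NULL,
                         train_frac = 2 / 3, seed = 1L) {
  if (train_frac <= 0 || train_frac >= 1)
    stop("`train_frac` must be in (0, 1)", call. = FALSE)
  labels <- as.character(labels)
  stratum <- if (is.null(stage)) labels else
    paste(labels, ifelse(is.na(stage), "", as.character(stage)), sep = "|")
  small <- names(which(table(stratum) < 2L))
  if (length(small)) {
    warning("merging ", length(small), " stratum(um/a) with < 2 samples ",
            "into class-level strata", call. = FALSE)
    stratum[stratum %in% small] <- labels[stratum %in% small]
  }
  train <- withr::with_seed(seed, {
    unlist(lapply(unique(stratum), function(s) {
      idx <- which(stratum == s)
      n_tr <- max(1L, min(length(idx) - 1L, round(train_frac * length(idx))))
      sample(idx, n_tr)
    }), use.names = FALSE)
  })
  list(train = sample_ids[sort(train)],
       test = sample_ids[sort(setdiff(seq_along(sample_ids), train))])
}

#' Decision cutoff maximizing accuracy or the Youden index
#'
#' Candidate cutoffs are the midpoints between adjacent distinct sorted
#' scores; a sample is called positive when its score is >= the cutoff.
#' Among candidates tied on the objective, the one with the higher
#' specificity (then the higher cutoff) is returned.
#'
#' @param scores numeric scores, higher = more disease-like.
#' @param labels two-class labels.
#' @param rule `"accuracy"` (best diagnostic accuracy) or `"youden"`
#'   (maximum sensitivity + specificity).
#' @param positive the positive class (defaults to `"ESCC"` if present,
#'   else the alphabetically second class).
#' @return the selected cutoff.
#' @export
choose_cutoff <- function(scores, labels, rule = c("accuracy", "youden"),
                          positive = NULL) {
  rule <- match.arg(rule)
  positive <- positive_class(labels, positive)
  y <- as.character(labels) == positive
  if (all(y) || !any(y)) stop("both classes required", call. = FALSE)
  s <- sort(unique(scores))
  if (length(s) < 2L) return(s[1])
  cand <- (s[-1] + s[-length(s)]) / 2
  n_pos <- sum(y); n_neg <- sum(!y)
  stat <- vapply(cand, function(ct) {
    pred <- scores >= ct
    sens <- sum(pred & y) / n_pos
    spec <- sum(!pred & !y) / n_neg
    obj <- if (rule == "accuracy")
      (sum(pred & y) + sum(!pred & !y)) / length(y) else sens + spec
    c(obj = obj, spec = spec)
  }, numeric(2))
  best <- which(stat["obj", ] == max(stat["obj", ]))
  best <- best[stat["spec", best] == max(stat["spec", best])]
  cand[best[length(best)]]
}

default_svm_grid <- function(n_features) {
  g0 <- 1 / max(n_features, 1L)  # scale heuristic on standardized features
  rbind(
    expand.grid(kernel = "linear", cost = c(0.1, 1, 10, 100), gamma = NA,
                stringsAsFactors = FALSE),
    expand.grid(kernel = "radial", cost = c(0.1, 1, 10, 100),
                gamma = g0 * c(0.1, 1, 10), stringsAsFactors = FALSE))
}

#' Train a per-analyte SVM classifier
#'
#' Grid search over (kernel, cost, gamma) by seeded stratified k-fold CV
#' accuracy; the best combination (ties: first in grid order) is refit on
#' the full training set with Platt probability calibration, so
#' `predict()` returns scores in \[0, 1\]. The decision cutoff is then set
#' on the training scores with [choose_cutoff()] (best diagnostic
#' accuracy by default). Features are standardized internally.
#'
#' @param x samples x features numeric matrix (selected features only).
#' @param labels two-class labels.
#' @param grid data frame of candidate (kernel, cost, gamma); default
#'   [default_svm_grid()].
#' @param k CV folds (default 10).
#' @param cutoff_rule passed to [choose_cutoff()].
#' @param positive positive class (see [choose_cutoff()]).
#' @param seed RNG seed (folds and probability calibration).
#' @return an `omic_svm` model.
#' @export
train_omic_svm <- function(x, labels, grid = NULL, k = 10L,
                           cutoff_rule = "accuracy", positive = NULL,
                           seed = 1L) {
  if (any(!is.finite(x))) stop("non-finite feature values", call. = FALSE)
  positive <- positive_class(labels, positive)
  y <- factor(ifelse(as.character(labels) == positive, "pos", "neg"),
              levels = c("neg", "pos"))
  if (min(table(y)) < k)
    k <- max(2L, min(table(y)))
  if (is.null(grid)) grid <- default_svm_grid(ncol(x))
  mu <- colMeans(x)
  sds <- apply(x, 2L, stats::sd); sds[sds == 0] <- 1
  xs <- scale(x, mu, sds)
  fold <- stratified_folds(as.character(y), k, seed, ids = rownames(x))
  cv_acc <- vapply(seq_len(nrow(grid)), function(i) {
    mean(vapply(seq_len(k), function(kk) {
      tr <- fold != kk
      fit <- svm_fit(xs[tr, , drop = FALSE], y[tr], grid[i, ],
                     probability = FALSE, seed = seed)
      mean(stats::predict(fit, xs[!tr, , drop = FALSE]) == y[!tr])
    }, numeric(1)))
  }, numeric(1))
  best <- which.max(cv_acc)  # first max = first in grid order
  fit <- svm_fit(xs, y, grid[best, ], probability = TRUE, seed = seed)
  scores <- svm_prob(fit, xs)
  cutoff <- choose_cutoff(scores, as.character(y), rule = cutoff_rule,
                          positive = "pos")
  structure(list(fit = fit, features = colnames(x), center = mu, scale = sds,
                 params = grid[best, ], cutoff = cutoff,
                 cv_report = cbind(grid, cv_accuracy = cv_acc),
                 positive = positive, seed = seed),
            class = "omic_svm")
}

svm_fit <- function(xs, y, par, probability, seed) {
  withr::with_seed(seed, {
    if (par$kernel == "linear")
      e1071::svm(xs, y, kernel = "linear", cost = par$cost,
                 probability = probability, scale = FALSE)
    else
      e1071::svm(xs, y, kernel = "radial", cost = par$cost,
                 gamma = par$gamma, probability = probability, scale = FALSE)
  })
}

svm_prob <- function(fit, xs) {
  pr <- stats::predict(fit, xs, probability = TRUE)
  attr(pr, "probabilities")[, "pos"]
}

#' @export
print.omic_svm <- function(x, ...) {
  cat("<omic_svm> ", length(x$features), " features; kernel ",
      x$params$kernel, ", cost ", x$params$cost,
      if (!is.na(x$params$gamma)) paste0(", gamma ",
                                         signif(x$params$gamma, 3)) else "",
      "; cutoff ", signif(x$cutoff, 4), "\n", sep = "")
  invisible(x)
}

#' Predict probability scores from an `omic_svm`
#'
#' @param object an `omic_svm` from [train_omic_svm()].
#' @param newdata samples x features matrix containing the model's features.
#' @param ... unused.
#' @return numeric scores in \[0, 1\] (probability of the positive class).
#' @export
predict.omic_svm <- function(object, newdata, ...) {
  xs <- scale(newdata[, object$features, drop = FALSE],
              object$center, object$scale)
  svm_prob(object$fit, xs)
}

#' Logistic integration model over the four analyte scores
#'
#' The integration combines the per-analyte classifier scores (NF,
#' fragment, motif, 5hmC) through
#' \deqn{Z = \beta_0 + \beta_1 NF + \beta_2 Fragment + \beta_3 Motif +
#'   \beta_4 hmC, \qquad p = e^Z / (1 + e^Z).}
#' `mode = "fixed"` pins the coefficients at
#' (-2.57, 3.35, 0.05, 0.75, 1.74) — the published combination weights —
#' while `mode = "refit"` is produced by [refit_integration()].
#'
#' @param mode `"fixed"` or `"refit"`.
#' @param coefficients named numeric of length 5 (`intercept`, `nf`,
#'   `fragment`, `motif`, `hmc`); required for `mode = "refit"`.
#' @return an `integrated_model`.
#' @export
integrated_model <- function(mode = c("fixed", "refit"),
                             coefficients = NULL) {
  mode <- match.arg(mode)
  nm <- c("intercept", "nf", "fragment", "motif", "hmc")
  if (mode == "fixed") {
    coefficients <- stats::setNames(c(-2.57, 3.35, 0.05, 0.75, 1.74), nm)
  } else {
    if (is.null(coefficients) || length(coefficients) != 5L)
      stop("`coefficients` (length 5) required for mode = \"refit\"",
           call. = FALSE)
    coefficients <- stats::setNames(as.numeric(coefficients), nm)
  }
  structure(list(mode = mode, coefficients = coefficients),
            class = "integrated_model")
}

#' @export
print.integrated_model <- function(x, ...) {
  cat("<integrated_model> mode ", x$mode, "; Z = ",
      sprintf("%.3g", x$coefficients[1]),
      paste(sprintf(" + (%.3g x %s)", x$coefficients[-1],
                    c("NF", "Fragment", "Motif", "5hmC")), collapse = ""),
      "\n", sep = "")
  invisible(x)
}

#' Integrated logistic score
#'
#' @param nf,fragment,motif,hmc analyte scores (vectorized; typically
#'   probabilities in \[0, 1\], but any finite values are accepted).
#' @param model an [integrated_model()]; default the fixed published
#'   coefficients.
#' @return the logistic score \eqn{e^Z/(1+e^Z)}.
#' @examples
#' integrate_logistic(0, 0, 0, 0)   # ~0.0711
#' integrate_logistic(1, 1, 1, 1)   # ~0.9651
#' @export
integrate_logistic <- function(nf, fragment, motif, hmc,
                               model = integrated_model("fixed")) {
  stopifnot(inherits(model, "integrated_model"))
  b <- model$coefficients
  z <- b[1] + b[2] * nf + b[3] * fragment + b[4] * motif + b[5] * hmc
  unname(stats::plogis(z))
}

#' Refit the integration coefficients by logistic regression
#'
#' Unpenalized maximum-likelihood logistic fit of the class label on the
#' four analyte scores. Under perfect separation (the MLE diverges), the
#' fit falls back to a lightly L2-penalized logistic regression with a
#' warning.
#'
#' @param scores samples x 4 matrix or data frame with columns `nf`,
#'   `fragment`, `motif`, `hmc`.
#' @param labels two-class labels.
#' @param positive positive class (see [choose_cutoff()]).
#' @return an [integrated_model()] with `mode = "refit"`; the underlying
#'   [stats::glm] fit is attached as attribute `"fit"` (NULL under the
#'   penalized fallback).
#' @export
refit_integration <- function(scores, labels, positive = NULL) {
  scores <- as.data.frame(scores)
  req <- c("nf", "fragment", "motif", "hmc")
  if (!all(req %in% names(scores)))
    stop("`scores` needs columns ", paste(req, collapse = ", "),
         call. = FALSE)
  positive <- positive_class(labels, positive)
  y <- as.integer(as.character(labels) == positive)
  if (min(table(y)) < 10L)
    stop("need at least 10 samples per class", call. = FALSE)
  dat <- cbind(scores[req], y = y)
  separated <- FALSE
  fit <- withCallingHandlers(
    stats::glm(y ~ nf + fragment + motif + hmc, data = dat,
               family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1",
                conditionMessage(w)) ||
          grepl("did not converge", conditionMessage(w))) {
        separated <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  if (separated || any(abs(stats::coef(fit)) > 50)) {
    warning("perfect separation detected; using L2-penalized fit",
            call. = FALSE)
    rfit <- glmnet::glmnet(as.matrix(scores[req]), y, family = "binomial",
                           alpha = 0, lambda = 0.01, standardize = FALSE)
    cf <- as.numeric(stats::coef(rfit, s = 0.01))
    mdl <- integrated_model("refit", cf)
    attr(mdl, "fit") <- NULL
    return(mdl)
  }
  mdl <- integrated_model("refit", stats::coef(fit))
  attr(mdl, "fit") <- fit
  mdl
}

#' Rank-based ROC evaluation with DeLong or bootstrap confidence interval
#'
#' AUC via the Mann-Whitney rank formulation (ties count 1/2); the 95% CI
#' comes from the DeLong method (default) or a stratified bootstrap, both
#' via \pkg{pROC}. If `cutoff` is supplied, sensitivity, specificity and
#' accuracy at that cutoff (positive call: score >= cutoff) are reported.
#'
#' @param scores numeric scores, higher = more disease-like.
#' @param labels two-class labels.
#' @param cutoff optional decision cutoff.
#' @param ci_method `"delong"` or `"bootstrap"`.
#' @param n_boot bootstrap replicates (when `ci_method = "bootstrap"`).
#' @param positive positive class (see [choose_cutoff()]).
#' @param seed RNG seed for the bootstrap.
#' @return a `roc_result`: list with `auc`, `ci` (length 2), `sensitivity`,
#'   `specificity`, `accuracy`, `cutoff`, and `curve` (data frame of
#'   threshold, sensitivity, specificity).
#' @export
roc_auc <- function(scores, labels, cutoff = NULL,
                    ci_method = c("delong", "bootstrap"), n_boot = 2000L,
                    positive = NULL, seed = 1L) {
  ci_method <- match.arg(ci_method)
  positive <- positive_class(labels, positive)
  y <- as.character(labels) == positive
  if (all(y) || !any(y)) stop("both classes required", call. = FALSE)
  n_pos <- sum(y); n_neg <- sum(!y)
  r <- rank(scores)
  auc <- (sum(r[y]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  resp <- factor(ifelse(y, "pos", "neg"), levels = c("neg", "pos"))
  ci <- withr::with_seed(seed, withCallingHandlers({
    obj <- pROC::roc(resp, scores, levels = c("neg", "pos"),
                     direction = "<", quiet = TRUE)
    if (ci_method == "delong")
      as.numeric(pROC::ci.auc(obj, method = "delong"))[c(1, 3)]
    else
      as.numeric(pROC::ci.auc(obj, method = "bootstrap",
                              boot.n = n_boot,
                              boot.stratified = TRUE))[c(1, 3)]
  }, warning = function(w) {
    if (grepl("AUC == 1 is always", conditionMessage(w)))
      invokeRestart("muffleWarning")
  }))
  # degenerate instances (e.g. one sample in a class) have no variance
  # estimate; report a point CI rather than NA
  ci[!is.finite(ci)] <- auc
  ci <- c(max(0, min(ci[1], auc)), min(1, max(ci[2], auc)))
  thr <- c(-Inf, sort(unique(scores)), Inf)
  curve <- data.frame(
    threshold = thr,
    sensitivity = vapply(thr, function(t) sum(scores >= t & y) / n_pos,
                         numeric(1)),
    specificity = vapply(thr, function(t) sum(scores < t & !y) / n_neg,
                         numeric(1)))
  sens <- spec <- acc <- NA_real_
  if (!is.null(cutoff)) {
    pred <- scores >= cutoff
    sens <- sum(pred & y) / n_pos
    spec <- sum(!pred & !y) / n_neg
    acc <- mean(pred == y)
  }
  structure(list(auc = auc, ci = ci, sensitivity = sens, specificity = spec,
                 accuracy = acc, cutoff = cutoff, curve = curve,
                 ci_method = ci_method),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC %.3f (95%% CI %.3f-%.3f, %s)\n",
              x$auc, x$ci[1], x$ci[2], x$ci_method))
  if (!is.na(x$sensitivity))
    cat(sprintf("  at cutoff %.3f: sens %.3f, spec %.3f, acc %.3f\n",
                x$cutoff, x$sensitivity, x$specificity, x$accuracy))
  invisible(x)
}
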