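#' Transformed AUC parameter for the sample-size calculation
#'
#' Computes the parameter \eqn{\alpha = \Phi^{-1}(\mathrm{AUC}) \times \sqrt{2}}
#' used by the binormal variance approximation of Hanley-type AUC precision
#' calculations. Two conventions for the \eqn{\sqrt{2}} factor and the normal
#' quantile are supported: `z_mode = "exact"` (the default) uses the
#' full-precision quantile and `sqrt(2)`, while `z_mode = "published"` uses the
#' truncated factor 1.414 as commonly printed in applied write-ups, so that
#' published arithmetic can be reproduced digit-for-digit. `z_override`
#' replaces the computed quantile with a supplied value (for the same
#' reproducibility purpose; see the methods vignette).
#'
#' @param auc_target expected AUC, strictly between 0.5 and 1.
#' @param z_mode `"exact"` (quantile via [stats::qnorm()], factor `sqrt(2)`)
#'   or `"published"` (factor 1.414).
#' @param z_override optional positive real replacing the computed normal
#'   quantile of `auc_target`.
#' @return the scalar \eqn{\alpha}.
#' @examples
#' alpha_from_auc(0.934)
#' alpha_from_auc(0.934, z_mode = "published", z_override = 1.5153)
#' @export
alpha_from_auc <- function(auc_target, z_mode = c("exact", "published"),
                           z_override = NULL) {
  z_mode <- match.arg(z_mode)
  if (!is.numeric(auc_target) || length(auc_target) != 1L ||
      auc_target <= 0.5 || auc_target >= 1) {
    stop("`auc_target` must be a single value in (0.5, 1)", call. = FALSE)
  }
  if (!is.null(z_override)) {
    if (!is.numeric(z_override) || length(z_override) != 1L || z_override <= 0)
      stop("`z_override` must be a single positive real", call. = FALSE)
    z <- z_override
  } else {
    z <- stats::qnorm(auc_target)
  }
  f <- if (z_mode == "published") 1.414 else sqrt(2)
  z * f
}

#' Variance of an estimated AUC under the binormal approximation
#'
#' \eqn{V(\widehat{AUC}) = (0.0099\, e^{-\alpha^2/2}) (6\alpha^2 + 16)},
#' where \eqn{\alpha} comes from [alpha_from_auc()]. The expression assumes
#' equal numbers of cases and controls.
#'
#' @param alpha non-negative transformed AUC parameter.
#' @return the variance term \eqn{V}.
#' @examples
#' auc_variance(2.142634)
#' @export
auc_variance <- function(alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) || alpha < 0)
    stop("`alpha` must be a single non-negative real", call. = FALSE)
  (0.0099 * exp(-alpha^2 / 2)) * (6 * alpha^2 + 16)
}

#' Required per-group sample size for estimating an AUC with given precision
#'
#' \eqn{n = \lceil z_{\alpha/2}^2\, V / d^2 \rceil} per group, where `d` is the
#' half-width of the desired confidence interval and \eqn{z_{\alpha/2}} is the
#' two-sided normal quantile of `conf_level` (1.96 at 95%). Rounding is by
#' ceiling (conservative).
#'
#' @param v_auc positive AUC variance term, from [auc_variance()].
#' @param d precision (CI half-width), in (0, 0.5).
#' @param conf_level confidence level, default 0.95.
#' @return list with `per_group` and `total` (= 2 * per_group), both integer.
#' @examples
#' required_n(0.043419, d = 0.05)
#' @export
required_n <- function(v_auc, d, conf_level = 0.95) {
  if (!is.numeric(v_auc) || length(v_auc) != 1L || v_auc <= 0)
    stop("`v_auc` must be a single positive real", call. = FALSE)
  if (!is.numeric(d) || length(d) != 1L || d <= 0 || d >= 0.5)
    stop("`d` must be a single value in (0, 0.5)", call. = FALSE)
  if (!is.numeric(conf_level) || length(conf_level) != 1L ||
      conf_level <= 0 || conf_level >= 1)
    stop("`conf_level` must be in (0, 1)", call. = FALSE)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  per_group <- as.integer(ceiling(z^2 * v_auc / d^2))
  list(per_group = per_group, total = 2L * per_group)
}

#' End-to-end AUC-precision sample-size calculation
#'
#' Chains [alpha_from_auc()], [auc_variance()] and [required_n()].
#'
#' @inheritParams alpha_from_auc
#' @inheritParams required_n
#' @return list with `alpha`, `v_auc`, `n_per_group`, `n_total`.
#' @examples
#' # reproduces a published calculation for a target AUC of 0.934
#' sample_size_auc(0.934, d = 0.05, z_mode = "published", z_override = 1.5153)
#' @export
sample_size_auc <- function(auc_target, d = 0.05, conf_level = 0.95,
                            z_mode = c("exact", "published"),
                            z_override = NULL) {
  alpha <- alpha_from_auc(auc_target, z_mode = z_mode, z_override = z_override)
  v <- auc_variance(alpha)
  n <- required_n(v, d = d, conf_level = conf_level)
  list(alpha = alpha, v_auc = v,
       n_per_group = n$per_group, n_total = n$total)
}
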