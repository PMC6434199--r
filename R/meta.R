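# Summary-level meta-analysis statistics: inverse-variance fixed-effect
# pooling, Cochran's Q / I-squared, and Egger's regression test.  These back
# the synthetic generator; the synopsis itself consumes published summaries.

#' Fixed-effect inverse-variance pooling
#'
#' Weights \code{w_i = 1/se_i^2}; pooled estimate \code{sum(w * theta) /
#' sum(w)} with standard error \code{sum(w)^(-1/2)}.
#'
#' @param log_ors per-study log odds ratios (k >= 1).
#' @param ses per-study standard errors (> 0).
#' @param ci_level confidence level for the pooled interval.
#' @return list with \code{pooled_log_or}, \code{pooled_se}, \code{ci_low},
#'   \code{ci_high} (OR scale) and \code{k}.
#' @export
pool_fixed <- function(log_ors, ses, ci_level = 0.95) {
  k <- length(log_ors)
  if (k == 0) stop("no studies to pool")
  stopifnot(length(ses) == k, all(ses > 0))
  w <- 1 / ses^2
  pooled <- sum(w * log_ors) / sum(w)
  se <- 1 / sqrt(sum(w))
  z <- qnorm((1 + ci_level) / 2)
  list(pooled_log_or = pooled, pooled_se = se,
       ci_low = exp(pooled - z * se), ci_high = exp(pooled + z * se), k = k)
}

#' Cochran's Q, its p-value and I-squared
#'
#' \code{Q = sum(w_i (theta_i - pooled)^2)}, chi-square with k - 1 df under
#' homogeneity; \code{I2 = max(0, (Q - (k-1)) / Q) * 100}.
#'
#' @inheritParams pool_fixed
#' @return list with \code{q_stat}, \code{q_p}, \code{i_squared}, \code{k}.
#' @export
heterogeneity <- function(log_ors, ses) {
  k <- length(log_ors)
  if (k < 2) stop("heterogeneity needs at least 2 studies")
  stopifnot(length(ses) == k, all(ses > 0))
  w <- 1 / ses^2
  pooled <- sum(w * log_ors) / sum(w)
  q <- sum(w * (log_ors - pooled)^2)
  i2 <- if (q > 0) max(0, (q - (k - 1)) / q) * 100 else 0
  list(q_stat = q, q_p = pchisq(q, df = k - 1, lower.tail = FALSE),
       i_squared = i2, k = k)
}

#' Egger's regression test for funnel-plot asymmetry
#'
#' Regresses the standard normal deviate \code{theta_i / se_i} on precision
#' \code{1 / se_i}; the intercept estimates small-study asymmetry and is
#' tested two-sided against a t distribution with k - 2 df.
#'
#' @inheritParams pool_fixed
#' @return list with \code{egger_intercept}, \code{egger_p}, \code{k}.
#' @export
egger_test <- function(log_ors, ses) {
  k <- length(log_ors)
  if (k < 3) stop("Egger's test needs at least 3 studies")
  stopifnot(length(ses) == k, all(ses > 0))
  if (length(unique(ses)) == 1) {
    # z = a + b/se is collinear when all ses coincide: asymmetry is
    # unidentifiable without a spread of study precisions
    stop("Egger's test needs studies of unequal precision")
  }
  z <- log_ors / ses
  prec <- 1 / ses
  fit <- lm(z ~ prec)
  est <- coef(summary(fit))
  intercept <- est["(Intercept)", "Estimate"]
  se_int <- est["(Intercept)", "Std. Error"]
  t_stat <- intercept / se_int
  p <- 2 * pt(abs(t_stat), df = k - 2, lower.tail = FALSE)
  list(egger_intercept = intercept, egger_p = min(1, p), k = k)
}

#' Meta-analysis summary of a set of studies
#'
#' Convenience wrapper combining \code{\link{pool_fixed}},
#' \code{\link{heterogeneity}} (k >= 2) and \code{\link{egger_test}}
#' (k >= 3); statistics whose minimum study count is not met are NA.
#'
#' @inheritParams pool_fixed
#' @return list merging the component results.
#' @export
meta_summary <- function(log_ors, ses, ci_level = 0.95) {
  out <- pool_fixed(log_ors, ses, ci_level)
  k <- out$k
  het <- if (k >= 2) heterogeneity(log_ors, ses) else
    list(q_stat = NA_real_, q_p = NA_real_, i_squared = NA_real_)
  egg <- if (k >= 3) {
    tryCatch(egger_test(log_ors, ses), error = function(e)
      list(egger_intercept = NA_real_, egger_p = NA_real_))
  } else list(egger_intercept = NA_real_, egger_p = NA_real_)
  c(out, het[c("q_stat", "q_p", "i_squared")],
    egg[c("egger_intercept", "egger_p")])
}
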