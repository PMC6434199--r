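# False-positive report probability (Wacholder-style) from summary OR + CI.
#
# All computations fold protective effects onto the risk scale (|log OR|)
# and use the convention that reproduces the published spreadsheet output:
# power to detect the target OR is evaluated with the critical value set at
# the observed z statistic, i.e. at significance level alpha = observed p.

#' FPRP configuration
#'
#' @param prior prior probability that the association is true (pi).
#' @param target_or target odds ratio the power term detects (theta > 1).
#' @param noteworthy_cutoff FPRP below this is "noteworthy".
#' @param strong_cutoff FPRP below this counts as strong (and triggers the
#'   one-step evidence upgrade); values above \code{noteworthy_cutoff}
#'   trigger the downgrade.
#' @param ci_level confidence level of the reported interval.
#' @return a list of class \code{fprp_config}.
#' @export
fprp_config <- function(prior = 0.001, target_or = 1.5,
                        noteworthy_cutoff = 0.2, strong_cutoff = 0.05,
                        ci_level = 0.95) {
  stopifnot(prior > 0, prior < 1, target_or > 1,
            strong_cutoff < noteworthy_cutoff,
            ci_level > 0, ci_level < 1)
  structure(list(prior = prior, target_or = target_or,
                 noteworthy_cutoff = noteworthy_cutoff,
                 strong_cutoff = strong_cutoff, ci_level = ci_level),
            class = "fprp_config")
}

#' Log-OR standard error recovered from a reported confidence interval
#'
#' \code{se = (log(ci_high) - log(ci_low)) / (2 * z_crit)} with
#' \code{z_crit = qnorm((1 + ci_level) / 2)} (1.959964 at 95\%).
#'
#' @param ci_low,ci_high positive CI bounds on the OR scale (vectorized).
#' @param ci_level confidence level, default 0.95.
#' @return standard error(s) of the log odds ratio.
#' @export
#' @examples
#' se_from_ci(1.33, 1.66)  # 0.05654
se_from_ci <- function(ci_low, ci_high, ci_level = 0.95) {
  stopifnot(all(ci_low > 0, na.rm = TRUE), ci_level > 0, ci_level < 1)
  if (any(ci_low >= ci_high, na.rm = TRUE)) {
    stop("degenerate interval: ci_low must be < ci_high")
  }
  (log(ci_high) - log(ci_low)) / (2 * qnorm((1 + ci_level) / 2))
}

#' Two-sided Wald p-value for a summary odds ratio
#'
#' Uses the complementary normal tail directly (\code{lower.tail = FALSE}),
#' accurate far beyond z = 40 where \code{1 - pnorm(z)} underflows.
#'
#' @param or_point odds ratio (> 0); protective values are folded via
#'   \code{|log OR|}.
#' @param se standard error of the log odds ratio (> 0).
#' @return two-sided p-value(s) in (0, 1].
#' @export
observed_p <- function(or_point, se) {
  stopifnot(all(or_point > 0, na.rm = TRUE), all(se > 0, na.rm = TRUE))
  z <- abs(log(or_point)) / se
  pmin(1, 2 * pnorm(z, lower.tail = FALSE))
}

#' Power to detect a target odds ratio at the observed significance level
#'
#' With \code{z_t = log(target_or)/se} and the critical value placed at the
#' observed statistic \code{z_obs = |log(or_point)|/se}:
#' \deqn{power = 1 - \Phi(z_{obs} - z_t) + \Phi(-z_{obs} - z_t)}
#' The second (opposite-tail) term is non-negligible for imprecise
#' estimates.  Protective ORs are folded to the risk scale, equivalent to
#' targeting \code{1/target_or}.
#'
#' @inheritParams observed_p
#' @param target_or target odds ratio (> 1), default 1.5.
#' @return power value(s) strictly inside (0, 1).
#' @export
#' @examples
#' power_to_detect(1.49, se_from_ci(1.33, 1.66))  # 0.547...
power_to_detect <- function(or_point, se, target_or = 1.5) {
  stopifnot(all(or_point > 0, na.rm = TRUE), all(se > 0, na.rm = TRUE),
            target_or > 1)
  z_obs <- abs(log(or_point)) / se
  z_t <- log(target_or) / se
  pnorm(z_obs - z_t, lower.tail = FALSE) + pnorm(-z_obs - z_t)
}

#' False-positive report probability
#'
#' \deqn{FPRP = \frac{p(1-\pi)}{p(1-\pi) + power\,\pi}}
#' where p is the observed two-sided p-value and \eqn{\pi} the prior
#' probability of a true association.
#'
#' @param p_obs observed p-value(s) in (0, 1].
#' @param power power to detect the target OR, in (0, 1).
#' @param prior prior probability of true association.
#' @return FPRP value(s) in [0, 1].
#' @export
fprp_value <- function(p_obs, power, prior = 0.001) {
  stopifnot(all(p_obs >= 0 & p_obs <= 1, na.rm = TRUE),
            all(power >= 0, na.rm = TRUE), prior > 0, prior <= 1)
  num <- p_obs * (1 - prior)
  den <- num + power * prior
  out <- ifelse(den == 0, 0, num / den)
  if (any(den == 0, na.rm = TRUE)) {
    warning("p_obs and power both zero: FPRP undefined, returning 0")
  }
  out
}

.fprp_category <- function(fprp, config) {
  ifelse(is.na(fprp), NA_character_,
         ifelse(fprp < config$strong_cutoff, "strong",
                ifelse(fprp <= config$noteworthy_cutoff, "moderate", "weak")))
}

#' FPRP assessment of association records
#'
#' Composes \code{\link{se_from_ci}}, \code{\link{observed_p}},
#' \code{\link{power_to_detect}} and \code{\link{fprp_value}} over a record
#' collection.  Rows lacking OR or CI yield \code{NA}.
#'
#' @param records an \code{\link{association_records}} data.frame (any
#'   data.frame with \code{or_point}, \code{ci_low}, \code{ci_high} works).
#' @param config an \code{\link{fprp_config}}.
#' @return \code{records} with columns \code{se}, \code{z_obs},
#'   \code{p_obs}, \code{power}, \code{fprp}, \code{fprp_category}
#'   (\code{strong} < 0.05, \code{moderate} 0.05-0.2, \code{weak} > 0.2)
#'   and \code{noteworthy} (\code{fprp < noteworthy_cutoff}) appended.
#' @export
fprp_assess <- function(records, config = fprp_config()) {
  stopifnot(inherits(config, "fprp_config"))
  ok <- !is.na(records$or_point) & !is.na(records$ci_low) &
    !is.na(records$ci_high)
  n <- nrow(records)
  se <- z_obs <- p_obs <- power <- fprp <- rep(NA_real_, n)
  se[ok] <- se_from_ci(records$ci_low[ok], records$ci_high[ok],
                       config$ci_level)
  z_obs[ok] <- abs(log(records$or_point[ok])) / se[ok]
  p_obs[ok] <- observed_p(records$or_point[ok], se[ok])
  power[ok] <- power_to_detect(records$or_point[ok], se[ok],
                               config$target_or)
  fprp[ok] <- fprp_value(p_obs[ok], power[ok], config$prior)
  records$se <- se
  records$z_obs <- z_obs
  records$p_obs <- p_obs
  records$power <- power
  records$fprp <- fprp
  records$fprp_category <- .fprp_category(fprp, config)
  records$noteworthy <- fprp < config$noteworthy_cutoff
  records
}
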