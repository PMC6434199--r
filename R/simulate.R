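# Synthetic case-control allele-count studies and their assembly into
# association records, emulating the data-generating process behind the
# extracted meta-analyses.  Everything is driven by R's RNG through a seed
# carried in the spec, so identical spec + seed reproduces identical output.

#' Specification of a synthetic case-control meta-analysis
#'
#' @param k_studies number of independent studies (>= 1).
#' @param n_cases,n_controls per-study sample sizes; scalars are recycled
#'   to length \code{k_studies}.
#' @param control_maf minor-allele frequency in controls, in (0, 1).
#' @param true_or true odds ratio of the tested contrast.
#' @param tau between-study SD of the log odds ratio (0 = homogeneous).
#' @param model genetic contrast: \code{allelic} (per-allele counts, 2n
#'   units), \code{dominant} (carriers under Hardy-Weinberg) or
#'   \code{recessive} (variant homozygotes).
#' @param censor_small_nonsig emulate publication bias by dropping
#'   non-significant studies smaller than the median study size.
#' @param seed integer RNG seed.
#' @return list of class \code{simulation_spec}.
#' @export
simulation_spec <- function(k_studies = 10, n_cases = 500, n_controls = 500,
                            control_maf = 0.3, true_or = 1.5, tau = 0,
                            model = c("allelic", "dominant", "recessive"),
                            censor_small_nonsig = FALSE, seed = 1L) {
  model <- match.arg(model)
  stopifnot(k_studies >= 1, all(n_cases > 0), all(n_controls > 0),
            control_maf > 0, control_maf < 1, true_or > 0, tau >= 0)
  structure(list(
    k_studies = as.integer(k_studies),
    n_cases = rep_len(as.integer(n_cases), k_studies),
    n_controls = rep_len(as.integer(n_controls), k_studies),
    control_maf = control_maf, true_or = true_or, tau = tau, model = model,
    censor_small_nonsig = censor_small_nonsig, seed = as.integer(seed)),
    class = "simulation_spec")
}

# exposure probability among controls implied by the genetic model
.control_exposure <- function(maf, model) {
  switch(model,
         allelic = maf,
         dominant = 1 - (1 - maf)^2,   # carrier frequency under HWE
         recessive = maf^2)
}

# number of sampling units per subject group
.exposure_units <- function(n, model) {
  if (model == "allelic") 2L * n else n
}

#' Simulate one case-control study
#'
#' The study's true log OR is \code{log(true_or) + Normal(0, tau^2)}.  The
#' control exposure probability comes from \code{control_maf} under the
#' genetic model; the case probability is the logit shift by the study log
#' OR.  Exposed counts are binomial; the 2x2 cells get a 0.5 continuity
#' correction only when a zero cell occurs.
#'
#' @param spec a \code{\link{simulation_spec}}.
#' @param study_index which study's sample sizes to use.
#' @return list (\code{SimulatedStudy}): cells \code{a} (exposed cases),
#'   \code{b} (unexposed cases), \code{c} (exposed controls), \code{d}
#'   (unexposed controls), plus \code{log_or}, \code{se}, \code{theta_true}.
#' @export
simulate_study <- function(spec, study_index = 1L) {
  stopifnot(inherits(spec, "simulation_spec"),
            study_index >= 1, study_index <= spec$k_studies)
  p0 <- .control_exposure(spec$control_maf, spec$model)
  if (p0 <= 0 || p0 >= 1) stop("degenerate control exposure probability")
  theta <- log(spec$true_or) + if (spec$tau > 0) rnorm(1, 0, spec$tau) else 0
  p1 <- plogis(qlogis(p0) + theta)
  if (p1 <= 0 || p1 >= 1) stop("degenerate case exposure probability")
  m_cases <- .exposure_units(spec$n_cases[study_index], spec$model)
  m_controls <- .exposure_units(spec$n_controls[study_index], spec$model)
  a <- rbinom(1, m_cases, p1)
  c_ <- rbinom(1, m_controls, p0)
  b <- m_cases - a
  d <- m_controls - c_
  cells <- c(a = a, b = b, c = c_, d = d)
  cc <- if (any(cells == 0)) 0.5 else 0
  log_or <- log((a + cc) * (d + cc) / ((b + cc) * (c_ + cc)))
  se <- sqrt(sum(1 / (cells + cc)))
  list(a = a, b = b, c = c_, d = d, log_or = log_or, se = se,
       theta_true = theta)
}

#' Simulate a full meta-analysis and assemble an association record
#'
#' Draws \code{k_studies} studies, optionally censors small non-significant
#' ones (publication-bias emulation), pools them with
#' \code{\link{meta_summary}} and packages the result as a one-row
#' \code{\link{association_records}} collection that passes validation and
#' can be graded end-to-end.  The record's \code{maf} is the pooled control
#' minor-allele frequency recovered from the observed control exposure
#' under the model's Hardy-Weinberg inverse; \code{test_count} is the total
#' observed count of test alleles/genotypes.
#'
#' @param spec a \code{\link{simulation_spec}}.
#' @param gene,variant labels for the synthetic record.
#' @return an \code{association_records} data.frame with one row and a
#'   \code{studies} attribute holding the per-study table.
#' @export
simulate_association <- function(spec, gene = "SIM", variant = "rs0") {
  stopifnot(inherits(spec, "simulation_spec"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)

  studies <- lapply(seq_len(spec$k_studies), function(i)
    simulate_study(spec, i))
  tab <- do.call(rbind, lapply(studies, function(s)
    data.frame(a = s$a, b = s$b, c = s$c, d = s$d,
               log_or = s$log_or, se = s$se)))
  tab$n_study <- spec$n_cases + spec$n_controls

  keep <- rep(TRUE, nrow(tab))
  if (spec$censor_small_nonsig && nrow(tab) > 1) {
    z <- abs(tab$log_or) / tab$se
    sig <- z > qnorm(0.975)
    small <- tab$n_study < median(tab$n_study)
    keep <- sig | !small
    if (!any(keep)) keep[which.max(tab$n_study)] <- TRUE
  }
  tab <- tab[keep, , drop = FALSE]
  ms <- meta_summary(tab$log_or, tab$se)

  m_controls <- .exposure_units(spec$n_controls[keep], spec$model)
  phat <- sum(tab$c) / sum(m_controls)
  maf_hat <- switch(spec$model,
                    allelic = phat,
                    dominant = 1 - sqrt(max(0, 1 - phat)),
                    recessive = sqrt(phat))
  maf_hat <- min(max(maf_hat, 1e-6), 1 - 1e-6)

  rec <- data.frame(
    gene = gene, variant = variant, cancer_type = "EC",
    year = NA_real_, model = spec$model, ethnicity = "diverse",
    or_point = exp(ms$pooled_log_or), ci_low = ms$ci_low,
    ci_high = ms$ci_high,
    egger_p = ms$egger_p, bias_tested = !is.na(ms$egger_p),
    het_p = ms$q_p, i_squared = ms$i_squared,
    n_studies = ms$k,
    n_total = sum(spec$n_cases[keep]) + sum(spec$n_controls[keep]),
    n_cases = sum(spec$n_cases[keep]), n_controls = sum(spec$n_controls[keep]),
    test_count = sum(tab$a) + sum(tab$c),
    maf = maf_hat, gwas_replicated = FALSE, source = "meta_analysis",
    stringsAsFactors = FALSE)
  rec <- association_records(rec)
  attr(rec, "studies") <- tab
  rec
}

#' Noteworthiness rate under the null
#'
#' Replicates \code{\link{simulate_association}} under \code{true_or = 1}
#' and reports the fraction of replicates whose FPRP falls below the
#' noteworthiness cutoff, alongside the fraction nominally significant
#' (p < 0.05).  With an informative prior the first is far below the
#' second: the FPRP screen absorbs most chance significance.
#'
#' @param spec a \code{\link{simulation_spec}} with \code{true_or = 1}.
#' @param n_replicates number of simulated meta-analyses.
#' @param config an \code{\link{fprp_config}}.
#' @return list with \code{rate_noteworthy}, \code{rate_significant},
#'   \code{n_replicates}.
#' @export
null_noteworthiness_rate <- function(spec, n_replicates = 2000,
                                     config = fprp_config()) {
  stopifnot(inherits(spec, "simulation_spec"), spec$true_or == 1)
  fprp <- p <- numeric(n_replicates)
  for (r in seq_len(n_replicates)) {
    s <- spec
    s$seed <- spec$seed + r - 1L
    rec <- fprp_assess(simulate_association(s), config)
    fprp[r] <- rec$fprp
    p[r] <- rec$p_obs
  }
  list(rate_noteworthy = mean(fprp < config$noteworthy_cutoff),
       rate_significant = mean(p < 0.05),
       n_replicates = n_replicates)
}
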