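# Cumulative evidence: FPRP-driven upgrade/downgrade of Venice levels,
# primary-analysis selection per variant, and summary tallies.

.level_rank <- c(strong = 3, moderate = 2, weak = 1)

#' FPRP adjustment of a Venice credibility level
#'
#' FPRP < 0.05 moves the level one step up (strong stays strong); FPRP >
#' 0.2 moves it one step down (weak stays weak); values in [0.05, 0.2]
#' leave it unchanged.  Ungraded input stays ungraded
#' (\code{adjustment = "not_applicable"}).  The move is at most one step and
#' re-applying with the same FPRP is idempotent in the tally sense (the
#' adjustment always starts from the Venice level, never from a previously
#' adjusted level).
#'
#' @param venice_level character vector in
#'   \code{strong/moderate/weak/ungraded} (NA treated as ungraded).
#' @param fprp_value numeric vector of FPRP values in [0, 1].
#' @param config an \code{\link{fprp_config}} supplying the 0.05 / 0.2
#'   cutoffs.
#' @return data.frame with \code{venice_level}, \code{fprp_value},
#'   \code{final_level} and \code{adjustment}
#'   (\code{upgraded/downgraded/unchanged/not_applicable}).
#' @export
adjust_evidence <- function(venice_level, fprp_value,
                            config = fprp_config()) {
  venice_level <- ifelse(is.na(venice_level), "ungraded", venice_level)
  stopifnot(all(venice_level %in% .levels_evidence))
  n <- length(venice_level)
  fprp_value <- rep_len(fprp_value, n)
  rank <- unname(.level_rank[venice_level])   # NA for ungraded
  step <- ifelse(is.na(fprp_value), 0,
                 ifelse(fprp_value < config$strong_cutoff, 1L,
                        ifelse(fprp_value > config$noteworthy_cutoff, -1L, 0L)))
  new_rank <- pmin(3L, pmax(1L, rank + step))
  final <- ifelse(is.na(rank), "ungraded",
                  c("weak", "moderate", "strong")[new_rank])
  adjustment <- ifelse(is.na(rank), "not_applicable",
                       ifelse(new_rank > rank, "upgraded",
                              ifelse(new_rank < rank, "downgraded",
                                     "unchanged")))
  data.frame(venice_level = venice_level, fprp_value = fprp_value,
             final_level = final, adjustment = adjustment,
             stringsAsFactors = FALSE)
}

#' Select the primary analysis within a group of records
#'
#' One published variant is usually reported several times (overall and
#' per-ethnicity, or per cancer subtype).  The headline analysis is the
#' diverse-population record when one exists, otherwise the record of the
#' sole reported ethnicity; remaining ties go to the larger total sample
#' size, then to the first row (input order).
#'
#' @param records non-empty \code{\link{association_records}} group sharing
#'   a (gene, variant) key.
#' @return a single-row data.frame.
#' @export
select_primary <- function(records) {
  if (nrow(records) == 0) stop("empty record group")
  cand <- records
  div <- !is.na(cand$ethnicity) & cand$ethnicity == "diverse"
  if (any(div)) cand <- cand[div, , drop = FALSE]
  if (nrow(cand) > 1) {
    nt <- ifelse(is.na(cand$n_total), -Inf, cand$n_total)
    cand <- cand[which.max(nt), , drop = FALSE]   # first max wins ties
  }
  cand
}

#' Tally cumulative-evidence levels over distinct variants
#'
#' Counts each distinct (gene, variant) pair once through its primary
#' analysis.  A curated \code{headline} flag, when present, pins the
#' editorial choice of primary row; otherwise \code{\link{select_primary}}
#' decides.  Ungraded variants are reported separately, never folded into
#' the strong/moderate/weak counts.
#'
#' @param assessments data.frame holding \code{gene}, \code{variant},
#'   \code{final_level} and optionally \code{headline}.
#' @return named integer vector
#'   \code{c(strong=, moderate=, weak=, ungraded=)}.
#' @export
summarize_evidence <- function(assessments) {
  counts <- setNames(integer(4), .levels_evidence)
  if (nrow(assessments) == 0) return(counts)
  key <- paste(assessments$gene, assessments$variant, sep = "\r")
  for (k in unique(key)) {
    grp <- assessments[key == k, , drop = FALSE]
    if (!is.null(grp$headline) && any(grp$headline %in% TRUE)) {
      row <- grp[which(grp$headline %in% TRUE)[1], , drop = FALSE]
    } else {
      row <- select_primary(grp)
    }
    lev <- row$final_level
    if (is.na(lev)) lev <- "ungraded"
    counts[lev] <- counts[lev] + 1L
  }
  counts
}

#' End-to-end cumulative-evidence assessment
#'
#' Runs the full pipeline over a record collection: Venice grading, FPRP
#' computation, and the FPRP adjustment.  Published grades and FPRP values
#' stored in the fixture columns (\code{venice_level}, \code{fprp_pub}) can
#' be substituted for the recomputed ones, which decouples the evidence
#' tally from the rounding noise of printed CIs.
#'
#' @param records an \code{\link{association_records}} data.frame.
#' @param config an \code{\link{fprp_config}}.
#' @param use_published_fprp take FPRP from the \code{fprp_pub} column.
#' @param use_published_grades take the Venice level from the
#'   \code{venice_level} column instead of regrading.
#' @return the records with FPRP/grading columns plus \code{final_level}
#'   and \code{adjustment}.
#' @export
assess_evidence <- function(records, config = fprp_config(),
                            use_published_fprp = FALSE,
                            use_published_grades = FALSE) {
  out <- venice_grade(fprp_assess(records, config))
  if (use_published_grades) {
    if (is.null(records$venice_level)) stop("no published venice_level column")
    out$venice_level <- records$venice_level    # curated level wins
  }
  fprp <- if (use_published_fprp) {
    if (is.null(records$fprp_pub)) stop("no published fprp_pub column")
    records$fprp_pub
  } else {
    out$fprp
  }
  adj <- adjust_evidence(out$venice_level, fprp, config)
  out$fprp_used <- adj$fprp_value
  out$final_level <- adj$final_level
  out$adjustment <- adj$adjustment
  out
}
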