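# Venice-criteria grading: amount of evidence, replication (heterogeneity),
# protection from bias; combined into strong / moderate / weak credibility.
#
# Grades are "A"/"B"/"C"; "X" marks an element that cannot be assessed
# (insufficient information) and blocks the combined level ("ungraded").

#' Amount-of-evidence grade from the test allele / genotype count
#'
#' A if count > 1000, B if 100 <= count <= 1000, C if count < 100, X if the
#' count is missing.  Boundary counts (100, 1000) fall in B.
#'
#' @param test_count non-negative count(s), NA allowed.
#' @return character vector of grades.
#' @export
amount_grade <- function(test_count) {
  ifelse(is.na(test_count), "X",
         ifelse(test_count > 1000, "A",
                ifelse(test_count >= 100, "B", "C")))
}

#' MAF-derived test-count bracket
#'
#' When a study does not report the test allele/genotype count, the bracket
#' \code{(round(n_total * maf), round(2 * n_total * maf))} -- the implied
#' genotype and allele counts at the database minor-allele frequency --
#' stands in.  The bracket is usable for amount grading only when its upper
#' bound is at least 3000; smaller calculated amounts are too far from the
#' true count to grade on.
#'
#' @param n_total total subjects (> 0), vectorized.
#' @param maf minor allele frequency in (0, 1).
#' @return data.frame with columns \code{low}, \code{high}, \code{usable}.
#' @export
#' @examples
#' calc_count_range(22935, 0.2985)  # 6846, 13692, usable
calc_count_range <- function(n_total, maf) {
  stopifnot(all(n_total > 0, na.rm = TRUE),
            all(maf > 0 & maf < 1, na.rm = TRUE))
  low <- round_half_up(n_total * maf, 0)
  high <- round_half_up(2 * n_total * maf, 0)
  data.frame(low = low, high = high, usable = !is.na(high) & high >= 3000)
}

#' Replication grade from I-squared
#'
#' A if I2 < 25\%, B if 25 <= I2 <= 50, C if I2 > 50, X if missing.  The
#' source bins are written as open intervals; both boundaries are assigned
#' to B (the choice is unobservable on the curated tables, no row sits on a
#' boundary).
#'
#' @param i_squared heterogeneity percentage(s) in [0, 100], NA allowed.
#' @return character vector of grades.
#' @export
replication_grade <- function(i_squared) {
  ifelse(is.na(i_squared), "X",
         ifelse(i_squared < 25, "A",
                ifelse(i_squared <= 50, "B", "C")))
}

#' Protection-from-bias grade
#'
#' Rule order per record: an explicit \code{bias_override} wins; a
#' significant Egger test (p < 0.05) gives C; a weak effect magnitude
#' (\code{max(OR, 1/OR) < 1.15}) gives C unless the association was
#' replicated by GWAS; no bias information at all (no Egger p and
#' \code{bias_tested} FALSE) gives X; otherwise A.  B is reachable only via
#' the override, which encodes a qualitative "bias could be present"
#' judgement that the summary columns cannot derive.
#'
#' @param records an \code{\link{association_records}} data.frame.
#' @return character vector of grades.
#' @export
bias_grade <- function(records) {
  n <- nrow(records)
  or_mag <- pmax(records$or_point, 1 / records$or_point)
  egger <- records$egger_p
  tested <- records$bias_tested
  tested[is.na(tested)] <- !is.na(egger[is.na(tested)])
  out <- rep("A", n)
  out[!is.na(egger) & egger < 0.05] <- "C"
  weak_mag <- out != "C" & !is.na(or_mag) & or_mag < 1.15 &
    !records$gwas_replicated
  out[weak_mag] <- "C"
  no_info <- out == "A" & is.na(egger) & !tested
  out[no_info] <- "X"
  ov <- !is.na(records$bias_override)
  out[ov] <- records$bias_override[ov]
  out
}

.combine_grades <- function(amount, replication, bias) {
  g <- cbind(amount, replication, bias)
  any_x <- apply(g == "X", 1, any)
  all_a <- apply(g == "A", 1, all)
  any_c <- apply(g == "C", 1, any)
  ifelse(any_x, "ungraded",
         ifelse(all_a, "strong", ifelse(any_c, "weak", "moderate")))
}

#' Venice-criteria grade for association records
#'
#' Assigns the three element grades and the combined level: all A = strong,
#' any C = weak (when no element is X), anything else = moderate; any X =
#' ungraded.  The amount element uses the observed \code{test_count} when
#' present, otherwise the MAF-calculated bracket
#' (\code{\link{calc_count_range}}) subject to its >= 3000 usability rule,
#' grading on the bracket's lower (genotype-scale) bound.
#'
#' @param records an \code{\link{association_records}} data.frame.
#' @return \code{records} with columns \code{amount}, \code{replication},
#'   \code{bias}, \code{grade_str} (e.g. \code{"ABA"}, \code{X} for
#'   unassessable elements) and \code{venice_level} appended.
#' @export
venice_grade <- function(records) {
  n <- nrow(records)
  count <- records$test_count
  need_calc <- is.na(count)
  if (any(need_calc)) {
    ok <- need_calc & !is.na(records$n_total) & !is.na(records$maf)
    if (any(ok)) {
      rng <- calc_count_range(records$n_total[ok], records$maf[ok])
      use <- rng$usable
      count[ok][use] <- rng$low[use]
    }
  }
  amount <- amount_grade(count)
  replication <- replication_grade(records$i_squared)
  bias <- if (n > 0) bias_grade(records) else character(0)
  records$amount <- amount
  records$replication <- replication
  records$bias <- bias
  records$grade_str <- paste0(amount, replication, bias)
  records$venice_level <- if (n > 0)
    .combine_grades(amount, replication, bias) else character(0)
  records
}
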