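# Association summary records: schema, validation, tabular I/O, fixtures.
#
# A record collection is a plain data.frame with class "association_records".
# One row = one published association analysis (gene x variant x cancer type
# x genetic model x ethnicity).  Missing values are written as "Na", the
# token used by the source tables; numbers may contain internal spaces
# ("22 935") which are stripped on input.

.record_numeric_cols <- c(
  "year", "or_point", "ci_low", "ci_high", "egger_p", "het_p", "i_squared",
  "n_studies", "n_total", "n_cases", "n_controls", "test_count",
  "calc_low", "calc_high", "maf", "power_pub", "fprp_pub", "maf_case"
)
.record_logical_cols <- c("bias_tested", "gwas_replicated", "significant",
                          "headline")
.record_required <- c("gene", "variant", "cancer_type", "model", "ethnicity")

#' Construct / validate a collection of association summary records
#'
#' Coerces a data.frame to the \code{association_records} class after
#' checking the schema invariants: CI bounds bracket the odds ratio,
#' probabilities and the MAF lie in their ranges, counts are non-negative,
#' and case + control totals agree with the overall sample size when all
#' three are present.  Validation is total: every offence is reported with
#' its row and column.
#'
#' @param df data.frame with at least the key columns \code{gene},
#'   \code{variant}, \code{cancer_type}, \code{model}, \code{ethnicity} and
#'   the effect columns \code{or_point}, \code{ci_low}, \code{ci_high}.
#' @return the validated data.frame, classed \code{association_records},
#'   with missing optional columns filled with \code{NA} and a
#'   \code{significant} column added (strict CI-excludes-1 rule) when absent.
#' @export
association_records <- function(df) {
  stopifnot(is.data.frame(df))
  df <- as.data.frame(df, stringsAsFactors = FALSE)

  missing_req <- setdiff(c(.record_required, "or_point", "ci_low", "ci_high"),
                         names(df))
  if (length(missing_req) > 0) {
    stop("missing required column(s): ", paste(missing_req, collapse = ", "))
  }
  optional <- c(.record_numeric_cols, .record_logical_cols,
                "bias_override", "source", "pmid")
  for (col in setdiff(optional, names(df))) {
    fill <- if (col %in% .record_logical_cols) NA else
      if (col %in% .record_numeric_cols) NA_real_ else NA_character_
    df[[col]] <- rep(fill, nrow(df))
  }
  df$source[is.na(df$source)] <- "meta_analysis"
  df$gwas_replicated[is.na(df$gwas_replicated)] <- FALSE
  # absent bias information defaults to "tested iff an Egger p is recorded"
  df$bias_tested[is.na(df$bias_tested)] <- !is.na(df$egger_p[is.na(df$bias_tested)])

  problems <- validate_records(df, stop_on_error = FALSE)
  if (length(problems) > 0) {
    stop("invalid association records:\n  ",
         paste(problems, collapse = "\n  "))
  }
  if (!"significant" %in% names(df) || all(is.na(df$significant))) {
    df$significant <- is_significant(df)
  }
  class(df) <- c("association_records", "data.frame")
  df
}

#' Validate association records
#'
#' @param df data.frame in the record schema.
#' @param stop_on_error stop at the first report (default) or return the
#'   character vector of located problems.
#' @return invisibly \code{TRUE}, or the problem vector when
#'   \code{stop_on_error = FALSE}.
#' @export
validate_records <- function(df, stop_on_error = TRUE) {
  problems <- character(0)
  note <- function(rows, col, what) {
    if (any(rows, na.rm = TRUE)) {
      problems <<- c(problems, sprintf("row %s, column %s: %s",
                                       paste(which(rows), collapse = ","),
                                       col, what))
    }
  }
  in01 <- function(x) !is.na(x) & (x < 0 | x > 1)

  note(!is.na(df$or_point) & df$or_point <= 0, "or_point", "must be > 0")
  note(!is.na(df$ci_low) & df$ci_low <= 0, "ci_low", "must be > 0")
  bad_order <- !is.na(df$ci_low) & !is.na(df$ci_high) & df$ci_low > df$ci_high
  note(bad_order, "ci_low/ci_high", "lower CI bound exceeds upper bound")
  bad_bracket <- !is.na(df$or_point) & !is.na(df$ci_low) & !is.na(df$ci_high) &
    !bad_order & (df$or_point < df$ci_low | df$or_point > df$ci_high)
  note(bad_bracket, "or_point", "odds ratio outside its own CI")
  note(in01(df$egger_p), "egger_p", "p-value outside [0,1]")
  note(in01(df$het_p), "het_p", "p-value outside [0,1]")
  note(!is.na(df$i_squared) & (df$i_squared < 0 | df$i_squared > 100),
       "i_squared", "percentage outside [0,100]")
  note(!is.na(df$maf) & (df$maf <= 0 | df$maf >= 1), "maf",
       "must lie strictly in (0,1)")
  for (col in c("n_studies", "n_total", "n_cases", "n_controls",
                "test_count")) {
    note(!is.na(df[[col]]) & df[[col]] < 0, col, "negative count")
  }
  all3 <- !is.na(df$n_total) & !is.na(df$n_cases) & !is.na(df$n_controls)
  note(all3 & df$n_cases + df$n_controls != df$n_total, "n_total",
       "cases + controls do not sum to the total")
  note(!is.na(df$cancer_type) & !df$cancer_type %in% .levels_cancer,
       "cancer_type", paste("must be one of", paste(.levels_cancer, collapse = "/")))
  note(!is.na(df$model) & !df$model %in% .levels_model, "model",
       paste("must be one of", paste(.levels_model, collapse = "/")))
  note(!is.na(df$ethnicity) & !df$ethnicity %in% .levels_ethnicity,
       "ethnicity", paste("must be one of", paste(.levels_ethnicity, collapse = "/")))
  note(!is.na(df$bias_override) & !df$bias_override %in% c("A", "B", "C"),
       "bias_override", "must be A, B or C")
  note(!is.na(df$source) & !df$source %in% .levels_source, "source",
       paste("must be one of", paste(.levels_source, collapse = "/")))

  if (stop_on_error && length(problems) > 0) {
    stop("invalid association records:\n  ",
         paste(problems, collapse = "\n  "))
  }
  if (stop_on_error) invisible(TRUE) else problems
}

# "22 935" -> 22935; "1.21E-11" kept; "Na"/"" -> NA; anything else -> error
.parse_numeric <- function(x, col) {
  x <- trimws(x)
  x[x %in% c("", "Na", "NA", "na")] <- NA
  x <- gsub("(?<=[0-9]) (?=[0-9])", "", x, perl = TRUE)
  out <- suppressWarnings(as.numeric(x))
  bad <- which(!is.na(x) & is.na(out))
  if (length(bad) > 0) {
    stop(sprintf("row %s, column %s: malformed number %s",
                 paste(bad, collapse = ","), col,
                 paste(sQuote(x[bad]), collapse = ", ")))
  }
  out
}

# split "1.49 (1.33-1.66)" (ASCII hyphen, en dash or U+2010) into 3 numbers
.parse_or_ci <- function(x) {
  x <- gsub("[‐‑‒–—]", "-", x)
  m <- regmatches(x, regexec(
    "^\\s*([0-9.]+)\\s*\\(\\s*([0-9. ]+?)\\s*-\\s*([0-9. ]+)\\s*\\)\\s*$", x))
  bad <- which(!is.na(x) & x != "Na" & lengths(m) != 4L)
  if (length(bad) > 0) {
    stop(sprintf("row %s, column or_ci: cannot parse %s",
                 paste(bad, collapse = ","),
                 paste(sQuote(x[bad]), collapse = ", ")))
  }
  pick <- function(i) .parse_numeric(vapply(m, function(g)
    if (length(g) == 4L) g[i + 1L] else NA_character_, ""), "or_ci")
  data.frame(or_point = pick(1), ci_low = pick(2), ci_high = pick(3))
}

#' Read association summary records from a delimited file
#'
#' Accepts either separate \code{or_point}/\code{ci_low}/\code{ci_high}
#' columns or a single \code{or_ci} column in the table notation
#' \code{"1.49 (1.33-1.66)"}.  Missing cells are \code{"Na"} or empty;
#' numbers may contain internal spaces.  Row order is preserved and every
#' row is validated (malformed cells raise an error naming row and column).
#'
#' @param path file to read.
#' @param dialect \code{"tsv"} (default) or \code{"csv"}.
#' @return an \code{\link{association_records}} data.frame.
#' @export
read_records <- function(path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- read.delim(path, sep = if (dialect == "tsv") "\t" else ",",
                    colClasses = "character", check.names = FALSE,
                    na.strings = NULL, fileEncoding = "UTF-8")
  if (nrow(raw) == 0 && !all(c("or_point", "or_ci") %in% names(raw))) {
    # header-only file: fabricate empty typed columns below
  }
  df <- raw
  if ("or_ci" %in% names(df) && !"or_point" %in% names(df)) {
    df <- cbind(df[setdiff(names(df), "or_ci")], .parse_or_ci(df$or_ci))
  }
  for (col in intersect(.record_numeric_cols, names(df))) {
    df[[col]] <- .parse_numeric(df[[col]], col)
  }
  for (col in intersect(.record_logical_cols, names(df))) {
    v <- trimws(df[[col]])
    v[v %in% c("", "Na", "NA", "na")] <- NA
    df[[col]] <- as.logical(v)
  }
  for (col in names(df)[vapply(df, is.character, TRUE)]) {
    v <- trimws(df[[col]])
    v[v %in% c("", "Na", "NA", "na")] <- NA
    df[[col]] <- v
  }
  association_records(df)
}

#' Write association summary records
#'
#' Inverse of \code{\link{read_records}}: \code{read_records(write_records(x))}
#' reproduces \code{x} field for field at stored precision.  Missing values
#' are written as \code{"Na"}.
#'
#' @param records an \code{association_records} data.frame.
#' @param path output file.
#' @param dialect \code{"tsv"} (default) or \code{"csv"}.
#' @return invisibly, \code{path}.
#' @export
write_records <- function(records, path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  out <- as.data.frame(records)
  for (col in names(out)) {
    v <- out[[col]]
    v <- if (is.numeric(v)) format(v, trim = TRUE, scientific = FALSE,
                                   drop0trailing = TRUE) else as.character(v)
    v[is.na(out[[col]]) | v == "NA"] <- "Na"
    out[[col]] <- v
  }
  write.table(out, path, sep = if (dialect == "tsv") "\t" else ",",
              quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Strict CI significance rule
#'
#' TRUE iff 1.0 lies outside the closed interval [ci_low, ci_high].  This is
#' advisory: curated fixtures carry a per-record \code{significant} flag
#' because printed CI bounds are rounded (a bound printed as exactly 1.00
#' can belong to an association classified significant from unrounded data).
#'
#' @param records an \code{association_records} data.frame (or any
#'   data.frame with \code{ci_low}/\code{ci_high}).
#' @return logical vector.
#' @export
is_significant <- function(records) {
  records$ci_low > 1 | records$ci_high < 1
}

#' Packaged synopsis fixtures
#'
#' Curated summary tables from a published esophageal-cancer field synopsis:
#' \code{"meta"} holds the statistically significant meta-analysis
#' associations (38 distinct gene-variant pairs, incl. non-significant
#' subgroup rows), with published Venice grades, power, FPRP and final
#' evidence levels in the \code{*_pub} columns; \code{"gwas"} holds the 17
#' genome-wide significant associations from six GWAS.
#'
#' @param which \code{"meta"} or \code{"gwas"}.
#' @return an \code{\link{association_records}} data.frame with a
#'   \code{label} attribute.
#' @export
fixture_records <- function(which = c("meta", "gwas")) {
  which <- match.arg(which)
  f <- system.file("extdata",
                   if (which == "meta") "esca_meta_synopsis.tsv"
                   else "esca_gwas_catalog.tsv",
                   package = "evigrade", mustWork = TRUE)
  rec <- read_records(f, "tsv")
  attr(rec, "label") <- which
  rec
}
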