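# small record collections built in code, shared across test files

make_records <- function(n = 2) {
  df <- data.frame(
    gene = paste0("G", seq_len(n)),
    variant = paste0("rs", seq_len(n)),
    cancer_type = "EC", year = 2015, model = "additive",
    ethnicity = "diverse",
    or_point = seq(1.2, 1.2 + 0.1 * (n - 1), by = 0.1),
    ci_low = seq(1.05, 1.05 + 0.1 * (n - 1), by = 0.1),
    ci_high = seq(1.40, 1.40 + 0.1 * (n - 1), by = 0.1),
    i_squared = 10, test_count = 1500, egger_p = 0.5,
    stringsAsFactors = FALSE)
  association_records(df)
}

# one-row record with free fields, for grading edge cases
one_record <- function(...) {
  base <- list(gene = "G", variant = "rs1", cancer_type = "EC", year = 2000,
               model = "additive", ethnicity = "diverse",
               or_point = 1.5, ci_low = 1.2, ci_high = 1.9)
  args <- utils::modifyList(base, list(...))
  association_records(as.data.frame(args, stringsAsFactors = FALSE))
}

meta_fix <- function() fixture_records("meta")
gwas_fix <- function() fixture_records("gwas")

row_key <- function(df) {
  paste(df$gene, df$variant, df$ethnicity, df$cancer_type, sep = "|")
}

# meta-fixture rows whose printed FPRP drifts >0.01 from the value
# recomputed from the printed (rounded) CI: frozen documented list, deltas
# surfaced by verify_fixture() -- see the methods vignette.
fprp_drift_keys <- c(
  "ERCC2|rs13181|diverse|EC", "Fas|rs2234767|diverse|EC",
  "MMP1|rs1799750|diverse|EC", "MTHFR|rs1801133|Asian|EC",
  "hOGG1|rs1052133|diverse|EC", "hOGG1|rs1052133|Asian|EC",
  "hOGG1|rs1052133|diverse|ESCC", "C20orf54|rs13042395|diverse|ESCC",
  "CASP8|rs3834129|Asian|EC", "CYP2E1|RsaI/PstI|Asian|EC",
  "MMP2|rs243865|Asian|EC", "SLC52A3|rs13042395|diverse|EC",
  "COX-2|rs20417|Asian|EC", "ERCC2|rs1799793|diverse|EC",
  "GSTM1|null/present|diverse|EC", "MDM2|rs2279744|diverse|EC",
  "MDM2|rs2279744|Asian|EC", "TP53|rs1042522|diverse|EC",
  "XRCC1|rs1799782|Asian|ESCC")

# rows where the printed replication grade contradicts the stated I^2 bins
# (B printed at I^2 = 68% / 61%); excluded from exact grade reproduction
grade_anomaly_keys <- c("PLCE1|rs2274223|diverse|EC", "PLCE1|rs2274223|Asian|EC")
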