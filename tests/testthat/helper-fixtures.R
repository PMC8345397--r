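# Shared in-code fixtures: tiny panels, cohorts and VCFs built at test time.

make_panel <- function(n = 3, beta = NULL, eaf = NULL, r2 = NULL, genotyped = NULL) {
  tibble::tibble(
    variant_id = sprintf("rs%d", seq_len(n)),
    chrom = as.character(rep_len(1:22, n)),
    pos = 1000L * seq_len(n),
    effect_allele = rep_len(c("A", "C", "G", "T"), n),
    other_allele = rep_len(c("G", "T", "A", "C"), n),
    beta = if (is.null(beta)) rep(0.1, n) else beta,
    eaf = if (is.null(eaf)) rep(0.3, n) else eaf,
    genotyped = if (is.null(genotyped)) rep(FALSE, n) else genotyped,
    imputation_r2 = if (is.null(r2)) rep(0.9, n) else r2,
    included = TRUE
  )
}

make_dosages <- function(mat, panel, ids = NULL) {
  mat <- as.matrix(mat)
  rownames(mat) <- if (is.null(ids)) sprintf("ind%03d", seq_len(nrow(mat))) else ids
  colnames(mat) <- panel$variant_id[seq_len(ncol(mat))]
  mat
}

make_cohort <- function(groups, ids = NULL) {
  n <- length(groups)
  tibble::tibble(
    individual_id = if (is.null(ids)) sprintf("ind%03d", seq_len(n)) else ids,
    group = groups,
    sex = rep_len(c("male", "female"), n),
    age = seq(40, 70, length.out = n),
    crc_affected = groups %in% c("fcrc", "sporadic_crc"),
    age_at_dx = ifelse(groups %in% c("fcrc", "sporadic_crc"), seq(40, 70, length.out = n), NA_real_),
    fam_history_crc = rep_len(c("yes", "no"), n),
    fam_history_any = rep_len(c("yes", "no"), n),
    multiple_crc = rep_len(c(TRUE, FALSE), n),
    multiple_any = rep_len(c(TRUE, FALSE), n),
    criteria = ifelse(groups == "fcrc", "bethesda", "none"),
    deceased = rep_len(c("alive", "deceased"), n)
  )
}

write_panel_tsv <- function(panel, path) {
  p <- panel
  p$imputation_r2 <- ifelse(p$genotyped, "genotyped", as.character(p$imputation_r2))
  readr::write_tsv(p[, c("variant_id", "chrom", "pos", "effect_allele", "other_allele",
                         "beta", "eaf", "imputation_r2")], path, progress = FALSE)
  path
}

# Minimal single-sample-block VCF writer for IO tests.
write_test_vcf <- function(path, records, samples, format = "GT") {
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Dosage\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO", "FORMAT", samples),
          collapse = "\t")
  )
  body <- vapply(records, function(r) {
    paste(c(r$chrom, r$pos, r$id, r$ref, r$alt, ".", "PASS", ".", format, r$values),
          collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  path
}

# A fixed 2x2 logistic test-bed: expand a table into individual rows.
table_to_individuals <- function(a, b, c, d) {
  tibble::tibble(
    exposed = c(rep(1, a + b), rep(0, c + d)),
    case = c(rep(1, a), rep(0, b), rep(1, c), rep(0, d))
  )
}
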