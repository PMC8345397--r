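#' Read a variant weight panel
#'
#' Reads the tabular weight panel that defines the score: one row per risk
#' variant with its effect (risk) allele, per-allele log-odds weight, effect
#' allele frequency and post-imputation quality. Directly genotyped variants
#' carry the flag `"genotyped"` in place of an imputation R-squared.
#'
#' @param path Path to a tab- or comma-separated file with a header naming at
#'   least `variant_id`, `chrom`, `pos`, `effect_allele`, `other_allele`,
#'   `beta`, `eaf`, `imputation_r2`.
#' @return A tibble with the columns above plus `genotyped` (logical),
#'   `imputation_r2` (numeric, `NA` when genotyped) and `included` (logical,
#'   all `TRUE` on read; downstream filters only ever clear it).
#' @seealso [filter_by_imputation_r2()]
#' @export
read_weights_table <- function(path) {
  if (!file.exists(path)) stop("weights table not found: ", path)
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(.default = readr::col_character()),
                           progress = FALSE)
  validate_panel_columns(raw)
  panel <- tibble::tibble(
    variant_id    = raw$variant_id,
    chrom         = as.character(raw$chrom),
    pos           = as.integer(raw$pos),
    effect_allele = toupper(raw$effect_allele),
    other_allele  = toupper(raw$other_allele),
    beta          = as.numeric(raw$beta),
    eaf           = as.numeric(raw$eaf),
    genotyped     = tolower(raw$imputation_r2) %in% c("genotyped", "typed"),
    imputation_r2 = suppressWarnings(as.numeric(raw$imputation_r2))
  )
  panel$included <- TRUE
  validate_panel(panel)
}

validate_panel_columns <- function(df) {
  required <- c("variant_id", "chrom", "pos", "effect_allele", "other_allele",
                "beta", "eaf", "imputation_r2")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("weights table is missing required column(s): ", paste(missing, collapse = ", "))
  }
  invisible(df)
}

#' Validate a variant panel
#'
#' Enforces the panel invariants: unique variant ids, distinct alleles drawn
#' from A/C/G/T (or indel strings), allele frequencies in \[0, 1\], and an
#' imputation R-squared for every non-genotyped variant.
#'
#' @param panel A panel tibble as returned by [read_weights_table()].
#' @return The panel, invisibly unchanged, or an error describing the first
#'   violated invariant.
#' @export
validate_panel <- function(panel) {
  dup <- panel$variant_id[duplicated(panel$variant_id)]
  if (length(dup) > 0) {
    stop("duplicated variant id(s) in panel: ", paste(unique(dup), collapse = ", "))
  }
  allele_ok <- grepl("^[ACGT]+$", panel$effect_allele) & grepl("^[ACGT]+$", panel$other_allele)
  if (any(!allele_ok)) {
    stop("malformed allele(s) for: ",
         paste(panel$variant_id[!allele_ok], collapse = ", "))
  }
  same <- panel$effect_allele == panel$other_allele
  if (any(same)) {
    stop("effect and other allele identical for: ",
         paste(panel$variant_id[same], collapse = ", "))
  }
  bad_eaf <- is.na(panel$eaf) | panel$eaf < 0 | panel$eaf > 1
  if (any(bad_eaf)) {
    stop("effect-allele frequency outside [0, 1] for: ",
         paste(panel$variant_id[bad_eaf], collapse = ", "))
  }
  no_r2 <- !panel$genotyped & is.na(panel$imputation_r2)
  if (any(no_r2)) {
    stop("missing imputation R2 for non-genotyped variant(s): ",
         paste(panel$variant_id[no_r2], collapse = ", "))
  }
  panel
}

#' Filter panel variants by imputation quality
#'
#' Marks imputed variants whose imputation R-squared falls strictly below
#' `threshold` as excluded (`included = FALSE`). Directly genotyped variants
#' are always retained. The filter only ever clears the `included` flag, so
#' repeated application is idempotent and raising the threshold never
#' re-includes a variant.
#'
#' @param panel A panel tibble.
#' @param threshold Exclusion threshold in (0, 1]; variants with
#'   R-squared `< threshold` are dropped. Default 0.3, the conventional
#'   post-imputation quality cutoff.
#' @return The panel with `included` updated; the per-variant exclusion log is
#'   attached as attribute `"exclusions"` (tibble: `variant_id`, `reason`).
#' @export
filter_by_imputation_r2 <- function(panel, threshold = 0.3) {
  stopifnot(is.numeric(threshold), length(threshold) == 1)
  if (threshold <= 0 || threshold > 1) stop("threshold must be in (0, 1]")
  keep <- panel$genotyped | (!is.na(panel$imputation_r2) & panel$imputation_r2 >= threshold)
  newly_excluded <- panel$included & !keep
  panel$included <- panel$included & keep
  prior <- attr(panel, "exclusions")
  log <- tibble::tibble(
    variant_id = panel$variant_id[newly_excluded],
    reason = sprintf("imputation_r2 %.4g < %.4g",
                     panel$imputation_r2[newly_excluded], threshold)
  )
  attr(panel, "exclusions") <- dplyr::bind_rows(prior, log)
  if (!any(panel$included)) warning("no variants remain included after imputation-R2 filter")
  panel
}

#' Read a cohort phenotype table
#'
#' @param path TSV/CSV with a header; requires `individual_id`, `group`,
#'   `sex`, `age`; recognises the optional clinical columns `crc_affected`,
#'   `age_at_dx`, `fam_history_crc`, `fam_history_any`, `multiple_crc`,
#'   `multiple_any`, `criteria`, `deceased`.
#' @return A validated cohort tibble; `group` is one of `control`,
#'   `sporadic_crc`, `fcrc`, `sp`.
#' @export
read_cohort_table <- function(path) {
  if (!file.exists(path)) stop("cohort table not found: ", path)
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- readr::read_delim(path, delim = delim, show_col_types = FALSE, progress = FALSE)
  validate_cohort(tibble::as_tibble(df))
}

#' Validate a cohort table
#'
#' @param cohort A cohort tibble.
#' @return The cohort tibble, or an error for the first violated invariant.
#' @export
validate_cohort <- function(cohort) {
  required <- c("individual_id", "group", "sex", "age")
  missing <- setdiff(required, names(cohort))
  if (length(missing) > 0) stop("cohort table missing column(s): ", paste(missing, collapse = ", "))
  groups <- c("control", "sporadic_crc", "fcrc", "sp")
  bad <- setdiff(unique(cohort$group), groups)
  if (length(bad) > 0) stop("unknown group label(s): ", paste(bad, collapse = ", "))
  if (anyDuplicated(cohort$individual_id)) stop("duplicated individual ids in cohort table")
  if (!all(cohort$sex %in% c("male", "female"))) stop("sex must be 'male' or 'female'")
  if ("crc_affected" %in% names(cohort) && "age_at_dx" %in% names(cohort)) {
    orphan <- cohort$crc_affected & is.na(cohort$age_at_dx) & cohort$group != "sp"
    if (any(orphan)) stop("age_at_dx missing for CRC-affected individual(s): ",
                          paste(utils::head(cohort$individual_id[orphan], 5), collapse = ", "))
  }
  cohort
}

#' Write a dosage matrix to the internal text format
#'
#' One row per individual, one column per variant, `NA` for missing dosages.
#' Doubles are serialised with 17 significant digits so a write/read
#' round-trip is bit-exact.
#'
#' @param dosages Numeric matrix (individuals x variants) with dimnames.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_dosage_matrix <- function(dosages, path) {
  stopifnot(is.matrix(dosages), !is.null(rownames(dosages)), !is.null(colnames(dosages)))
  chr <- apply(dosages, 2, function(col) ifelse(is.na(col), "NA", sprintf("%.17g", col)))
  if (nrow(dosages) == 1L) chr <- matrix(chr, nrow = 1L, dimnames = dimnames(dosages))
  out <- cbind(individual_id = rownames(dosages), chr)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a dosage matrix from the internal text format
#'
#' @param path TSV written by [write_dosage_matrix()].
#' @return Numeric matrix (individuals x variants), `NA` marking missing.
#' @export
read_dosage_matrix <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          colClasses = "character")
  ids <- df[[1]]
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  bad <- !is.na(m) & (m < 0 | m > 2)
  if (any(bad)) stop("dosage outside [0, 2] in ", path)
  m
}

complement_allele <- function(a) {
  chartr("ACGT", "TGCA", a)
}

is_strand_ambiguous <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

#' Harmonize a genotype record onto the panel's effect allele
#'
#' Converts an ALT-allele dosage from a genotype record to an effect-allele
#' dosage for a panel variant. If the record's ALT is the effect allele the
#' dosage passes through; if REF is the effect allele the dosage is flipped to
#' `2 - dosage`. Non-ambiguous records whose alleles only match after strand
#' complementation are accepted on the complemented strand. Strand-ambiguous
#' pairs (A/T, C/G) are handled per `ambiguity_policy`; irreconcilable allele
#' pairs degrade to missing. All arguments are vectorised.
#'
#' @param ref,alt Record REF and ALT alleles (ALT dosage convention).
#' @param dosage Numeric ALT dosage in \[0, 2\] (`NA` allowed).
#' @param effect_allele,other_allele Panel alleles for the variant.
#' @param ambiguity_policy `"drop"` (default; A/T and C/G records become
#'   missing) or `"keep"` (scored assuming same-strand reporting).
#' @return Numeric vector of effect-allele dosages, `NA` where the record
#'   could not be reconciled; attribute `"reasons"` records why.
#' @export
harmonize_alleles <- function(ref, alt, dosage, effect_allele, other_allele,
                              ambiguity_policy = c("drop", "keep")) {
  ambiguity_policy <- match.arg(ambiguity_policy)
  n <- length(dosage)
  ref <- rep_len(toupper(ref), n); alt <- rep_len(toupper(alt), n)
  effect_allele <- rep_len(toupper(effect_allele), n)
  other_allele <- rep_len(toupper(other_allele), n)
  out <- rep(NA_real_, n)
  reason <- rep(NA_character_, n)

  ambiguous <- is_strand_ambiguous(ref, alt)
  direct  <- alt == effect_allele & ref == other_allele
  swapped <- ref == effect_allele & alt == other_allele
  cref <- complement_allele(ref); calt <- complement_allele(alt)
  flip_direct  <- !ambiguous & calt == effect_allele & cref == other_allele
  flip_swapped <- !ambiguous & cref == effect_allele & calt == other_allele

  use_direct  <- direct  | (ambiguous & ambiguity_policy == "keep" & direct)
  use_swapped <- swapped | (ambiguous & ambiguity_policy == "keep" & swapped)
  if (ambiguity_policy == "drop") {
    use_direct <- direct & !ambiguous
    use_swapped <- swapped & !ambiguous
  }
  out[use_direct | flip_direct] <- dosage[use_direct | flip_direct]
  out[use_swapped | flip_swapped] <- 2 - dosage[use_swapped | flip_swapped]
  reason[ambiguous & ambiguity_policy == "drop"] <- "strand_ambiguous"
  unmatched <- is.na(out) & !(ambiguous & ambiguity_policy == "drop") & !is.na(dosage)
  reason[unmatched & !(use_direct | use_swapped | flip_direct | flip_swapped)] <- "allele_mismatch"
  attr(out, "reasons") <- reason
  out
}

#' Read genotype dosages from a VCF
#'
#' Extracts effect-allele dosages for every included panel variant from a
#' VCF 4.x file. Variants are matched by chromosome, position and unordered
#' allele pair (rsIDs are reporting metadata only). The `DS` FORMAT field is
#' preferred when present; otherwise dosage is the ALT-allele count from `GT`.
#' Panel variants absent from the VCF become all-missing columns and are
#' counted in the attached warning log.
#'
#' @param path VCF path (plain text or bgzipped).
#' @param panel Panel tibble; only rows with `included = TRUE` are extracted.
#' @param ambiguity_policy Passed to [harmonize_alleles()].
#' @return Numeric dosage matrix (samples x included variants) with an
#'   `"unmatched"` attribute listing panel variants not found.
#' @export
read_dosages_vcf <- function(path, panel, ambiguity_policy = "drop") {
  if (!file.exists(path)) stop("VCF not found: ", path)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  samples <- colnames(vcf@gt)[-1]
  if (length(samples) == 0) stop("VCF contains no sample columns")

  inc <- panel[panel$included, , drop = FALSE]
  dosages <- matrix(NA_real_, nrow = length(samples), ncol = nrow(inc),
                    dimnames = list(samples, inc$variant_id))

  ds <- tryCatch(vcfR::extract.gt(vcf, element = "DS", as.numeric = TRUE),
                 error = function(e) NULL)
  gt <- tryCatch(vcfR::extract.gt(vcf, element = "GT"), error = function(e) NULL)
  alt_count <- function(g) {
    ifelse(is.na(g) | g %in% c(".", "./.", ".|."), NA_real_,
           stringr::str_count(g, "1"))
  }

  rec_chrom <- as.character(fix[, "CHROM"])
  rec_pos <- as.integer(fix[, "POS"])
  rec_ref <- toupper(fix[, "REF"])
  rec_alt <- toupper(fix[, "ALT"])
  unmatched <- character(0)
  for (j in seq_len(nrow(inc))) {
    pv <- inc[j, ]
    pair <- sort(c(pv$effect_allele, pv$other_allele))
    cpair <- sort(complement_allele(c(pv$effect_allele, pv$other_allele)))
    hit <- which(rec_chrom == pv$chrom & rec_pos == pv$pos &
                   (purrr::map2_lgl(rec_ref, rec_alt,
                                    ~ identical(sort(c(.x, .y)), pair) ||
                                      identical(sort(c(.x, .y)), cpair))))
    if (length(hit) == 0) {
      unmatched <- c(unmatched, pv$variant_id)
      next
    }
    hit <- hit[1]
    raw <- if (!is.null(ds) && !all(is.na(ds[hit, ]))) as.numeric(ds[hit, ]) else alt_count(gt[hit, ])
    dosages[, j] <- harmonize_alleles(rec_ref[hit], rec_alt[hit], raw,
                                      pv$effect_allele, pv$other_allele,
                                      ambiguity_policy = ambiguity_policy)
  }
  if (length(unmatched) > 0) {
    warning(length(unmatched), " panel variant(s) absent from VCF: ",
            paste(utils::head(unmatched, 5), collapse = ", "))
  }
  attr(dosages, "unmatched") <- unmatched
  dosages
}
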