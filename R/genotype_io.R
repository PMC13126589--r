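#' Locus panel constructors
#'
#' A locus panel is a data frame with one row per biallelic SNP: `rs_id`
#' (dbSNP identifier, unique), `gene` (symbol), `allele_a` and `allele_b`
#' (distinct single characters from A/C/G/T). Genotype calls are stored as
#' two-character strings in canonical (lexicographic) order, so `"TC"` and
#' `"CT"` denote the same unphased call.
#'
#' @param rs_id,gene,allele_a,allele_b character vectors of equal length.
#' @return A `data.frame` of class `episurv_panel`.
#' @examples
#' locus_panel("rs833061", "VEGF-A", "C", "T")
#' @export
locus_panel <- function(rs_id, gene, allele_a, allele_b) {
  panel <- data.frame(rs_id = as.character(rs_id),
                      gene = as.character(gene),
                      allele_a = as.character(allele_a),
                      allele_b = as.character(allele_b),
                      stringsAsFactors = FALSE)
  if (anyDuplicated(panel$rs_id))
    stop_input("duplicate rs_id in panel")
  ok <- panel$allele_a %in% c("A", "C", "G", "T") &
    panel$allele_b %in% c("A", "C", "G", "T") &
    panel$allele_a != panel$allele_b
  if (!all(ok))
    stop_input(paste0("invalid alleles for: ",
                      paste(panel$rs_id[!ok], collapse = ", ")))
  class(panel) <- c("episurv_panel", "data.frame")
  panel
}

#' Default angiogenesis SNP panel
#'
#' The four loci analysed by default: VEGF-A rs833061 (C/T), VEGFR-2
#' rs1870377 (T/A) and rs11133360 (C/T), and IL-8 rs4073 (A/T). The panel
#' is user-extensible: pass any [locus_panel()] to the readers and to
#' [search_best_model()].
#'
#' @return An `episurv_panel` data frame with four rows.
#' @export
default_panel <- function() {
  locus_panel(
    rs_id = c("rs833061", "rs1870377", "rs11133360", "rs4073"),
    gene = c("VEGF-A", "VEGFR-2", "VEGFR-2", "IL-8"),
    allele_a = c("C", "T", "C", "A"),
    allele_b = c("T", "A", "T", "T"))
}

panel_locus <- function(panel, rs) {
  i <- match(rs, panel$rs_id)
  if (any(is.na(i)))
    stop_input(paste0("locus not in panel: ",
                      paste(rs[is.na(i)], collapse = ", ")))
  panel[i, , drop = FALSE]
}

# The three canonical genotype strings of a locus, ordered by copies of
# allele_b: 0 (homozygous a), 1 (het), 2 (homozygous b).
genotype_levels <- function(locus) {
  het <- paste0(sort(c(locus$allele_a, locus$allele_b)), collapse = "")
  c(strrep(locus$allele_a, 2), het, strrep(locus$allele_b, 2))
}

#' Canonicalize a genotype call
#'
#' Normalizes an unphased two-character genotype string to canonical
#' (lexicographic) allele order and validates both alleles against the
#' locus definition. Missing tokens yield `NA`.
#'
#' @param raw two-character string (e.g. `"TC"`), or a missing token.
#' @param locus single-row locus panel (see [locus_panel()]).
#' @param missing_tokens strings treated as a missing call.
#' @return Canonical two-character string, or `NA_character_` if missing.
#' @examples
#' p <- default_panel()
#' canonicalize_genotype("TC", p[1, ])  # "CT"
#' @export
canonicalize_genotype <- function(raw, locus,
                                  missing_tokens = c("", "NA", ".")) {
  if (is.na(raw) || raw %in% missing_tokens) return(NA_character_)
  raw <- toupper(raw)
  if (nchar(raw) != 2L)
    stop_input(paste0(locus$rs_id, ": genotype '", raw,
                      "' is not a two-allele call"))
  al <- strsplit(raw, "")[[1]]
  valid <- c(locus$allele_a, locus$allele_b)
  bad <- setdiff(al, valid)
  if (length(bad))
    stop_input(paste0(locus$rs_id, ": invalid allele '", bad[1],
                      "' (expected ", locus$allele_a, "/", locus$allele_b, ")"))
  paste0(sort(al), collapse = "")
}

covariate_columns <- function() {
  c("adjuvant_cht", "adjuvant_taxanes", "adjuvant_ht", "dfi_ge_12m",
    "sites_ge_3", "visceral", "age_ge_65", "node_positive",
    "grading", "toxicity", "ecog")
}

#' Construct a cohort
#'
#' A cohort couples a locus panel with a patient table. Required columns of
#' `data`: `patient_id` (unique), `arm` (`"PTX_BEV"` or `"PTX"`),
#' `hr_status` (`"positive"`/`"negative"`), `pfs_months`, `pfs_event`,
#' `os_months`, `os_event` (events coded 1 = event, 0 = censored), one
#' genotype column per panel rs_id (canonical strings or `NA`), and any of
#' the clinical covariate columns (binary flags plus `grading` in 2/3,
#' `toxicity` in `"g1_2"`/`"g3_4"`, `ecog` in `"0_1"`/`"2"`).
#'
#' @param data patient data frame (see Details).
#' @param panel locus panel; genotype columns are validated against it.
#' @return An object of class `episurv_cohort`.
#' @export
cohort <- function(data, panel = default_panel()) {
  req <- c("patient_id", "arm", "hr_status", "pfs_months", "pfs_event",
           "os_months", "os_event")
  miss <- setdiff(req, names(data))
  if (length(miss))
    stop_input(paste0("missing required column(s): ",
                      paste(miss, collapse = ", ")))
  data$patient_id <- as.character(data$patient_id)
  if (anyDuplicated(data$patient_id))
    stop_input(paste0("duplicate patient_id: ",
                      data$patient_id[duplicated(data$patient_id)][1]))
  if (!all(data$arm %in% c("PTX_BEV", "PTX")))
    stop_input("arm must be 'PTX_BEV' or 'PTX'")
  data$pfs_event <- parse_event(data$pfs_event, "pfs_event")
  data$os_event <- parse_event(data$os_event, "os_event")
  for (col in c("pfs_months", "os_months")) {
    data[[col]] <- as.numeric(data[[col]])
    if (anyNA(data[[col]]) || any(data[[col]] < 0))
      stop_input(paste0(col, " must be non-negative and non-missing"))
  }
  if (any(data$os_months < data$pfs_months))
    stop_input("os_months < pfs_months for at least one record")
  for (rs in intersect(panel$rs_id, names(data))) {
    loc <- panel_locus(panel, rs)
    data[[rs]] <- vapply(as.character(data[[rs]]), canonicalize_genotype,
                         character(1), locus = loc, USE.NAMES = FALSE)
  }
  structure(list(panel = panel, data = data), class = "episurv_cohort")
}

parse_event <- function(x, what) {
  if (is.character(x) || is.factor(x)) {
    x <- as.character(x)
    out <- ifelse(x %in% c("event", "1"), 1L,
                  ifelse(x %in% c("censored", "0"), 0L, NA_integer_))
  } else out <- as.integer(x)
  if (anyNA(out) || !all(out %in% c(0L, 1L)))
    stop_input(paste0(what, " must be 0/1 or 'event'/'censored'"))
  out
}

#' @export
print.episurv_cohort <- function(x, ...) {
  cat(sprintf("<episurv_cohort> %d patients, %d-locus panel (%s)\n",
              nrow(x$data), nrow(x$panel),
              paste(x$panel$rs_id, collapse = ", ")))
  tab <- table(x$data$arm)
  cat("  arms:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      "\n")
  invisible(x)
}

#' Read a patient table
#'
#' Reads a delimited patient-level table (header row required; genotype
#' columns named exactly by rs_id) into a cohort, canonicalizing genotype
#' calls on ingest.
#'
#' @param path file path.
#' @param panel locus panel to validate genotypes against.
#' @param sep field delimiter (tab by default).
#' @param missing_tokens genotype strings treated as missing.
#' @return An `episurv_cohort`.
#' @export
read_patient_table <- function(path, panel = default_panel(), sep = "\t",
                               missing_tokens = c("", "NA", ".")) {
  if (!file.exists(path)) stop_input(paste0("file not found: ", path))
  df <- read.delim(path, sep = sep, header = TRUE,
                   colClasses = "character", check.names = FALSE,
                   na.strings = NULL, fileEncoding = "UTF-8")
  for (rs in intersect(panel$rs_id, names(df)))
    df[[rs]][df[[rs]] %in% missing_tokens] <- NA_character_
  for (col in intersect(c("adjuvant_cht", "adjuvant_taxanes", "adjuvant_ht",
                          "dfi_ge_12m", "sites_ge_3", "visceral",
                          "age_ge_65", "node_positive", "grading"),
                        names(df))) {
    suppressWarnings(v <- as.integer(df[[col]]))
    df[[col]] <- v  # unparseable optional covariates become NA
  }
  cohort(df, panel = panel)
}

#' Write a cohort as TSV
#'
#' Emits the same schema [read_patient_table()] consumes; numeric fields
#' are formatted to 6 significant digits so output is byte-stable.
#'
#' @param x an `episurv_cohort`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(x, path) {
  stopifnot(inherits(x, "episurv_cohort"))
  df <- x$data
  for (col in names(df))
    if (is.numeric(df[[col]]) && !is.integer(df[[col]]))
      df[[col]] <- fmt_num(df[[col]])
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA", fileEncoding = "UTF-8")
  invisible(path)
}

#' Merge genotypes from a VCF file
#'
#' Updates a cohort's genotype calls from a VCF (v4.x), matching sites on
#' the ID column (rs_id) and samples on patient_id. Only biallelic panel
#' sites are accepted; phase separators are ignored (calls are unphased).
#' Requires the VariantAnnotation package.
#'
#' @param x an `episurv_cohort`.
#' @param vcf_path path to an (uncompressed or bgzipped) VCF.
#' @param overwrite overwrite existing non-missing table-derived calls?
#' @return The updated cohort.
#' @export
merge_vcf_genotypes <- function(x, vcf_path, overwrite = FALSE) {
  stopifnot(inherits(x, "episurv_cohort"))
  if (!requireNamespace("VariantAnnotation", quietly = TRUE))
    stop_input("merge_vcf_genotypes requires the VariantAnnotation package")
  if (!file.exists(vcf_path)) stop_input(paste0("file not found: ", vcf_path))
  vcf <- VariantAnnotation::readVcf(vcf_path, genome = "unknown")
  ids <- rownames(vcf)
  keep <- which(ids %in% x$panel$rs_id)
  if (!length(keep)) {
    message("merge_vcf_genotypes: no panel sites found in VCF")
    return(x)
  }
  gt <- VariantAnnotation::geno(vcf)$GT
  ref <- as.character(VariantAnnotation::ref(vcf))
  altl <- VariantAnnotation::alt(vcf)
  samples <- colnames(gt)
  unmatched <- setdiff(samples, x$data$patient_id)
  if (length(unmatched))
    message("merge_vcf_genotypes: ", length(unmatched),
            " VCF sample(s) not in cohort: ",
            paste(utils::head(unmatched, 5), collapse = ", "))
  for (i in keep) {
    rs <- ids[i]
    alts <- as.character(altl[[i]])
    if (length(alts) != 1L)
      stop_input(paste0(rs, ": multiallelic site (ALT = ",
                        paste(alts, collapse = ","), ")"))
    loc <- panel_locus(x$panel, rs)
    alleles <- c(ref[i], alts)
    if (!setequal(alleles, c(loc$allele_a, loc$allele_b)))
      stop_input(paste0(rs, ": VCF alleles ", ref[i], "/", alts,
                        " do not match panel ", loc$allele_a, "/",
                        loc$allele_b))
    for (s in intersect(samples, x$data$patient_id)) {
      g <- gt[i, s]
      call <- vcf_gt_to_call(g, alleles)
      row <- match(s, x$data$patient_id)
      if (is.null(x$data[[rs]])) x$data[[rs]] <- NA_character_
      if (overwrite || is.na(x$data[[rs]][row]))
        x$data[[rs]][row] <- if (is.na(call)) x$data[[rs]][row] else
          canonicalize_genotype(call, loc)
    }
  }
  x
}

vcf_gt_to_call <- function(gt, alleles) {
  if (is.na(gt) || gt %in% c(".", "./.", ".|.")) return(NA_character_)
  idx <- suppressWarnings(as.integer(strsplit(gt, "[/|]")[[1]]))
  if (length(idx) != 2L || anyNA(idx)) return(NA_character_)
  paste0(alleles[idx + 1L], collapse = "")
}

# Integer genotype codes (copies of allele_b: 0/1/2, NA if missing) for
# the given loci; rows follow cohort record order.
genotype_codes <- function(x, rs_ids) {
  stopifnot(inherits(x, "episurv_cohort"))
  sapply(rs_ids, function(rs) {
    loc <- panel_locus(x$panel, rs)
    if (is.null(x$data[[rs]]))
      stop_input(paste0("no genotype column for ", rs))
    match(x$data[[rs]], genotype_levels(loc)) - 1L
  })
}
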