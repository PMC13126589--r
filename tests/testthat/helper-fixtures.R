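# Fixture builders. Everything is generated in code; nothing binary.

two_locus_panel <- function() {
  locus_panel(c("rs833061", "rs1870377"), c("VEGF-A", "VEGFR-2"),
              c("C", "T"), c("T", "A"))
}

# Minimal valid patient data frame; override columns via ...
patient_df <- function(n, ...) {
  df <- data.frame(patient_id = sprintf("P%02d", seq_len(n)),
                   arm = "PTX_BEV", hr_status = "positive",
                   pfs_months = 5, pfs_event = 1L,
                   os_months = 10, os_event = 1L,
                   stringsAsFactors = FALSE)
  over <- list(...)
  for (nm in names(over)) df[[nm]] <- over[[nm]]
  df
}

# A labeled cohort with prescribed labels and genotypes. `genos` is a data
# frame (or list) of genotype columns named by rs_id, strings or NA.
make_labeled <- function(labels, genos, panel = default_panel()) {
  n <- length(labels)
  pfs <- ifelse(labels == "responder", 25, 5)
  df <- patient_df(n, pfs_months = pfs, os_months = pfs + 5)
  for (nm in names(genos)) df[[nm]] <- genos[[nm]]
  assign_responder_labels(cohort(df, panel = panel))
}

# Random HWE genotypes for a locus (canonical strings).
hwe_genotypes <- function(n, locus, q) {
  code <- stats::rbinom(n, 2, q)
  epistasurv:::genotype_levels(locus)[code + 1L]
}

# Random labeled cohort over the default 4-locus panel: genotype-label
# association absent unless `sep_pair` is given (then that pair's cell
# parity determines the label deterministically).
random_labeled <- function(n, seed, panel = default_panel(),
                           q = c(0.5, 0.3, 0.45, 0.4)) {
  withr::with_seed(seed, {
    genos <- lapply(seq_len(nrow(panel)), function(i)
      hwe_genotypes(n, panel[i, ], q[i]))
    names(genos) <- panel$rs_id
    labels <- sample(rep_len(c("responder", "non_responder"), n))
    make_labeled(labels, genos, panel)
  })
}

write_fixture_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# Plain-text VCF with the given sample genotypes at panel sites.
# `records` is a data frame: id, ref, alt, plus one GT column per sample.
write_fixture_vcf <- function(records, samples,
                              path = tempfile(fileext = ".vcf")) {
  hdr <- c("##fileformat=VCFv4.2",
           "##contig=<ID=1,length=1000000>",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  body <- vapply(seq_len(nrow(records)), function(i) {
    paste(c("1", as.character(1000 + i), records$id[i], records$ref[i],
            records$alt[i], ".", "PASS", ".", "GT",
            unlist(records[i, samples])), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, body), path)
  path
}
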