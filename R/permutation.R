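#' Permutation test for the best MDR model
#'
#' Empirical significance of the searched model: responder/non-responder
#' labels are randomly reassigned (preserving class counts) and the
#' *entire* search — all locus tuples, fresh cross-validation folds drawn
#' from the permutation RNG stream — is re-run for each permutation, so
#' the null distribution accounts for selection over tuples. The p-value
#' uses the add-one (Davison-Hinkley) upper-tail estimator
#' p = (1 + #\{null >= observed\}) / (1 + n_perm), which is never smaller
#' than 1/(n_perm + 1).
#'
#' @param labeled a `labeled_cohort`.
#' @param loci candidate rs_ids (default: cohort panel).
#' @param k tuple size.
#' @param cv a [cv_config()]; its own seed governs the observed statistic's
#'   fold draw.
#' @param n_perm number of permutations (default 1000).
#' @param seed integer seed for the permutation stream.
#' @return A `permutation_result`: `observed_stat` (mean CV testing
#'   balanced accuracy of the winning tuple), `null_stats`, `n_perm`,
#'   `p_value`, `seed`.
#' @export
permutation_test <- function(labeled, loci = NULL, k = 2, cv = cv_config(),
                             n_perm = 1000, seed = NULL) {
  stopifnot(inherits(labeled, "labeled_cohort"))
  if (n_perm < 1) stop_input("n_perm must be >= 1")
  observed <- search_best_model(labeled, loci = loci, k = k, cv = cv)
  co <- labeled$cohort
  loci_all <- loci %||% co$panel$rs_id
  loci_all <- co$panel$rs_id[co$panel$rs_id %in% loci_all]
  lab <- labeled$labels[co$data$patient_id]
  keep <- !is.na(lab)
  y <- as.integer(lab[keep] == "responder")
  combos <- combn(loci_all, k)
  codes <- genotype_codes(co, loci_all)[keep, , drop = FALSE]
  cells <- matrix(as.integer(apply(combos, 2, function(tp)
    cell_index(codes[, tp, drop = FALSE]))), nrow = length(y))
  ncell <- 3L^as.integer(k)
  null_stats <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    y_perm <- sample(y)
    folds <- make_folds(y_perm, cv$n_folds, cv$stratified)
    ba <- mdr_cv_ba(cells, y_perm, as.integer(folds), cv$n_folds, ncell)
    stat <- suppressWarnings(max(rowMeans(ba, na.rm = TRUE)))
    if (is.nan(stat)) -Inf else stat  # degenerate permutation: no score
  }, numeric(1)))
  obs <- observed$test_ba
  if (is.nan(obs)) obs <- -Inf  # undefined statistic cannot beat the null
  p <- (1 + sum(null_stats >= obs)) / (1 + n_perm)
  structure(list(observed_stat = observed$test_ba,
                 null_stats = null_stats, n_perm = as.integer(n_perm),
                 p_value = p, seed = seed, model = observed),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf(paste0("<permutation_result> observed BA %.4f, %d ",
                     "permutations, upper-tail Monte Carlo p = %.4g\n"),
              x$observed_stat, x$n_perm, x$p_value))
  invisible(x)
}

#' Write a permutation null distribution as single-column TSV
#'
#' @param x a `permutation_result`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_null_stats <- function(x, path) {
  write.table(data.frame(null_ba = fmt_num(x$null_stats)), path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
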