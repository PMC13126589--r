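# Multifactor dimensionality reduction (MDR), from scratch.
#
# MDR pools the genotypes of a k-locus tuple into 3^k cells and collapses
# them to one binary attribute: a cell is "favorable" when its
# responder/non-responder ratio reaches the sample-wide ratio T of the
# training data. Tuples are ranked by cross-validated testing balanced
# accuracy; the inner scorer lives in src/mdr_cv.cpp because the
# permutation test re-runs the whole search thousands of times.

#' Cross-validation configuration for the MDR search
#'
#' @param n_folds number of folds (>= 2, default 10).
#' @param seed integer seed for fold assignment (NULL = current RNG).
#' @param stratified stratify folds by class (default TRUE; guarantees both
#'   classes in every training fold when class counts >= n_folds).
#' @return A `cv_config` object.
#' @export
cv_config <- function(n_folds = 10, seed = NULL, stratified = TRUE) {
  if (n_folds < 2) stop_input("n_folds must be >= 2")
  structure(list(n_folds = as.integer(n_folds), seed = seed,
                 stratified = isTRUE(stratified)), class = "cv_config")
}

# Fold assignment: within each class (if stratified), fold sizes differ by
# at most one and assignment order is randomized.
make_folds <- function(y, n_folds, stratified = TRUE) {
  f <- integer(length(y))
  groups <- if (stratified) split(seq_along(y), y) else list(seq_along(y))
  for (idx in groups)
    f[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
  f
}

# Flattened genotype-cell index (0..3^k-1; -1 when any locus is missing)
# for each record, first locus most significant.
cell_index <- function(codes) {
  codes <- as.matrix(codes)
  k <- ncol(codes)
  idx <- rep(0L, nrow(codes))
  for (j in seq_len(k)) idx <- idx * 3L + codes[, j]
  idx[is.na(idx)] <- -1L
  as.integer(idx)
}

# Canonical names of all 3^k cells of a locus tuple, in cell_index order.
cell_names <- function(panel, rs_ids) {
  lv <- lapply(rs_ids, function(rs) genotype_levels(panel_locus(panel, rs)))
  k <- length(rs_ids)
  idx <- 0:(3^k - 1)
  vapply(idx, function(i) {
    digits <- integer(k)
    for (j in k:1) { digits[j] <- i %% 3; i <- i %/% 3 }
    paste(mapply(function(l, d) l[d + 1], lv, digits), collapse = "/")
  }, character(1))
}

#' Build a k-locus genotype contingency table
#'
#' Cross-tabulates responders and non-responders over the 3^k genotype
#' cells of a locus tuple. Records missing a genotype at any of the k loci
#' are dropped and counted in `n_dropped_missing`.
#'
#' @param labeled a `labeled_cohort` (see [assign_responder_labels()]).
#' @param loci character vector of k rs_ids (must be in the cohort panel).
#' @return An `mdr_table`: data frame `cells` (cell, n_resp, n_nonresp)
#'   covering all 3^k cells, plus `loci`, `n_used`, `n_dropped_missing`.
#' @export
build_contingency <- function(labeled, loci) {
  stopifnot(inherits(labeled, "labeled_cohort"))
  co <- labeled$cohort
  lab <- labeled$labels[co$data$patient_id]
  keep <- !is.na(lab)
  codes <- genotype_codes(co, loci)[keep, , drop = FALSE]
  lab <- lab[keep]
  idx <- cell_index(codes)
  used <- idx >= 0L
  ncell <- 3L^length(loci)
  n_resp <- tabulate(idx[used & lab == "responder"] + 1L, nbins = ncell)
  n_non <- tabulate(idx[used & lab == "non_responder"] + 1L, nbins = ncell)
  structure(list(
    loci = loci,
    cells = data.frame(cell = cell_names(co$panel, loci),
                       n_resp = n_resp, n_nonresp = n_non,
                       stringsAsFactors = FALSE),
    n_used = sum(used), n_dropped_missing = sum(!used)),
    class = "mdr_table")
}

#' Classify genotype cells as favorable / unfavorable / indeterminate
#'
#' A cell is favorable when its responder/non-responder ratio is at least
#' the threshold T (ties classify favorable); a non-empty cell below T is
#' unfavorable; an empty cell is indeterminate. With `threshold_T = NULL`
#' (the default) T is the table's own responder/non-responder total ratio
#' and the comparison is done by exact integer cross-multiplication, so
#' ties are free of floating-point artifacts. A cell with responders but
#' no non-responders has infinite ratio and is favorable at any T.
#'
#' @param table an `mdr_table` from [build_contingency()].
#' @param threshold_T positive ratio, or NULL to use the table totals.
#' @return Named character vector over all 3^k cells.
#' @export
classify_cells <- function(table, threshold_T = NULL) {
  stopifnot(inherits(table, "mdr_table"))
  r <- table$cells$n_resp
  n <- table$cells$n_nonresp
  if (is.null(threshold_T)) {
    R <- sum(r); N <- sum(n)
    fav <- r * N >= R * n
  } else {
    if (!(is.numeric(threshold_T) && threshold_T > 0))
      stop_input("threshold_T must be a positive number")
    fav <- ifelse(n == 0, r > 0, r / n >= threshold_T)
  }
  out <- ifelse(r + n == 0, "indeterminate",
                ifelse(fav, "favorable", "unfavorable"))
  setNames(out, table$cells$cell)
}

#' Balanced accuracy of a cell profile against known labels
#'
#' Predicting responder for favorable cells, the statistic is
#' (sensitivity + specificity) / 2. Records whose profile is `"unknown"`
#' (missing genotype or indeterminate cell) are excluded from both terms.
#'
#' @param profile character vector of `"favorable"`/`"unfavorable"`/
#'   `"unknown"` per record.
#' @param labels matching vector of `"responder"`/`"non_responder"`.
#' @return Balanced accuracy in \[0, 1\].
#' @export
balanced_accuracy <- function(profile, labels) {
  stopifnot(length(profile) == length(labels))
  keep <- profile != "unknown" & !is.na(profile)
  profile <- profile[keep]; labels <- labels[keep]
  n_resp <- sum(labels == "responder")
  n_non <- sum(labels == "non_responder")
  if (n_resp == 0 || n_non == 0)
    stop_stat("balanced accuracy undefined: a class is absent")
  sens <- sum(profile == "favorable" & labels == "responder") / n_resp
  spec <- sum(profile == "unfavorable" & labels == "non_responder") / n_non
  (sens + spec) / 2
}

#' Exhaustive cross-validated MDR model search
#'
#' Enumerates all `choose(length(loci), k)` locus tuples. For each tuple
#' and cross-validation fold, the threshold T and the cell classification
#' are computed on the training split only (no test-set leakage) and the
#' held-out fold is scored by balanced accuracy. The winner maximizes mean
#' testing balanced accuracy; ties break by higher CV consistency (number
#' of folds in which the tuple was fold-best), then lexicographic rs_id
#' order. The returned cell profile is refit on all labeled records.
#'
#' @param labeled a `labeled_cohort`.
#' @param loci candidate rs_ids (default: the whole cohort panel).
#' @param k tuple size (default 2).
#' @param cv a [cv_config()].
#' @return An `mdr_model`: `loci` (winning tuple, in panel order — cell
#'   names follow this order), `cell_profile`
#'   (all 3^k cells), `threshold_T`, `train_ba`, `test_ba` (mean CV testing
#'   balanced accuracy), `cv_consistency`, `cv_ba` (tuple-by-fold matrix),
#'   `folds` (assignment used), `table` (full-data contingency table).
#' @export
search_best_model <- function(labeled, loci = NULL, k = 2,
                              cv = cv_config()) {
  stopifnot(inherits(labeled, "labeled_cohort"))
  co <- labeled$cohort
  loci <- loci %||% co$panel$rs_id
  k <- as.integer(k)
  if (length(loci) < 1L) stop_input("empty candidate locus list")
  if (k < 1L || k > length(loci))
    stop_input("k must be between 1 and the panel size")
  loci <- co$panel$rs_id[co$panel$rs_id %in% loci]  # panel order
  lab <- labeled$labels[co$data$patient_id]
  keep <- !is.na(lab)
  y <- as.integer(lab[keep] == "responder")
  if (length(y) == 0L) stop_input("no labeled records")
  combos <- combn(loci, k)
  codes <- genotype_codes(co, loci)[keep, , drop = FALSE]
  cells <- apply(combos, 2, function(tp)
    cell_index(codes[, tp, drop = FALSE]))
  cells <- matrix(as.integer(cells), nrow = length(y))
  folds <- with_seed(cv$seed,
                     make_folds(y, cv$n_folds, cv$stratified))
  ba <- mdr_cv_ba(cells, y, as.integer(folds), cv$n_folds, 3L^k)
  mean_ba <- rowMeans(ba, na.rm = TRUE)
  # fold-best counts for every tuple (used for the winner and tie-breaks)
  consistency <- integer(ncol(combos))
  for (f in seq_len(cv$n_folds)) {
    col <- ba[, f]
    if (all(is.na(col))) next
    best <- which(col >= max(col, na.rm = TRUE) - 1e-12)
    consistency[best] <- consistency[best] + 1L
  }
  tuple_id <- apply(combos, 2, function(tp)
    paste(sort(tp), collapse = "+"))
  ord <- order(-mean_ba, -consistency, tuple_id)
  w <- ord[1]
  winner <- combos[, w]
  tab <- build_contingency(restrict_labeled(labeled, keep), winner)
  prof <- classify_cells(tab)
  idx <- cells[, w]
  rec_prof <- ifelse(idx < 0L, "unknown", unname(prof[idx + 1L]))
  rec_prof[rec_prof == "indeterminate"] <- "unknown"
  structure(list(
    loci = winner,
    cell_profile = prof,
    threshold_T = sum(tab$cells$n_resp) / sum(tab$cells$n_nonresp),
    train_ba = balanced_accuracy(rec_prof, ifelse(y == 1, "responder",
                                                  "non_responder")),
    test_ba = mean_ba[w],
    cv_consistency = consistency[w],
    n_folds = cv$n_folds,
    cv_ba = ba, tuples = tuple_id, mean_ba = setNames(mean_ba, tuple_id),
    folds = folds, table = tab),
    class = "mdr_model")
}

restrict_labeled <- function(labeled, keep) {
  co <- labeled$cohort
  co$data <- co$data[keep, , drop = FALSE]
  rownames(co$data) <- NULL
  labeled$cohort <- co
  labeled
}

#' Apply an MDR model's genotype profile to patients
#'
#' Looks up each patient's genotype cell in the model's cell map. A
#' missing genotype at any model locus, or an indeterminate cell, yields
#' `"unknown"`.
#'
#' @param model an `mdr_model` (or any list with `loci` and
#'   `cell_profile`).
#' @param x an `episurv_cohort`.
#' @return Character vector (`"favorable"`/`"unfavorable"`/`"unknown"`),
#'   one entry per record, named by patient_id.
#' @export
apply_profile <- function(model, x) {
  stopifnot(inherits(x, "episurv_cohort"))
  idx <- cell_index(genotype_codes(x, model$loci))
  nm <- cell_names(x$panel, model$loci)
  out <- ifelse(idx < 0L, "unknown",
                unname(model$cell_profile[nm[idx + 1L]]))
  out[is.na(out) | out == "indeterminate"] <- "unknown"
  setNames(out, x$data$patient_id)
}

#' @export
print.mdr_model <- function(x, ...) {
  cat(sprintf("<mdr_model> loci: %s\n", paste(x$loci, collapse = " x ")))
  cat(sprintf("  mean CV test BA %.4f, CV consistency %d/%d, train BA %.4f\n",
              x$test_ba, x$cv_consistency, x$n_folds, x$train_ba))
  cat(sprintf("  threshold T = %.4f\n", x$threshold_T))
  for (lb in c("favorable", "unfavorable", "indeterminate")) {
    cells <- names(x$cell_profile)[x$cell_profile == lb]
    if (length(cells))
      cat(sprintf("  %-13s %s\n", paste0(lb, ":"),
                  paste(cells, collapse = ", ")))
  }
  invisible(x)
}

#' Serialize an MDR model to JSON
#'
#' @param model an `mdr_model`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_mdr_model <- function(model, path) {
  obj <- list(loci = model$loci,
              cell_profile = as.list(model$cell_profile),
              threshold_T = model$threshold_T,
              train_ba = model$train_ba, test_ba = model$test_ba,
              cv_consistency = model$cv_consistency,
              n_folds = model$n_folds)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = 10,
                       pretty = TRUE)
  invisible(path)
}
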