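#' Responder dichotomization rule
#'
#' Patients are labeled *responder* when progression-free past `t_hi`
#' months (event or censored), *non-responder* when progressing before
#' `t_lo` months, and excluded otherwise. The window `[t_lo, t_hi)` is
#' excluded by design to sharpen the contrast the interaction search sees.
#'
#' @param t_lo lower PFS bound in months (default 10).
#' @param t_hi upper PFS bound in months (default 20).
#' @return A `dichotomization_rule` object.
#' @export
dichotomization_rule <- function(t_lo = 10, t_hi = 20) {
  if (!(t_lo > 0 && t_hi > t_lo))
    stop_input("need 0 < t_lo < t_hi")
  structure(list(t_lo = t_lo, t_hi = t_hi), class = "dichotomization_rule")
}

#' Restrict a cohort to hormone-receptor-positive patients
#'
#' @param x an `episurv_cohort`.
#' @param quiet suppress the attrition message?
#' @return The filtered cohort (possibly empty).
#' @export
filter_hr_positive <- function(x, quiet = FALSE) {
  stopifnot(inherits(x, "episurv_cohort"))
  keep <- x$data$hr_status == "positive"
  if (!quiet)
    message(sprintf("filter_hr_positive: %d -> %d records",
                    nrow(x$data), sum(keep)))
  x$data <- x$data[keep, , drop = FALSE]
  rownames(x$data) <- NULL
  x
}

#' Assign responder / non-responder labels by the PFS window
#'
#' Labels each patient by the rule: responder iff `pfs_months >= t_hi`
#' (event or censored — being progression-free past the bound satisfies
#' the definition either way); non-responder iff `pfs_months < t_lo` with
#' an observed progression event. Patients inside the window are excluded
#' with reason `"window"`; patients censored before `t_lo` are excluded
#' with reason `"early_censor"` since their true PFS could exceed `t_hi`
#' (set `early_censor_as_nonresponder = TRUE` to label them instead).
#'
#' @param x an `episurv_cohort`.
#' @param rule a [dichotomization_rule()].
#' @param early_censor_as_nonresponder see Description.
#' @return A `labeled_cohort`: list with the input `cohort`, `labels`
#'   (named character vector, `"responder"`/`"non_responder"`) and
#'   `excluded` (data frame of `patient_id`, `reason`). Labels plus
#'   exclusions partition the input records.
#' @export
assign_responder_labels <- function(x, rule = dichotomization_rule(),
                                    early_censor_as_nonresponder = FALSE) {
  stopifnot(inherits(x, "episurv_cohort"),
            inherits(rule, "dichotomization_rule"))
  pfs <- x$data$pfs_months
  ev <- x$data$pfs_event == 1L
  lab <- rep(NA_character_, nrow(x$data))
  reason <- rep(NA_character_, nrow(x$data))
  lab[pfs >= rule$t_hi] <- "responder"
  nr <- pfs < rule$t_lo & (ev | early_censor_as_nonresponder)
  lab[nr] <- "non_responder"
  reason[is.na(lab) & pfs < rule$t_lo] <- "early_censor"
  reason[is.na(lab) & pfs >= rule$t_lo] <- "window"
  excluded <- data.frame(patient_id = x$data$patient_id[is.na(lab)],
                         reason = reason[is.na(lab)],
                         stringsAsFactors = FALSE)
  labels <- setNames(lab[!is.na(lab)], x$data$patient_id[!is.na(lab)])
  structure(list(cohort = x, labels = labels, excluded = excluded,
                 rule = rule),
            class = "labeled_cohort")
}

#' @export
print.labeled_cohort <- function(x, ...) {
  cat(sprintf(paste0("<labeled_cohort> %d responders, %d non-responders, ",
                     "%d excluded (window [%g, %g))\n"),
              sum(x$labels == "responder"),
              sum(x$labels == "non_responder"),
              nrow(x$excluded), x$rule$t_lo, x$rule$t_hi))
  invisible(x)
}

#' Split a cohort by treatment arm
#'
#' @param x an `episurv_cohort`.
#' @return A list with components `ptx_bev` and `ptx`, each a cohort.
#' @export
split_by_arm <- function(x) {
  stopifnot(inherits(x, "episurv_cohort"))
  if (!all(x$data$arm %in% c("PTX_BEV", "PTX")))
    stop_input("unknown arm value")
  pick <- function(a) {
    y <- x
    y$data <- x$data[x$data$arm == a, , drop = FALSE]
    rownames(y$data) <- NULL
    y
  }
  list(ptx_bev = pick("PTX_BEV"), ptx = pick("PTX"))
}

# Subset a labeled cohort to the labeled records of one arm, preserving
# record order. Internal: feeds the MDR search.
labeled_subset_arm <- function(labeled, arm) {
  co <- labeled$cohort
  keep <- co$data$arm == arm & co$data$patient_id %in% names(labeled$labels)
  co$data <- co$data[keep, , drop = FALSE]
  rownames(co$data) <- NULL
  structure(list(cohort = co,
                 labels = labeled$labels[co$data$patient_id],
                 excluded = labeled$excluded, rule = labeled$rule),
            class = "labeled_cohort")
}
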