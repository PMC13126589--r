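# Synthetic cohort generator. Plants exactly the structure the analysis
# assumes: Hardy-Weinberg genotypes at independent loci, a two-locus
# cell -> profile map, exponential PFS whose hazard depends on (arm,
# profile) — with the profile effect confined to the combination arm —
# OS = PFS plus an independent exponential tail, and administrative
# censoring at a fixed horizon.

#' Published favorable/unfavorable two-locus profile map
#'
#' The 9-cell map over VEGF-A rs833061 x VEGFR-2 rs1870377 used by the
#' paper-shaped preset: favorable cells CT/AT, CT/AA, TT/AA, TT/TT, CC/TT;
#' unfavorable cells CC/AA, CC/AT, CT/TT, TT/AT.
#'
#' @return Named character vector over all 9 cells
#'   (`"<rs833061>/<rs1870377>"`).
#' @export
published_profile_map <- function() {
  c("CC/AA" = "unfavorable", "CC/AT" = "unfavorable",
    "CC/TT" = "favorable",
    "CT/AA" = "favorable", "CT/AT" = "favorable",
    "CT/TT" = "unfavorable",
    "TT/AA" = "favorable", "TT/AT" = "unfavorable",
    "TT/TT" = "favorable")
}

#' Specify a synthetic cohort
#'
#' @param n_bev,n_ctrl arm sizes (combination arm, chemo-only arm).
#' @param panel locus panel (see [locus_panel()]).
#' @param maf named per-locus frequency of `allele_b` in \[0, 0.5\]
#'   (0 makes every call homozygous for `allele_a`).
#' @param planted_pair two panel rs_ids carrying the planted interaction.
#' @param planted_map cell -> `"favorable"`/`"unfavorable"` map over all 9
#'   cells of the planted pair.
#' @param median_pfs_fav_bev,median_pfs_unfav_bev exponential PFS medians
#'   (months) by profile in the combination arm.
#' @param median_pfs_ctrl PFS median in the chemo-only arm — used for both
#'   profiles, so the profile is predictive (combination arm only), not
#'   prognostic.
#' @param os_extra_median median (months) of the independent exponential
#'   tail added to PFS to give OS; scalar or named vector with entries
#'   `fav_bev`, `unfav_bev`, `ctrl`.
#' @param censor_admin administrative censoring horizon in months
#'   (`Inf` disables censoring).
#' @param responder_rule a [dichotomization_rule()].
#' @param covariate_prevalence named prevalences of the binary clinical
#'   covariates plus `grading_3`, `toxicity_g3_4`, `ecog_2`.
#' @param seed default seed used by [generate_cohort()].
#' @return A `synthetic_spec` object.
#' @export
synthetic_spec <- function(n_bev = 106, n_ctrl = 62,
                           panel = default_panel(),
                           maf = c(rs833061 = 0.5, rs1870377 = 0.3,
                                   rs11133360 = 0.45, rs4073 = 0.4),
                           planted_pair = c("rs833061", "rs1870377"),
                           planted_map = published_profile_map(),
                           median_pfs_fav_bev = 22.9,
                           median_pfs_unfav_bev = 8.7,
                           median_pfs_ctrl = 8.7,
                           os_extra_median = 20,
                           censor_admin = 60,
                           responder_rule = dichotomization_rule(),
                           covariate_prevalence = default_prevalence(),
                           seed = NULL) {
  stopifnot(n_bev >= 0, n_ctrl >= 0)
  if (!all(panel$rs_id %in% names(maf)))
    stop_input("maf must name every panel locus")
  maf <- maf[panel$rs_id]
  if (any(maf < 0 | maf > 0.5))
    stop_input("per-locus maf must lie in [0, 0.5]")
  if (!all(planted_pair %in% panel$rs_id) || length(planted_pair) != 2L)
    stop_input("planted_pair must be two panel rs_ids")
  cells <- cell_names(panel, planted_pair)
  if (!setequal(names(planted_map), cells))
    stop_input("planted_map must cover all 9 cells of the planted pair")
  if (!all(planted_map %in% c("favorable", "unfavorable")))
    stop_input("planted_map values must be favorable/unfavorable")
  meds <- c(median_pfs_fav_bev, median_pfs_unfav_bev, median_pfs_ctrl)
  if (any(meds <= 0)) stop_input("PFS medians must be positive")
  if (length(os_extra_median) == 1L && is.null(names(os_extra_median)))
    os_extra_median <- c(fav_bev = unname(os_extra_median),
                         unfav_bev = unname(os_extra_median),
                         ctrl = unname(os_extra_median))
  if (!all(c("fav_bev", "unfav_bev", "ctrl") %in% names(os_extra_median)) ||
      any(os_extra_median <= 0))
    stop_input("os_extra_median needs positive fav_bev/unfav_bev/ctrl")
  structure(list(n_bev = as.integer(n_bev), n_ctrl = as.integer(n_ctrl),
                 panel = panel, maf = maf, planted_pair = planted_pair,
                 planted_map = planted_map[cells],
                 median_pfs_fav_bev = median_pfs_fav_bev,
                 median_pfs_unfav_bev = median_pfs_unfav_bev,
                 median_pfs_ctrl = median_pfs_ctrl,
                 os_extra_median = os_extra_median,
                 censor_admin = censor_admin,
                 responder_rule = responder_rule,
                 covariate_prevalence = covariate_prevalence,
                 seed = seed),
            class = "synthetic_spec")
}

default_prevalence <- function() {
  # pooled baseline-table prevalences of the emulated trial population
  c(adjuvant_cht = 0.56, adjuvant_taxanes = 0.23, adjuvant_ht = 0.70,
    dfi_ge_12m = 0.69, sites_ge_3 = 0.30, visceral = 0.66,
    age_ge_65 = 0.30, node_positive = 0.62,
    grading_3 = 0.14, toxicity_g3_4 = 0.17, ecog_2 = 0.06)
}

# Survival function of Exp(rate la) + Exp(rate mu), la != mu.
hypoexp_surv <- function(t, la, mu) {
  if (abs(la - mu) < 1e-12)
    return((1 + la * t) * exp(-la * t))
  (mu * exp(-la * t) - la * exp(-mu * t)) / (mu - la)
}

# Median of the exponential tail needed so that PFS (exponential with
# median pfs_median) plus the tail has the requested OS median.
solve_os_tail <- function(pfs_median, os_median) {
  stopifnot(os_median > pfs_median)
  la <- log(2) / pfs_median
  f <- function(mu) hypoexp_surv(os_median, la, mu) - 0.5
  mu <- stats::uniroot(f, interval = c(1e-8, 1e3), tol = 1e-12)$root
  log(2) / mu
}

#' Paper-shaped synthetic preset
#'
#' Arm sizes 106/62; the published 9-cell profile map planted on
#' rs833061 x rs1870377; exponential PFS medians 22.9 (favorable) and 8.7
#' (unfavorable) months in the combination arm and 8.7 months for
#' everybody in the chemo-only arm; OS tails calibrated so the
#' censoring-free OS medians are 50.2 (favorable, combination) and 23.5
#' months (unfavorable and control); administrative censoring at 60
#' months.
#'
#' @param ... overrides passed on to [synthetic_spec()].
#' @return A `synthetic_spec`.
#' @export
paper_like_preset <- function(...) {
  tail_fav <- solve_os_tail(22.9, 50.2)
  tail_unfav <- solve_os_tail(8.7, 23.5)
  synthetic_spec(os_extra_median = c(fav_bev = tail_fav,
                                     unfav_bev = tail_unfav,
                                     ctrl = tail_unfav), ...)
}

#' Null synthetic preset (no genotype effect)
#'
#' Same shape as [paper_like_preset()] but every (arm, profile) group
#' shares one PFS median and one OS tail, so the planted hazard ratio is 1
#' and any detected association is a false positive. Used to calibrate the
#' permutation test and the log-rank false-positive rate.
#'
#' @param median_pfs common PFS median in months (default 12).
#' @param ... overrides passed on to [synthetic_spec()].
#' @return A `synthetic_spec`.
#' @export
null_preset <- function(median_pfs = 12, ...) {
  synthetic_spec(median_pfs_fav_bev = median_pfs,
                 median_pfs_unfav_bev = median_pfs,
                 median_pfs_ctrl = median_pfs,
                 os_extra_median = solve_os_tail(median_pfs,
                                                 2.5 * median_pfs), ...)
}

#' Generate a synthetic cohort
#'
#' Draws genotypes per locus under Hardy-Weinberg equilibrium
#' (independent loci), assigns each patient the profile of their planted
#' two-locus cell, then draws PFS exponentially with rate log(2)/median
#' for the patient's (arm, profile) group, OS = PFS + an independent
#' exponential tail, and censors both endpoints administratively at the
#' horizon. Clinical covariates are drawn independently of genotype and
#' outcome. All patients are hormone-receptor positive.
#'
#' @param spec a [synthetic_spec()].
#' @param seed overrides `spec$seed`.
#' @return List with `cohort` (an `episurv_cohort`) and `truth` (a
#'   `planted_truth`: per-patient true profile, realized cell counts, and
#'   the spec).
#' @export
generate_cohort <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  seed <- seed %||% spec$seed
  with_seed(seed, {
    n <- spec$n_bev + spec$n_ctrl
    arm <- rep(c("PTX_BEV", "PTX"), c(spec$n_bev, spec$n_ctrl))
    ids <- sprintf("S%04d", seq_len(n))
    geno <- list()
    for (i in seq_len(nrow(spec$panel))) {
      loc <- spec$panel[i, ]
      q <- spec$maf[[loc$rs_id]]
      code <- rbinom(n, 1, q) + rbinom(n, 1, q)  # two HWE allele draws
      geno[[loc$rs_id]] <- genotype_levels(loc)[code + 1L]
    }
    pair_codes <- cbind(
      match(geno[[spec$planted_pair[1]]],
            genotype_levels(panel_locus(spec$panel,
                                        spec$planted_pair[1]))) - 1L,
      match(geno[[spec$planted_pair[2]]],
            genotype_levels(panel_locus(spec$panel,
                                        spec$planted_pair[2]))) - 1L)
    cell <- cell_names(spec$panel, spec$planted_pair)[
      cell_index(pair_codes) + 1L]
    profile <- unname(spec$planted_map[cell])
    pfs_median <- ifelse(arm == "PTX", spec$median_pfs_ctrl,
                         ifelse(profile == "favorable",
                                spec$median_pfs_fav_bev,
                                spec$median_pfs_unfav_bev))
    tail_median <- ifelse(arm == "PTX", spec$os_extra_median[["ctrl"]],
                          ifelse(profile == "favorable",
                                 spec$os_extra_median[["fav_bev"]],
                                 spec$os_extra_median[["unfav_bev"]]))
    pfs_true <- rexp(n, log(2) / pfs_median)
    os_true <- pfs_true + rexp(n, log(2) / tail_median)
    horizon <- spec$censor_admin
    pfs <- pmin(pfs_true, horizon)
    os <- pmin(os_true, horizon)
    pv <- spec$covariate_prevalence
    df <- data.frame(
      patient_id = ids, arm = arm, hr_status = "positive",
      pfs_months = pfs, pfs_event = as.integer(pfs_true <= horizon),
      os_months = os, os_event = as.integer(os_true <= horizon),
      stringsAsFactors = FALSE)
    for (cv in c("adjuvant_cht", "adjuvant_taxanes", "adjuvant_ht",
                 "dfi_ge_12m", "sites_ge_3", "visceral", "age_ge_65",
                 "node_positive"))
      df[[cv]] <- rbinom(n, 1, pv[[cv]])
    df$grading <- 2L + rbinom(n, 1, pv[["grading_3"]])
    df$toxicity <- ifelse(rbinom(n, 1, pv[["toxicity_g3_4"]]) == 1,
                          "g3_4", "g1_2")
    df$ecog <- ifelse(rbinom(n, 1, pv[["ecog_2"]]) == 1, "2", "0_1")
    for (rs in spec$panel$rs_id) df[[rs]] <- geno[[rs]]
    co <- cohort(df, panel = spec$panel)
    truth <- structure(list(profile = setNames(profile, ids),
                            cell = setNames(cell, ids),
                            cell_counts = table(cell),
                            pfs_true = setNames(pfs_true, ids),
                            os_true = setNames(os_true, ids),
                            spec = spec),
                       class = "planted_truth")
    list(cohort = co, truth = truth)
  })
}

#' Write the planted truth as a JSON sidecar
#'
#' @param truth a `planted_truth` from [generate_cohort()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_planted_truth <- function(truth, path) {
  obj <- list(profile = as.list(truth$profile),
              cell_counts = as.list(unclass(truth$cell_counts)),
              planted_pair = truth$spec$planted_pair,
              planted_map = as.list(truth$spec$planted_map))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
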