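#' Pipeline configuration
#'
#' @param input path to a patient TSV (mutually exclusive with `preset`).
#' @param preset `"paper_like"` or `"null"` to generate a synthetic cohort.
#' @param rule a [dichotomization_rule()].
#' @param panel locus panel used for reading / generation.
#' @param loci candidate rs_ids for the search (default: whole panel).
#' @param k MDR tuple size.
#' @param n_folds cross-validation folds.
#' @param n_perm permutations for the significance test (0 skips it).
#' @param seed master seed; deterministically fans out to the generator,
#'   fold assignment and permutation stream.
#' @param stay_alpha backward-selection stay threshold.
#' @param ties Cox tie handling.
#' @param cox_covariates clinical covariate columns entered (with the
#'   profile indicator) into the Cox models.
#' @param outdir report output directory (NULL: nothing written).
#' @return A `pipeline_config`.
#' @export
pipeline_config <- function(input = NULL, preset = NULL,
                            rule = dichotomization_rule(),
                            panel = default_panel(), loci = NULL, k = 2,
                            n_folds = 10, n_perm = 1000, seed = 1,
                            stay_alpha = 0.05,
                            ties = c("efron", "breslow"),
                            cox_covariates = c("adjuvant_cht",
                                               "adjuvant_taxanes",
                                               "sites_ge_3", "age_ge_65",
                                               "grading_3"),
                            outdir = NULL) {
  if (is.null(input) == is.null(preset))
    stop_input("exactly one of input/preset must be given")
  if (!is.null(preset) && !preset %in% c("paper_like", "null"))
    stop_input("preset must be 'paper_like' or 'null'")
  structure(list(input = input, preset = preset, rule = rule,
                 panel = panel, loci = loci, k = as.integer(k),
                 n_folds = as.integer(n_folds),
                 n_perm = as.integer(n_perm), seed = as.integer(seed),
                 stay_alpha = stay_alpha, ties = match.arg(ties),
                 cox_covariates = cox_covariates, outdir = outdir),
            class = "pipeline_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    cls <- class(e)
    stop(errorCondition(
      paste0("[", name, "] ", conditionMessage(e)),
      class = c(setdiff(cls, c("simpleError", "error", "condition")),
                "episurv_stage_error", "error")))
  })
}

#' Run the full pharmacogenetic interaction pipeline
#'
#' Stages, in order: load or generate the cohort; restrict to
#' hormone-receptor-positive patients; dichotomize responders by the PFS
#' window; split arms; search the MDR model on the combination-arm labeled
#' patients (the chemo-only arm is annotation-and-test only, so it never
#' influences model selection); permutation significance; annotate every
#' patient in both arms with the learned profile; per arm and endpoint
#' (PFS, OS): Kaplan-Meier by profile, log-rank, full and
#' backward-selected Cox models over the clinical covariates plus the
#' profile indicator; post-hoc power from the fitted profile hazard
#' ratios; baseline tables by arm and, in the combination arm, by profile.
#'
#' @param config a [pipeline_config()].
#' @return An `analysis_report` list; see [render_report()] to write it.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  seeds <- derive_seeds(config$seed)
  cohort0 <- stage("load", {
    if (!is.null(config$input))
      read_patient_table(config$input, panel = config$panel)
    else {
      sp <- if (config$preset == "paper_like")
        paper_like_preset(panel = config$panel,
                          responder_rule = config$rule)
      else null_preset(panel = config$panel, responder_rule = config$rule)
      generate_cohort(sp, seed = seeds["generate"])[["cohort"]]
    }
  })
  hrpos <- stage("filter_hr", filter_hr_positive(cohort0, quiet = TRUE))
  labeled <- stage("dichotomize",
                   assign_responder_labels(hrpos, config$rule))
  arms <- stage("split_arms", split_by_arm(hrpos))
  attrition <- data.frame(
    stage = c("input", "hr_positive", "labeled", "excluded_window",
              "excluded_early_censor", "arm_ptx_bev", "arm_ptx"),
    n = c(nrow(cohort0$data), nrow(hrpos$data), length(labeled$labels),
          sum(labeled$excluded$reason == "window"),
          sum(labeled$excluded$reason == "early_censor"),
          nrow(arms$ptx_bev$data), nrow(arms$ptx$data)))
  bev_labeled <- labeled_subset_arm(labeled, "PTX_BEV")
  cv <- cv_config(n_folds = config$n_folds, seed = seeds["folds"])
  model <- stage("mdr_search",
                 search_best_model(bev_labeled, loci = config$loci,
                                   k = config$k, cv = cv))
  perm <- if (config$n_perm > 0)
    stage("permutation",
          permutation_test(bev_labeled, loci = config$loci, k = config$k,
                           cv = cv, n_perm = config$n_perm,
                           seed = seeds["perm"]))
  else NULL
  survival_val <- list()
  power <- list()
  for (arm in c("ptx_bev", "ptx")) {
    co <- arms[[arm]]
    profile <- stage("profile", apply_profile(model, co))
    dat <- cox_frame(co, profile)
    res <- list(profile_counts = table(profile))
    for (ep in c("pfs", "os")) {
      tcol <- paste0(ep, "_months"); ecol <- paste0(ep, "_event")
      known <- dat[dat$profile_favorable %in% c(0, 1), , drop = FALSE]
      res[[ep]] <- stage(paste(arm, ep, sep = "_"), {
        km <- lapply(c(favorable = 1, unfavorable = 0), function(g) {
          sub <- known[known$profile_favorable == g, ]
          if (nrow(sub) == 0) NULL else km_fit(sub[[tcol]], sub[[ecol]])
        })
        lr <- if (length(unique(known$profile_favorable)) == 2)
          logrank_test(known[[tcol]], known[[ecol]],
                       known$profile_favorable)
        else NULL
        covs <- c(intersect(config$cox_covariates, names(known)),
                  "profile_favorable")
        full <- cox_fit(known, tcol, ecol, covs, ties = config$ties)
        selected <- backward_select(known, tcol, ecol, covs,
                                    stay_alpha = config$stay_alpha,
                                    ties = config$ties)
        list(km = km, logrank = lr, cox_full = full,
             cox_selected = selected)
      })
      hr_prof <- with(res[[ep]]$cox_full$terms,
                      hazard_ratio[name == "profile_favorable"])
      d <- sum(known[[ecol]])
      pgrp <- mean(known$profile_favorable)
      power[[paste(arm, ep, sep = "_")]] <-
        if (length(hr_prof) == 1 && d >= 1 && pgrp > 0 && pgrp < 1)
          schoenfeld_power(hr_prof, d, pgrp)
        else NA_real_
    }
    survival_val[[arm]] <- res
  }
  baseline_covs <- intersect(c("adjuvant_cht", "adjuvant_taxanes",
                               "adjuvant_ht", "dfi_ge_12m", "sites_ge_3",
                               "visceral", "age_ge_65", "toxicity",
                               "grading", "ecog", "node_positive"),
                             names(hrpos$data))
  baselines <- stage("baseline", {
    bev_prof <- apply_profile(model, arms$ptx_bev)
    bev <- arms$ptx_bev
    bev$data$profile <- unname(bev_prof)
    known <- bev
    known$data <- known$data[known$data$profile != "unknown", ,
                             drop = FALSE]
    list(by_arm = baseline_table(hrpos, "arm", baseline_covs),
         bev_by_profile = if (length(unique(known$data$profile)) == 2)
           baseline_table(known, "profile", baseline_covs) else NULL)
  })
  report <- structure(list(config = config, attrition = attrition,
                           model = model, permutation = perm,
                           survival = survival_val, power = power,
                           baselines = baselines),
                      class = "analysis_report")
  if (!is.null(config$outdir)) render_report(report, config$outdir)
  report
}

# Deterministic sub-seeds below 2^31 derived from the master seed.
derive_seeds <- function(seed) {
  with_seed(seed,
            setNames(sample.int(.Machine$integer.max, 3),
                     c("generate", "folds", "perm")))
}

# Numeric modelling frame for the Cox stages: binary clinical flags,
# grading recoded as an indicator for grade 3, profile as favorable = 1 /
# unfavorable = 0 / unknown = NA.
cox_frame <- function(co, profile) {
  df <- co$data
  out <- df[, intersect(c("patient_id", "pfs_months", "pfs_event",
                          "os_months", "os_event", "adjuvant_cht",
                          "adjuvant_taxanes", "adjuvant_ht", "dfi_ge_12m",
                          "sites_ge_3", "visceral", "age_ge_65",
                          "node_positive"), names(df)), drop = FALSE]
  if (!is.null(df$grading)) out$grading_3 <- as.integer(df$grading == 3L)
  out$profile_favorable <- ifelse(profile == "favorable", 1L,
                                  ifelse(profile == "unfavorable", 0L,
                                         NA_integer_))
  out
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("<analysis_report>\n")
  cat("  attrition:", paste(sprintf("%s=%d", x$attrition$stage,
                                    x$attrition$n), collapse = ", "), "\n")
  cat("  model:", paste(x$model$loci, collapse = " x "),
      sprintf("(test BA %.3f)\n", x$model$test_ba))
  if (!is.null(x$permutation))
    cat(sprintf("  permutation p = %.4g (%d perms)\n",
                x$permutation$p_value, x$permutation$n_perm))
  for (arm in names(x$survival)) {
    for (ep in c("pfs", "os")) {
      lr <- x$survival[[arm]][[ep]]$logrank
      km <- x$survival[[arm]][[ep]]$km
      if (!is.null(lr))
        cat(sprintf("  %s %s: median fav %.1f vs unfav %.1f, log-rank p = %.4g\n",
                    arm, toupper(ep),
                    km$favorable$median %||% NA,
                    km$unfavorable$median %||% NA, lr$p))
    }
  }
  invisible(x)
}

#' Write an analysis report to disk
#'
#' Writes `report.json` plus TSV tables: the 9-cell profile map, full and
#' backward-selected Cox tables per arm and endpoint (columns
#' Characteristics, Subset, HR, 95% CI, p), Kaplan-Meier curves per arm /
#' endpoint / profile, baseline tables, the attrition log, and (when a
#' permutation test ran) the null distribution. File contents are
#' deterministic for a fixed seed.
#'
#' @param report an `analysis_report`.
#' @param outdir output directory (created if absent).
#' @return `outdir`, invisibly.
#' @export
render_report <- function(report, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir)) stop_input(paste0("cannot create ", outdir))
  model <- report$model
  write.table(
    data.frame(cell = names(model$cell_profile),
               profile = unname(model$cell_profile)),
    file.path(outdir, "profile_map.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  for (arm in names(report$survival)) {
    for (ep in c("pfs", "os")) {
      blk <- report$survival[[arm]][[ep]]
      if (is.null(blk)) next
      for (which_fit in c("cox_full", "cox_selected")) {
        tf <- blk[[which_fit]]$terms
        cox_tab <- data.frame(
          Characteristics = tf$name,
          Subset = rep("Yes", nrow(tf)),
          HR = fmt_num(tf$hazard_ratio),
          `95% CI` = if (nrow(tf)) paste0(fmt_num(tf$ci_low), "-",
                                          fmt_num(tf$ci_high))
                     else character(0),
          p = fmt_num(tf$p), check.names = FALSE)
        write.table(cox_tab,
                    file.path(outdir, sprintf("%s_%s_%s.tsv", which_fit,
                                              arm, ep)),
                    sep = "\t", quote = FALSE, row.names = FALSE)
      }
      for (prof in c("favorable", "unfavorable")) {
        km <- blk$km[[prof]]
        if (is.null(km)) next
        cv <- km$curve
        cv$surv <- fmt_num(cv$surv)
        cv$lower <- fmt_num(cv$lower); cv$upper <- fmt_num(cv$upper)
        cv$time <- fmt_num(cv$time)
        write.table(cv, file.path(outdir, sprintf("km_%s_%s_%s.tsv", arm,
                                                  ep, prof)),
                    sep = "\t", quote = FALSE, row.names = FALSE)
      }
    }
  }
  write.table(report$attrition, file.path(outdir, "attrition.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(report$baselines$by_arm,
              file.path(outdir, "baseline_by_arm.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(report$baselines$bev_by_profile))
    write.table(report$baselines$bev_by_profile,
                file.path(outdir, "baseline_bev_by_profile.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(report$permutation))
    write_null_stats(report$permutation,
                     file.path(outdir, "null_stats.tsv"))
  jsonlite::write_json(report_json(report),
                       file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE,
                       na = "null")
  invisible(outdir)
}

report_json <- function(report) {
  surv <- lapply(report$survival, function(armres) {
    out <- list(profile_counts = as.list(unclass(
      armres$profile_counts)))
    for (ep in c("pfs", "os")) {
      blk <- armres[[ep]]
      if (is.null(blk)) next
      out[[ep]] <- list(
        median = lapply(blk$km, function(km) if (is.null(km)) NULL else
          list(median = km$median, ci = km$median_ci)),
        logrank = if (!is.null(blk$logrank))
          list(chi2 = blk$logrank$chi2, df = blk$logrank$df,
               p = blk$logrank$p),
        cox_full = blk$cox_full$terms,
        cox_selected = list(terms = blk$cox_selected$terms,
                            dropped = blk$cox_selected$selection_trace))
    }
    out
  })
  list(
    seed = report$config$seed,
    attrition = report$attrition,
    model = list(loci = report$model$loci,
                 cell_profile = as.list(report$model$cell_profile),
                 threshold_T = report$model$threshold_T,
                 train_ba = report$model$train_ba,
                 test_ba = report$model$test_ba,
                 cv_consistency = report$model$cv_consistency,
                 n_folds = report$model$n_folds),
    permutation = if (!is.null(report$permutation))
      list(observed_stat = report$permutation$observed_stat,
           n_perm = report$permutation$n_perm,
           p_value = report$permutation$p_value),
    survival = surv,
    power = report$power)
}

#' Command-line entry point
#'
#' Backs the installed `epistasurv` CLI script (`inst/cli/epistasurv.R`).
#' Exit codes: 0 success, 2 input error, 3 statistical/convergence error.
#'
#' @param args character vector of command-line arguments.
#' @return Integer exit code, invisibly.
#' @export
epistasurv_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!requireNamespace("optparse", quietly = TRUE)) {
    message("the CLI requires the optparse package")
    return(invisible(2L))
  }
  parser <- optparse::OptionParser(
    prog = "epistasurv",
    description = "SNP-interaction discovery and survival validation")
  parser <- optparse::add_option(parser, "--input", type = "character",
                                 default = NULL, help = "patient TSV")
  parser <- optparse::add_option(parser, "--preset", type = "character",
                                 default = NULL,
                                 help = "paper_like or null")
  parser <- optparse::add_option(parser, "--pfs-low", type = "double",
                                 default = 10, dest = "pfs_low")
  parser <- optparse::add_option(parser, "--pfs-high", type = "double",
                                 default = 20, dest = "pfs_high")
  parser <- optparse::add_option(parser, "--k", type = "integer",
                                 default = 2)
  parser <- optparse::add_option(parser, "--folds", type = "integer",
                                 default = 10)
  parser <- optparse::add_option(parser, "--n-perm", type = "integer",
                                 default = 1000, dest = "n_perm")
  parser <- optparse::add_option(parser, "--seed", type = "integer",
                                 default = 1)
  parser <- optparse::add_option(parser, "--out", type = "character",
                                 default = "epistasurv_out")
  opt <- optparse::parse_args(parser, args = args)
  code <- tryCatch({
    cfg <- pipeline_config(
      input = opt$input, preset = opt$preset,
      rule = dichotomization_rule(opt$pfs_low, opt$pfs_high),
      k = opt$k, n_folds = opt$folds, n_perm = opt$n_perm,
      seed = opt$seed, outdir = opt$out)
    report <- run_pipeline(cfg)
    print(report)
    0L
  },
  episurv_input_error = function(e) { message("input error: ",
                                              conditionMessage(e)); 2L },
  episurv_stat_error = function(e) { message("statistical error: ",
                                             conditionMessage(e)); 3L },
  error = function(e) { message("error: ", conditionMessage(e)); 1L })
  invisible(code)
}
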