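# Survival validation of genotype profiles. The Kaplan-Meier estimator is
# implemented directly (the median convention and the Brookmeyer-Crowley
# median CI on the log(-log) scale are part of this package's contract);
# log-rank and Cox fitting are delegated to the survival package behind
# the same interfaces and cross-checked against independent oracles in the
# test suite.

#' Kaplan-Meier product-limit fit
#'
#' Computes S(t) at every distinct observed time with Greenwood variance
#' and pointwise log(-log) confidence limits. The median is the smallest
#' observed time with S(t) <= 0.5 (undefined when S never reaches 0.5);
#' its confidence interval inverts the transformed pointwise test
#' (Brookmeyer-Crowley): each bound is the earliest time at which the
#' corresponding confidence limit of S drops to 0.5 or below.
#'
#' @param times non-negative event/censoring times (months).
#' @param events event indicators (1/TRUE = event, 0/FALSE = censored).
#' @param conf_level confidence level (default 0.95).
#' @return A `km_curve`: data frame `curve` (time, n_risk, n_event,
#'   n_censor, surv, lower, upper) plus `median`, `median_ci`, `n`.
#' @export
km_fit <- function(times, events, conf_level = 0.95) {
  if (length(times) == 0L) stop_input("empty input")
  if (length(times) != length(events))
    stop_input("times and events must have equal length")
  if (any(times < 0)) stop_input("negative survival time")
  events <- as.integer(as.logical(events))
  ut <- sort(unique(times))
  d <- vapply(ut, function(t) sum(times == t & events == 1L), numeric(1))
  cns <- vapply(ut, function(t) sum(times == t & events == 0L), numeric(1))
  n_risk <- vapply(ut, function(t) sum(times >= t), numeric(1))
  surv <- cumprod(1 - d / n_risk)
  # Greenwood cumulative variance of log S
  gw <- cumsum(ifelse(n_risk > d, d / (n_risk * (n_risk - d)), Inf))
  z <- qnorm(1 - (1 - conf_level) / 2)
  lower <- upper <- rep(NA_real_, length(ut))
  pos <- surv > 0 & surv < 1 & is.finite(gw)
  sig <- sqrt(gw[pos]) / abs(log(surv[pos]))      # se of log(-log S)
  lower[pos] <- surv[pos]^exp(z * sig)
  upper[pos] <- surv[pos]^exp(-z * sig)
  med_i <- which(surv <= 0.5)
  median <- if (length(med_i)) ut[min(med_i)] else NA_real_
  # S(t) = 0 is degenerate (CI collapses to {0}): counts as crossing 0.5
  lo_i <- which((!is.na(lower) & lower <= 0.5) | surv == 0)
  hi_i <- which((!is.na(upper) & upper <= 0.5) | surv == 0)
  median_ci <- c(if (length(lo_i)) ut[min(lo_i)] else NA_real_,
                 if (length(hi_i)) ut[min(hi_i)] else NA_real_)
  structure(list(curve = data.frame(time = ut, n_risk = n_risk,
                                    n_event = d, n_censor = cns,
                                    surv = surv, lower = lower,
                                    upper = upper),
                 median = median, median_ci = median_ci,
                 conf_level = conf_level, n = length(times)),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  ci <- sprintf("(%s-%s)",
                ifelse(is.na(x$median_ci[1]), "NA",
                       format(x$median_ci[1], digits = 4)),
                ifelse(is.na(x$median_ci[2]), "NA",
                       format(x$median_ci[2], digits = 4)))
  cat(sprintf("<km_curve> n = %d, median = %s months, %.0f%% CI %s\n",
              x$n, ifelse(is.na(x$median), "not reached",
                          format(x$median, digits = 4)),
              100 * x$conf_level, ci))
  invisible(x)
}

#' Log-rank test
#'
#' Mantel-Haenszel observed-minus-expected statistic with hypergeometric
#' variance, referred to a chi-square distribution on (groups - 1) degrees
#' of freedom.
#'
#' @param times,events as in [km_fit()].
#' @param group group membership vector (>= 2 non-empty groups).
#' @return A `logrank_result` with `chi2`, `df`, `p`.
#' @export
logrank_test <- function(times, events, group) {
  group <- as.factor(group)
  if (nlevels(droplevels(group)) < 2L)
    stop_stat("log-rank test needs at least two non-empty groups")
  sd <- survival::survdiff(
    survival::Surv(times, as.integer(as.logical(events))) ~ group)
  df <- length(sd$n) - 1L
  structure(list(chi2 = unname(sd$chisq), df = df,
                 p = pchisq(sd$chisq, df, lower.tail = FALSE)),
            class = "logrank_result")
}

#' @export
print.logrank_result <- function(x, ...) {
  cat(sprintf("<logrank> chi2 = %.4f on %d df, p = %.4g\n",
              x$chi2, x$df, x$p))
  invisible(x)
}

#' Cox proportional-hazards fit
#'
#' Maximizes the partial likelihood (Efron tie handling by default;
#' Breslow available) and reports per-term hazard ratios with Wald
#' confidence intervals and p-values. Non-convergence and monotone
#' likelihood (complete separation) are reported via the `converged` flag
#' and attached messages rather than silently.
#'
#' @param data data frame with the modelling columns.
#' @param time_col,event_col column names of the duration and 0/1 event.
#' @param covariates character vector of numeric/binary column names.
#' @param ties `"efron"` (default) or `"breslow"`.
#' @param conf_level confidence level for the Wald intervals.
#' @return A `cox_fit`: data frame `terms` (name, coefficient,
#'   hazard_ratio, ci_low, ci_high, p), `ties_method`, `converged`,
#'   `messages`, `n`, `n_events`, and the underlying `coxph` object `fit`.
#' @export
cox_fit <- function(data, time_col, event_col, covariates,
                    ties = c("efron", "breslow"), conf_level = 0.95) {
  ties <- match.arg(ties)
  if (!sum(data[[event_col]]) >= 1) stop_stat("no events in data")
  fml <- stats::reformulate(
    covariates,
    response = sprintf("survival::Surv(%s, %s)", time_col, event_col))
  msgs <- character(0)
  fit <- withCallingHandlers(
    survival::coxph(fml, data = data, ties = ties),
    warning = function(w) {
      msgs <<- c(msgs, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  beta <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  z <- qnorm(1 - (1 - conf_level) / 2)
  converged <- !any(grepl("converge|infinite|out of iterations", msgs,
                          ignore.case = TRUE)) && !anyNA(beta)
  structure(list(
    terms = data.frame(name = names(beta), coefficient = unname(beta),
                       hazard_ratio = exp(unname(beta)),
                       ci_low = exp(unname(beta) - z * se),
                       ci_high = exp(unname(beta) + z * se),
                       p = 2 * pnorm(-abs(unname(beta) / se)),
                       stringsAsFactors = FALSE),
    ties_method = ties, converged = converged, messages = msgs,
    selection_trace = character(0),
    n = fit$n, n_events = fit$nevent, fit = fit),
    class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("<cox_fit> n = %d, events = %d, ties = %s%s\n", x$n,
              x$n_events, x$ties_method,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  tf <- x$terms
  for (i in seq_len(nrow(tf)))
    cat(sprintf("  %-22s HR %.3f (%.3f-%.3f)  p = %.4g\n", tf$name[i],
                tf$hazard_ratio[i], tf$ci_low[i], tf$ci_high[i], tf$p[i]))
  if (length(x$selection_trace))
    cat("  dropped:", paste(x$selection_trace, collapse = " -> "), "\n")
  invisible(x)
}

#' Stepwise backward covariate selection for a Cox model
#'
#' Starting from the full model, repeatedly removes the term with the
#' largest Wald p-value above `stay_alpha` and refits, until every
#' remaining term satisfies p <= `stay_alpha` (or none remain).
#'
#' @inheritParams cox_fit
#' @param stay_alpha stay threshold (default 0.05).
#' @return A `cox_fit` whose `selection_trace` records removals in order.
#' @export
backward_select <- function(data, time_col, event_col, covariates,
                            stay_alpha = 0.05,
                            ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  trace <- character(0)
  current <- covariates
  fit <- cox_fit(data, time_col, event_col, current, ties = ties)
  while (length(current) > 1 && max(fit$terms$p) > stay_alpha) {
    drop <- fit$terms$name[which.max(fit$terms$p)]
    trace <- c(trace, drop)
    current <- setdiff(current, drop)
    fit <- cox_fit(data, time_col, event_col, current, ties = ties)
  }
  if (length(current) == 1 && max(fit$terms$p) > stay_alpha) {
    trace <- c(trace, fit$terms$name)
    fit$terms <- fit$terms[0, , drop = FALSE]
  }
  fit$selection_trace <- trace
  fit
}

#' Post-hoc power for a two-group survival comparison (Schoenfeld)
#'
#' Normal approximation for the two-sided log-rank / Cox test:
#' power = Phi( sqrt(D p (1-p)) |ln HR| - z_{1-alpha/2} ), with D total
#' events and p the proportion allocated to group 1.
#'
#' @param hazard_ratio assumed hazard ratio (> 0).
#' @param n_events total number of events D (>= 1).
#' @param prop_group1 proportion in group 1, in (0, 1).
#' @param alpha two-sided significance level (default 0.05).
#' @return Power in (0, 1).
#' @export
schoenfeld_power <- function(hazard_ratio, n_events, prop_group1,
                             alpha = 0.05) {
  stopifnot(hazard_ratio > 0, n_events >= 1,
            prop_group1 > 0, prop_group1 < 1)
  pnorm(sqrt(n_events * prop_group1 * (1 - prop_group1)) *
          abs(log(hazard_ratio)) - qnorm(1 - alpha / 2))
}

#' Baseline characteristics table with chi-square comparisons
#'
#' For each categorical covariate: cross-tabulated counts against the
#' stratifier, column percentages, and a Pearson chi-square p-value
#' without continuity correction. A covariate with a single observed level
#' gets an undefined (NA) p.
#'
#' @param x an `episurv_cohort`.
#' @param stratifier column name defining the comparison groups.
#' @param covariates character vector of categorical column names.
#' @return Data frame: covariate, level, one count and one percentage
#'   column per stratum, p (repeated within covariate).
#' @export
baseline_table <- function(x, stratifier, covariates) {
  stopifnot(inherits(x, "episurv_cohort"))
  df <- x$data
  strata <- as.factor(df[[stratifier]])
  out <- list()
  for (cov in covariates) {
    v <- as.factor(df[[cov]])
    tab <- table(v, strata)
    p <- if (nrow(tab) < 2L || ncol(tab) < 2L) NA_real_ else
      pearson_chisq(tab)$p
    pct <- sweep(tab, 2, colSums(tab), "/") * 100
    block <- data.frame(covariate = cov, level = rownames(tab),
                        stringsAsFactors = FALSE)
    for (s in colnames(tab)) {
      block[[paste0("n_", s)]] <- as.vector(tab[, s])
      block[[paste0("pct_", s)]] <- round(as.vector(pct[, s]), 2)
    }
    block$p <- p
    out[[cov]] <- block
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Pearson chi-square without continuity correction, kept explicit so the
# (uncorrected) convention is pinned independently of chisq.test defaults.
pearson_chisq <- function(tab) {
  tab <- as.matrix(tab)
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  chi2 <- sum((tab - E)^2 / E)
  df <- (nrow(tab) - 1) * (ncol(tab) - 1)
  list(chi2 = chi2, df = df, p = pchisq(chi2, df, lower.tail = FALSE))
}
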