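# Independent slow oracles. These deliberately share no code with the
# package internals: plain loops, explicit formulas, fraction arithmetic.

# --- MDR -------------------------------------------------------------------

# Genotype string of record i at locus rs (canonical), or NA.
oracle_cells <- function(labeled, loci) {
  co <- labeled$cohort
  lab <- labeled$labels[co$data$patient_id]
  keep <- which(!is.na(lab))
  cells <- vapply(keep, function(i) {
    g <- vapply(loci, function(rs) co$data[[rs]][i], character(1))
    if (anyNA(g)) NA_character_ else paste(g, collapse = "/")
  }, character(1))
  list(cells = cells, y = unname(lab[keep]))
}

# Favorable iff r/n >= R/N, by integer cross-multiplication.
oracle_cell_label <- function(r, n, R, N) {
  if (r == 0 && n == 0) return("indeterminate")
  if (r * N >= R * n) "favorable" else "unfavorable"
}

oracle_ba <- function(pred, y) {
  keep <- pred %in% c("favorable", "unfavorable")
  pred <- pred[keep]; y <- y[keep]
  nr <- sum(y == "responder"); nn <- sum(y == "non_responder")
  if (nr == 0 || nn == 0) return(NA_real_)
  sens <- sum(pred == "favorable" & y == "responder") / nr
  spec <- sum(pred == "unfavorable" & y == "non_responder") / nn
  (sens + spec) / 2
}

# Full brute-force re-enumeration of the search for given folds: every
# tuple, every fold, training-split threshold, test balanced accuracy.
oracle_search <- function(labeled, loci, k, folds) {
  panel <- labeled$cohort$panel
  loci <- panel$rs_id[panel$rs_id %in% loci]
  tuples <- utils::combn(loci, k, simplify = FALSE)
  n_folds <- max(folds)
  res <- lapply(tuples, function(tp) {
    oc <- oracle_cells(labeled, tp)
    ba <- numeric(n_folds)
    for (f in seq_len(n_folds)) {
      tr <- which(folds != f & !is.na(oc$cells))
      te <- which(folds == f & !is.na(oc$cells))
      R <- sum(oc$y[tr] == "responder")
      N <- sum(oc$y[tr] == "non_responder")
      lab_of <- new.env()
      for (cl in unique(oc$cells[tr])) {
        r <- sum(oc$cells[tr] == cl & oc$y[tr] == "responder")
        n <- sum(oc$cells[tr] == cl & oc$y[tr] == "non_responder")
        assign(cl, oracle_cell_label(r, n, R, N), envir = lab_of)
      }
      pred <- vapply(oc$cells[te], function(cl)
        if (exists(cl, envir = lab_of)) get(cl, envir = lab_of)
        else "indeterminate", character(1))
      ba[f] <- oracle_ba(pred, oc$y[te])
    }
    ba
  })
  mean_ba <- vapply(res, function(b) mean(b, na.rm = TRUE), numeric(1))
  cons <- integer(length(tuples))
  for (f in seq_len(n_folds)) {
    col <- vapply(res, `[`, numeric(1), f)
    if (all(is.na(col))) next
    best <- which(col >= max(col, na.rm = TRUE) - 1e-12)
    cons[best] <- cons[best] + 1L
  }
  id <- vapply(tuples, function(tp) paste(sort(tp), collapse = "+"),
               character(1))
  w <- order(-mean_ba, -cons, id)[1]
  # final refit on all labeled records
  oc <- oracle_cells(labeled, tuples[[w]])
  used <- !is.na(oc$cells)
  R <- sum(oc$y[used] == "responder")
  N <- sum(oc$y[used] == "non_responder")
  all_cells <- epistasurv:::cell_names(panel, tuples[[w]])
  prof <- vapply(all_cells, function(cl) {
    r <- sum(oc$cells[used] == cl & oc$y[used] == "responder")
    n <- sum(oc$cells[used] == cl & oc$y[used] == "non_responder")
    oracle_cell_label(r, n, R, N)
  }, character(1))
  pred <- vapply(oc$cells, function(cl)
    if (is.na(cl)) "unknown" else prof[[cl]], character(1))
  list(loci = tuples[[w]], mean_ba = setNames(mean_ba, id),
       consistency = cons, cell_profile = prof,
       test_ba = mean_ba[w], cv_consistency = cons[w],
       threshold_T = R / N, train_ba = oracle_ba(pred, oc$y))
}

# --- survival --------------------------------------------------------------

# Naive product-limit recomputation of S(t) at time t.
oracle_km_surv <- function(times, events, t) {
  s <- 1
  for (u in sort(unique(times[events == 1 & times <= t]))) {
    d <- sum(times == u & events == 1)
    n <- sum(times >= u)
    s <- s * (1 - d / n)
  }
  s
}

# Two-group log-rank by explicit O-E and hypergeometric variance sums.
oracle_logrank2 <- function(t1, e1, t2, e2) {
  times <- sort(unique(c(t1[e1 == 1], t2[e2 == 1])))
  O <- E <- V <- 0
  for (u in times) {
    n1 <- sum(t1 >= u); n2 <- sum(t2 >= u); n <- n1 + n2
    d1 <- sum(t1 == u & e1 == 1); d2 <- sum(t2 == u & e2 == 1)
    d <- d1 + d2
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (n2 / n) * (n - d) / (n - 1)
  }
  chi2 <- (O - E)^2 / V
  list(chi2 = chi2, p = pchisq(chi2, 1, lower.tail = FALSE))
}

# Efron partial log-likelihood for one binary/numeric covariate.
oracle_cox_loglik <- function(beta, time, event, x, ties = "efron") {
  ll <- 0
  for (u in sort(unique(time[event == 1]))) {
    D <- which(time == u & event == 1)
    R <- which(time >= u)
    d <- length(D)
    sD <- sum(x[D]) * beta
    rs <- sum(exp(x[R] * beta))
    ds <- sum(exp(x[D] * beta))
    if (ties == "efron") {
      for (l in seq_len(d) - 1) ll <- ll - log(rs - (l / d) * ds)
      ll <- ll + sD
    } else {                       # breslow
      ll <- ll + sD - d * log(rs)
    }
  }
  ll
}

oracle_cox_beta <- function(time, event, x, ties = "efron") {
  stats::optimize(function(b) oracle_cox_loglik(b, time, event, x, ties),
                  interval = c(-8, 8), maximum = TRUE,
                  tol = 1e-9)$maximum
}
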