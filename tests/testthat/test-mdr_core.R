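test_that("contingency tables count cells and conserve records", {
  lab <- make_labeled(rep(c("responder", "non_responder"), each = 3),
                      list(rs833061 = rep(c("CT", "CC"), each = 3),
                           rs1870377 = rep(c("AT", "AA"), each = 3)))
  tab <- build_contingency(lab, c("rs833061", "rs1870377"))
  expect_s3_class(tab, "mdr_table")
  expect_identical(nrow(tab$cells), 9L)
  expect_identical(tab$cells$n_resp[tab$cells$cell == "CT/AT"], 3L)
  expect_identical(tab$cells$n_nonresp[tab$cells$cell == "CC/AA"], 3L)
  expect_identical(sum(tab$cells$n_resp) + sum(tab$cells$n_nonresp), 6L)
  expect_identical(tab$n_dropped_missing, 0L)
  # a record missing one model locus is dropped and counted
  lab2 <- make_labeled(rep(c("responder", "non_responder"), each = 3),
                       list(rs833061 = rep(c("CT", "CC"), each = 3),
                            rs1870377 = c("AT", NA, "AT", "AA", "AA", "AA")))
  tab2 <- build_contingency(lab2, c("rs833061", "rs1870377"))
  expect_identical(tab2$n_dropped_missing, 1L)
  expect_identical(tab2$n_used, 5L)
  expect_error(build_contingency(lab, c("rs833061", "rsX")), "not in panel")
  # conservation on a larger cohort with injected missingness
  labn <- random_labeled(200, seed = 21)
  labn$cohort$data$rs1870377[1:17] <- NA
  tabn <- build_contingency(labn, c("rs833061", "rs1870377"))
  expect_identical(tabn$n_used + tabn$n_dropped_missing, 200L)
  expect_identical(sum(tabn$cells$n_resp) + sum(tabn$cells$n_nonresp),
                   tabn$n_used)
})

test_that("cell classification applies the ratio-threshold rule", {
  mk <- function(r, n) {
    structure(list(loci = "x",
                   cells = data.frame(cell = paste0("c", seq_along(r)),
                                      n_resp = r, n_nonresp = n)),
              class = "mdr_table")
  }
  # empty cell indeterminate; r>0/n=0 favorable at any threshold
  expect_identical(unname(classify_cells(mk(c(0, 3), c(0, 0)), 99)),
                   c("indeterminate", "favorable"))
  # T = 59/47: a (5,4) cell has ratio 1.25 < 1.2553 -> unfavorable
  expect_identical(unname(classify_cells(mk(5, 4), 59 / 47)),
                   "unfavorable")
  # ties classify favorable, and the rule is scale-invariant
  tab <- mk(c(6, 1, 0), c(4, 3, 2))   # totals 7/9; cell1 6/4 >= 7/9
  tab10 <- mk(c(60, 10, 0), c(40, 30, 20))
  expect_identical(classify_cells(tab), classify_cells(tab10))
  tie <- mk(c(7, 7), c(9, 9))         # cell ratio equals total ratio
  expect_identical(unname(classify_cells(tie)),
                   c("favorable", "favorable"))
  expect_error(classify_cells(mk(1, 1), -2), "positive")
})

test_that("balanced accuracy matches its definition and edge cases", {
  expect_identical(balanced_accuracy(c("favorable", "unfavorable"),
                                     c("responder", "non_responder")), 1)
  expect_identical(balanced_accuracy(rep("favorable", 4),
                                     c("responder", "responder",
                                       "non_responder", "non_responder")),
                   0.5)
  # TP=3 FN=1 TN=2 FP=2 -> (0.75 + 0.5)/2
  prof <- c(rep("favorable", 3), "unfavorable",
            rep("unfavorable", 2), rep("favorable", 2), "unknown")
  labs <- c(rep("responder", 4), rep("non_responder", 4), "responder")
  expect_equal(balanced_accuracy(prof, labs), 0.625)
  expect_error(balanced_accuracy(c("favorable", "favorable"),
                                 c("responder", "responder")),
               "class is absent")
})

test_that("profile application uses the published map and handles missing", {
  model <- list(loci = c("rs833061", "rs1870377"),
                cell_profile = published_profile_map())
  co <- cohort(patient_df(4,
                          rs833061 = c("CT", "CC", "TT", "CT"),
                          rs1870377 = c("AT", "AA", "TT", NA)),
               panel = two_locus_panel())
  expect_identical(unname(apply_profile(model, co)),
                   c("favorable", "unfavorable", "favorable", "unknown"))
})

test_that("a pure two-locus interaction dominates the search", {
  # XOR-style pattern: neither locus is marginally informative, the pair
  # separates perfectly, a third locus is noise
  panel <- locus_panel(c("rs1870377", "rs4073", "rs833061"),
                       c("VEGFR-2", "IL-8", "VEGF-A"),
                       c("T", "A", "C"), c("A", "T", "T"))
  n <- 40
  g1 <- rep(c("CC", "CC", "TT", "TT"), n / 4)
  g2 <- rep(c("TT", "AA", "TT", "AA"), n / 4)
  labels <- ifelse((g1 == "CC") == (g2 == "TT"), "responder",
                   "non_responder")
  noise <- withr::with_seed(4, hwe_genotypes(n, panel[2, ], 0.4))
  lab <- make_labeled(labels, list(rs833061 = g1, rs1870377 = g2,
                                   rs4073 = noise), panel = panel)
  m <- search_best_model(lab, k = 2, cv = cv_config(n_folds = 5, seed = 9))
  expect_setequal(m$loci, c("rs833061", "rs1870377"))
  expect_identical(m$test_ba, 1)
  expect_identical(m$cv_consistency, 5L)
  expect_identical(m$train_ba, 1)
  # loci are reported in panel order
  expect_identical(m$loci, c("rs1870377", "rs833061"))
  # exhaustiveness: one score per tuple
  expect_length(m$mean_ba, choose(3, 2))
  expect_length(search_best_model(lab, k = 3,
                                  cv = cv_config(n_folds = 5, seed = 9)
  )$mean_ba, 1L)
  expect_error(search_best_model(lab, k = 4), "between 1 and")
})

test_that("search equals the brute-force oracle on a small instance", {
  lab <- random_labeled(30, seed = 31)
  cv <- cv_config(n_folds = 5, seed = 17)
  m <- search_best_model(lab, k = 2, cv = cv)
  o <- oracle_search(lab, lab$cohort$panel$rs_id, 2, m$folds)
  expect_identical(m$loci, o$loci)
  expect_equal(m$mean_ba, o$mean_ba[names(m$mean_ba)], tolerance = 1e-12)
  expect_identical(as.character(m$cell_profile),
                   as.character(o$cell_profile))
  expect_equal(m$test_ba, unname(o$test_ba), tolerance = 1e-12)
  expect_identical(m$cv_consistency, o$cv_consistency)
  expect_equal(m$train_ba, o$train_ba, tolerance = 1e-12)
})

test_that("the search is deterministic under a fixed fold seed", {
  lab <- random_labeled(60, seed = 44)
  m1 <- search_best_model(lab, cv = cv_config(seed = 5))
  m2 <- search_best_model(lab, cv = cv_config(seed = 5))
  expect_identical(m1[c("loci", "cell_profile", "threshold_T", "train_ba",
                        "test_ba", "cv_consistency", "folds")],
                   m2[c("loci", "cell_profile", "threshold_T", "train_ba",
                        "test_ba", "cv_consistency", "folds")])
})

test_that("label-permuted data scores near chance", {
  # per-tuple CV testing BA is centred on 0.5 under the null (the
  # training-split threshold leaks nothing into the held-out folds);
  # the *winner* sits slightly above 0.5 by selection over 6 tuples
  per_tuple <- winner <- numeric(100)
  for (s in 1:100) {
    m <- search_best_model(random_labeled(200, seed = 700 + s),
                           cv = cv_config(seed = s))
    per_tuple[s] <- mean(m$mean_ba)
    winner[s] <- m$test_ba
  }
  expect_gt(mean(per_tuple), 0.45)
  expect_lt(mean(per_tuple), 0.55)
  expect_gte(mean(winner), mean(per_tuple))
})

test_that("models serialize to JSON with the full cell map", {
  lab <- random_labeled(40, seed = 50)
  m <- search_best_model(lab, cv = cv_config(n_folds = 5, seed = 2))
  path <- tempfile(fileext = ".json")
  write_mdr_model(m, path)
  back <- jsonlite::read_json(path)
  expect_length(back$cell_profile, 9L)
  expect_identical(unlist(back$loci), m$loci)
})
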