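test_that("confusion_metrics reproduces the standard formulas on hand counts", {
  m <- confusion_metrics(tp = 3, fn = 1, fp = 2, tn = 4)
  expect_equal(m$accuracy, 0.7)
  expect_equal(m$recall, 0.75)
  expect_equal(m$precision, 0.6)
  expect_equal(m$f1, 2 * 0.75 * 0.6 / (0.75 + 0.6))
  expect_equal(round(m$f1, 4), 0.6667)
})

test_that("zero-denominator metrics are NA with a reason, never silently 0", {
  m <- confusion_metrics(tp = 0, fn = 0, fp = 2, tn = 4)
  expect_true(is.na(m$recall))
  expect_match(m$note, "recall undefined")
  m2 <- confusion_metrics(tp = 0, fn = 3, fp = 0, tn = 4)
  expect_true(is.na(m2$precision))
  expect_error(confusion_metrics(0, 0, 0, 0), class = "psn_empty_error")
  expect_error(confusion_metrics(-1, 1, 1, 1), class = "psn_precondition_error")
})

test_that("auc_score equals brute-force pairwise comparison on 200 random instances", {
  set.seed(77)
  for (trial in 1:200) {
    n <- sample(4:30, 1)
    labels <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (all(labels) || !any(labels)) labels[1:2] <- c(TRUE, FALSE)
    scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # forces ties
    expect_equal(auc_score(scores, labels), bf_auc(scores, labels),
                 tolerance = 1e-12)
  }
})

test_that("auc_score agrees with the pROC reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(78)
  for (trial in 1:20) {
    n <- sample(20:60, 1)
    labels <- c(TRUE, FALSE, sample(c(TRUE, FALSE), n - 2, replace = TRUE))
    scores <- round(runif(n), 2)
    ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                          direction = "<")))
    expect_equal(auc_score(scores, labels), ref, tolerance = 1e-12)
  }
})

test_that("degenerate single-class AUC is NA with a warning", {
  expect_warning(a <- auc_score(c(0.2, 0.8), c(TRUE, TRUE)), "one class")
  expect_true(is.na(a))
})

test_that("macro multiclass AUC averages the defined one-vs-rest AUCs", {
  S <- rbind(c(0.7, 0.2, 0.1, 0), c(0.1, 0.6, 0.2, 0.1),
             c(0.2, 0.2, 0.5, 0.1), c(0.3, 0.3, 0.2, 0.2))
  colnames(S) <- c("I", "II", "III", "IV")
  labels <- c("I", "II", "III", "I")
  r <- auc_multiclass(S, labels)
  expect_true(is.na(r$per_class$auc[r$per_class$class == "IV"]))
  manual <- sapply(c("I", "II", "III"), function(cl) bf_auc(S[, cl], labels == cl))
  expect_equal(r$macro, mean(manual), tolerance = 1e-12)
})

test_that("optimize_k honours the grid, tie rule and metric argument", {
  co <- small_cohort(60, seed = 51)
  psn <- build_psn(co, generate_toy_ontology(), default_indicator_schema())
  k1 <- optimize_k(psn, "complication", k_grid = 7)
  expect_equal(as.integer(k1), 7L)
  path <- attr(optimize_k(psn, "complication", k_grid = c(5, 10, 20)), "path")
  expect_equal(path$k, c(5, 10, 20))
  # ties go to the smallest k: force one by duplicating a grid value
  k2 <- optimize_k(psn, "complication", k_grid = c(10, 10, 20))
  expect_true(as.integer(k2) %in% c(10L, 20L))
  ka <- optimize_k(psn, "complication", k_grid = c(5, 10), metric = "auc")
  pa <- attr(ka, "path")
  expect_equal(as.integer(ka), as.integer(pa$k[which.max(pa$score)]))
})

test_that("group_outcome_tests reproduces the documented examples", {
  members <- tibble::tibble(icu_los_days = c(1, 2, 3), complication = c(TRUE, rep(FALSE, 2)))
  others <- tibble::tibble(icu_los_days = c(4, 5, 6), complication = c(TRUE, FALSE, TRUE))
  r <- group_outcome_tests(members, others)
  mw <- r[r$outcome == "icu_los_days", ]
  expect_identical(mw$test, "mann_whitney_u")
  expect_equal(mw$statistic, 0)           # complete separation
  expect_equal(mw$p_value, 0.1, tolerance = 1e-9)  # exact two-sided p = 2/20
  # 2x2 table (10,0 / 0,10) -> Pearson chi-squared = 20
  m2 <- tibble::tibble(complication = rep(TRUE, 10))
  o2 <- tibble::tibble(complication = rep(FALSE, 10))
  r2 <- group_outcome_tests(m2, o2)
  expect_equal(r2$statistic, 20)
  expect_true(r2$significant)
})

test_that("zero-variance contrasts come back undefined with a reason", {
  m <- tibble::tibble(icu_los_days = rep(2, 4), complication = rep(FALSE, 4))
  o <- tibble::tibble(icu_los_days = rep(2, 4), complication = rep(FALSE, 4))
  r <- group_outcome_tests(m, o)
  expect_true(all(is.na(r$statistic)))
  expect_true(all(grepl("no variance", r$note)))
  expect_error(group_outcome_tests(m[0, ], o), class = "psn_precondition_error")
})

test_that("group_outcome_tests accepts a psn and a group directly", {
  co <- small_cohort(40, seed = 52)
  psn <- build_psn(co, generate_toy_ontology(), default_indicator_schema())
  g <- knn_neighbors(psn, psn$ids[1], 10)
  r <- group_outcome_tests(psn, g)
  expect_setequal(r$outcome, c("ventilation_hours", "icu_los_days",
                               "hospital_los_days", "complication", "survived"))
})

test_that("run_benchmark rejects train/test leakage", {
  co <- small_cohort(30, seed = 53)
  expect_error(run_benchmark(co, co[1:5, ], generate_toy_ontology(),
                             default_indicator_schema()),
               class = "psn_leakage_error")
})
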