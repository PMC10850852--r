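#' Classification metrics from a confusion table
#'
#' Accuracy = (TP + TN) / (TP + TN + FP + FN), Recall = TP / (TP + FN),
#' Precision = TP / (TP + FP), F1 = 2 * Recall * Precision /
#' (Recall + Precision). A ratio with a zero denominator is reported as `NA`
#' with the reason in `note`, never silently as 0.
#'
#' @param tp,tn,fp,fn Non-negative integer counts.
#' @return One-row tibble: `accuracy`, `recall`, `precision`, `f1`, `note`.
#' @export
confusion_metrics <- function(tp, tn, fp, fn) {
  counts <- c(tp = tp, tn = tn, fp = fp, fn = fn)
  if (any(counts < 0) || any(counts != floor(counts))) {
    psn_abort("confusion counts must be non-negative integers", "psn_precondition_error")
  }
  if (sum(counts) == 0) psn_abort("empty evaluation: all confusion counts are zero",
                                  "psn_empty_error")
  notes <- character()
  accuracy <- (tp + tn) / sum(counts)
  recall <- if (tp + fn == 0) { notes <- c(notes, "recall undefined: TP+FN=0"); NA_real_ } else tp / (tp + fn)
  precision <- if (tp + fp == 0) { notes <- c(notes, "precision undefined: TP+FP=0"); NA_real_ } else tp / (tp + fp)
  f1 <- if (is.na(recall) || is.na(precision)) {
    notes <- c(notes, "f1 undefined: needs recall and precision")
    NA_real_
  } else if (recall + precision == 0) {
    notes <- c(notes, "f1 undefined: recall+precision=0")
    NA_real_
  } else {
    2 * recall * precision / (recall + precision)
  }
  tibble(accuracy = accuracy, recall = recall, precision = precision, f1 = f1,
         note = if (length(notes)) paste(notes, collapse = "; ") else NA_character_)
}

#' Rank-based (Mann-Whitney) AUC
#'
#' Area under the ROC curve computed from ranks with mid-rank tie handling:
#' equivalent to the probability that a random positive scores above a random
#' negative, with half credit for ties.
#'
#' @param scores Numeric prediction scores.
#' @param labels Logical (or 0/1) true labels.
#' @return AUC in `[0, 1]`; `NA` with a warning if only one class is present.
#' @export
auc_score <- function(scores, labels) {
  labels <- as.logical(labels)
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]; labels <- labels[keep]
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) {
    warn("AUC undefined: only one class present")
    return(NA_real_)
  }
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' One-vs-rest multiclass AUC with macro average
#'
#' @param scores Matrix of per-class scores (columns named by class).
#' @param labels Character/factor true classes.
#' @return List with `per_class` (tibble `class`, `auc`) and `macro`
#'   (mean over classes with both positives and negatives).
#' @export
auc_multiclass <- function(scores, labels) {
  labels <- as.character(labels)
  classes <- colnames(scores)
  per <- map_dbl(classes, function(cl) {
    y <- labels == cl
    if (sum(y) == 0 || sum(!y) == 0) return(NA_real_)
    auc_score(scores[, cl], y)
  })
  list(per_class = tibble(class = classes, auc = per),
       macro = mean(per, na.rm = TRUE))
}

# Leave-one-out neighbour orderings for a fused matrix: for each patient the
# indices of the others sorted by (distance, patient_id).
loo_orderings <- function(psn) {
  n <- length(psn$ids)
  lapply(seq_len(n), function(i) {
    d <- psn$values[i, -i]
    ids <- psn$ids[-i]
    idx <- seq_len(n)[-i]
    idx[order(d, ids)]
  })
}

# Leave-one-out KNN vote predictions on the training cohort at one k.
# Returns a tibble with truth, label and score(s).
loo_vote <- function(psn, task = c("complication", "ventilation_class"), k,
                     orderings = NULL) {
  task <- match.arg(task)
  orderings <- orderings %||% loo_orderings(psn)
  n <- length(psn$ids)
  k <- min(k, n - 1)
  if (task == "complication") {
    y <- as.logical(psn$cohort$complication)
    score <- map_dbl(orderings, ~ mean(y[.x[seq_len(k)]]))
    tibble(patient_id = psn$ids, truth = y, score = score, label = score > 0.5)
  } else {
    yv <- as.character(bin_ventilation(psn$cohort$ventilation_hours))
    prev <- table(factor(yv, levels = VENT_CLASSES))
    S <- t(vapply(orderings, function(o) {
      tab <- table(factor(yv[o[seq_len(k)]], levels = VENT_CLASSES))
      as.numeric(tab) / k
    }, numeric(4)))
    colnames(S) <- VENT_CLASSES
    lab <- apply(S, 1, function(s) {
      VENT_CLASSES[order(-s, -as.numeric(prev), seq_along(VENT_CLASSES))[1]]
    })
    tibble(patient_id = psn$ids, truth = yv, label = lab, scores = split(S, row(S)) %>%
             map(~ setNames(.x, VENT_CLASSES)))
  }
}

binary_confusion <- function(truth, label) {
  list(tp = sum(truth & label), tn = sum(!truth & !label),
       fp = sum(!truth & label), fn = sum(truth & !label))
}

macro_f1 <- function(truth, label, classes) {
  f1s <- map_dbl(classes, function(cl) {
    cm <- binary_confusion(truth == cl, label == cl)
    if (cm$tp + cm$fn == 0 || cm$tp + cm$fp == 0) return(NA_real_)
    if (cm$tp == 0) return(0)
    r <- cm$tp / (cm$tp + cm$fn); p <- cm$tp / (cm$tp + cm$fp)
    2 * r * p / (r + p)
  })
  mean(f1s, na.rm = TRUE)
}

#' Select the population-level k on the training cohort
#'
#' Leave-one-out neighbourhood voting over the training map at each
#' candidate k; returns the k maximising the selection metric - F1 (binary)
#' or macro-F1 (ventilation classes) by default, AUC / macro one-vs-rest AUC
#' when an analysis targets ranking performance. Ties go to the smallest k,
#' so the choice is deterministic.
#'
#' @param psn A [build_psn()] object on the training cohort.
#' @param task `"complication"` or `"ventilation_class"`.
#' @param k_grid Candidate k values (clipped to `[1, n - 1]`).
#' @param metric Selection metric, `"f1"` (default) or `"auc"`.
#' @return The selected k (integer), with the score path in the
#'   `"path"` attribute.
#' @export
optimize_k <- function(psn, task = c("complication", "ventilation_class"),
                       k_grid = c(3, 5, 10, 15, 20, 30, 50, 75, 100, 150, 200),
                       metric = c("f1", "auc")) {
  task <- match.arg(task)
  metric <- match.arg(metric)
  n <- length(psn$ids)
  k_grid <- sort(unique(pmin(pmax(k_grid, 1), n - 1)))
  if (length(k_grid) == 0) psn_abort("empty k grid", "psn_config_error")
  if (task == "complication" && length(unique(psn$cohort$complication)) < 2) {
    psn_abort("degenerate cohort: single outcome class", "psn_precondition_error")
  }
  orderings <- loo_orderings(psn)
  score <- map_dbl(k_grid, function(k) {
    pred <- loo_vote(psn, task, k, orderings)
    if (task == "complication") {
      if (metric == "auc") return(suppressWarnings(auc_score(pred$score, pred$truth)))
      cm <- binary_confusion(pred$truth, pred$label)
      m <- confusion_metrics(cm$tp, cm$tn, cm$fp, cm$fn)
      if (is.na(m$f1)) 0 else m$f1
    } else {
      if (metric == "auc") {
        S <- do.call(rbind, pred$scores)
        return(auc_multiclass(S, pred$truth)$macro)
      }
      macro_f1(pred$truth, pred$label, VENT_CLASSES)
    }
  })
  best <- k_grid[which.max(score)] # which.max takes the first (smallest k) on ties
  structure(as.integer(best), path = tibble(k = k_grid, score = score))
}

metrics_row <- function(truth, label, score_auc) {
  if (is.logical(truth)) {
    cm <- binary_confusion(truth, label)
    m <- confusion_metrics(cm$tp, cm$tn, cm$fp, cm$fn)
    m$auc <- suppressWarnings(auc_score(score_auc, truth))
    m
  } else {
    rec <- mean(map_dbl(VENT_CLASSES, function(cl) {
      if (sum(truth == cl) == 0) return(NA_real_)
      sum(truth == cl & label == cl) / sum(truth == cl)
    }), na.rm = TRUE)
    prec <- mean(map_dbl(VENT_CLASSES, function(cl) {
      if (sum(label == cl) == 0) return(NA_real_)
      sum(truth == cl & label == cl) / sum(label == cl)
    }), na.rm = TRUE)
    tibble(accuracy = mean(truth == label), recall = rec, precision = prec,
           f1 = macro_f1(truth, label, VENT_CLASSES),
           note = NA_character_,
           auc = auc_multiclass(score_auc, truth)$macro)
  }
}

predict_test_set <- function(psn, test, method, k, spec, cd = NULL) {
  classes <- if (spec$target == "complication") c("no", "yes") else VENT_CLASSES
  # one cross-distance pass for the whole test set, then per-index groups
  cd <- cd %||% cross_distances(psn, test)
  k <- min(k, length(psn$ids))
  rows <- map(seq_len(nrow(test)), function(i) {
    sp <- spec
    sp$seed <- spec$seed + i  # fresh random baseline per index case
    d <- cd$values[i, ]
    ord <- order(d, psn$ids)
    sel <- ord[seq_len(k)]
    group <- new_group(as.character(test$patient_id[i]), psn$ids[sel],
                       unname(d[sel]), list(type = "k", value = k))
    predict_from_group(psn, group, test[i, ], method, sp)
  })
  pred <- bind_rows(rows)
  S <- do.call(rbind, map(pred$scores, ~ .x[classes]))
  colnames(S) <- classes
  list(pred = pred, scores = S)
}

#' Run the full benchmark grid on a train/test cohort pair
#'
#' Mirrors the method-comparison protocol: for each indicator preprocessing
#' (`origin`, `zscore`, `combination`) crossed with each diagnosis mode
#' (`ungrade`, `grade`), the population-level k is selected on the training
#' map and the test cases are predicted by neighbourhood vote (KNN) and by
#' the group-trained logistic model (KNN+LR); one size-matched random-cohort
#' baseline row (k-Random+LR) completes the table. Both tasks are scored
#' with accuracy, recall, precision, F1 and AUC (KNN vote scores are the
#' neighbour proportions; multiclass AUC is macro one-vs-rest).
#'
#' @param train,test Disjoint cohort tibbles.
#' @param onto A [ontology()].
#' @param schema An [indicator_schema()].
#' @param tasks Tasks to run (default both).
#' @param weights A [weight_vector()].
#' @param k Fixed k, or `NULL` to optimise per configuration and task.
#' @param k_grid Grid for [optimize_k()].
#' @param alpha Grade-mode primary weight.
#' @param seed Master seed (drives the random baselines).
#' @return Tibble with one row per method x task: `task`, `family`,
#'   `preprocessing`, `mode`, `k`, and the five metrics.
#' @export
run_benchmark <- function(train, test, onto, schema,
                          tasks = c("complication", "ventilation_class"),
                          weights = weight_vector(), k = NULL,
                          k_grid = c(3, 5, 10, 15, 20, 30, 50, 75, 100, 150, 200),
                          alpha = 0.7, seed = 1L) {
  train <- as_tibble(train); test <- as_tibble(test)
  overlap <- intersect(train$patient_id, test$patient_id)
  if (length(overlap) > 0) {
    psn_abort(paste0("train/test leakage: shared patient_id ",
                     paste(head(overlap, 3), collapse = ", ")), "psn_leakage_error")
  }
  grid <- tidyr::expand_grid(preprocessing = c("origin", "zscore", "combination"),
                             mode = c("ungrade", "grade"))
  out <- list()
  first_cfg <- NULL
  for (g in seq_len(nrow(grid))) {
    psn <- build_psn(train, onto, schema, method = grid$preprocessing[g],
                     mode = grid$mode[g], weights = weights, alpha = alpha)
    cd <- cross_distances(psn, test)
    if (g == 1) { first_cfg <- psn; first_cd <- cd }
    for (task in tasks) {
      k_use <- k %||% optimize_k(psn, task, k_grid)
      spec <- local_model_spec(target = task, seed = seed)
      truth <- if (task == "complication") as.logical(test$complication) else
        as.character(bin_ventilation(test$ventilation_hours))
      for (fam in c("KNN", "KNN+LR")) {
        method <- if (fam == "KNN") "vote" else "knn_lr"
        res <- predict_test_set(psn, test, method, k_use, spec, cd = cd)
        lab <- if (task == "complication") res$pred$label == "yes" else res$pred$label
        sc <- if (task == "complication") res$scores[, "yes"] else res$scores
        m <- metrics_row(truth, lab, sc)
        out[[length(out) + 1]] <- mutate(m, task = task, family = fam,
                                         preprocessing = grid$preprocessing[g],
                                         mode = grid$mode[g], k = as.integer(k_use))
      }
    }
  }
  # one size-matched random baseline per task, on the first configuration
  for (task in tasks) {
    k_use <- k %||% optimize_k(first_cfg, task, k_grid)
    spec <- local_model_spec(target = task, seed = seed)
    truth <- if (task == "complication") as.logical(test$complication) else
      as.character(bin_ventilation(test$ventilation_hours))
    res <- predict_test_set(first_cfg, test, "random_lr", k_use, spec, cd = first_cd)
    lab <- if (task == "complication") res$pred$label == "yes" else res$pred$label
    sc <- if (task == "complication") res$scores[, "yes"] else res$scores
    m <- metrics_row(truth, lab, sc)
    out[[length(out) + 1]] <- mutate(m, task = task, family = "k-Random+LR",
                                     preprocessing = NA_character_, mode = NA_character_,
                                     k = as.integer(k_use))
  }
  bind_rows(out) %>%
    select("task", "family", "preprocessing", "mode", "k",
           "accuracy", "recall", "precision", "f1", "auc", "note") %>%
    arrange(.data$task, factor(.data$family, levels = c("KNN", "KNN+LR", "k-Random+LR")))
}

wilcox_contrast <- function(x, y) {
  if (sd(c(x, y)) == 0) {
    return(list(statistic = NA_real_, p = NA_real_, note = "no variance on either side"))
  }
  exact <- length(x) <= 8 && length(y) <= 8 && !anyDuplicated(c(x, y))
  wt <- suppressWarnings(wilcox.test(x, y, exact = exact, correct = FALSE))
  list(statistic = unname(wt$statistic), p = wt$p.value, note = NA_character_)
}

chisq_contrast <- function(x, y, yates = FALSE) {
  tab <- rbind(c(sum(x), sum(!x)), c(sum(y), sum(!y)))
  if (any(colSums(tab) == 0)) {
    return(list(statistic = NA_real_, p = NA_real_, note = "no variance on either side"))
  }
  ct <- suppressWarnings(chisq.test(tab, correct = yates))
  list(statistic = unname(ct$statistic), p = ct$p.value, note = NA_character_)
}

#' Outcome contrasts between a similarity group and the rest of the cohort
#'
#' The outcome-view statistics: continuous outcomes (ventilation hours, ICU
#' and hospital stay) are compared with the two-sided Mann-Whitney U test
#' (exact when both sides have at most 8 untied values, otherwise the normal
#' approximation with tie correction); binary outcomes (complication,
#' survival) with the Pearson chi-squared test on the 2x2 table (Yates
#' continuity correction optional). The `significant` flag at `alpha` is the
#' "check box turns red" signal of the interactive view.
#'
#' @param members,others Cohort tibbles for the similarity group and the
#'   remaining patients; alternatively pass a `psn` and a `psn_group` as the
#'   first two arguments.
#' @param yates Use Yates continuity correction for the chi-squared tests.
#' @param alpha Significance level for the flag.
#' @return Tibble: `outcome`, `test`, `statistic`, `p_value`, `significant`,
#'   `note`.
#' @export
group_outcome_tests <- function(members, others, yates = FALSE, alpha = 0.05) {
  if (inherits(members, "psn") && inherits(others, "psn_group")) {
    psn <- members; group <- others
    members <- psn$cohort[psn$cohort$patient_id %in% group$members$patient_id, ]
    others <- psn$cohort[!psn$cohort$patient_id %in%
                           c(group$members$patient_id, group$index_id), ]
  }
  members <- as_tibble(members); others <- as_tibble(others)
  if (nrow(members) == 0 || nrow(others) == 0) {
    psn_abort("both groups must be non-empty", "psn_precondition_error")
  }
  cont <- intersect(c("ventilation_hours", "icu_los_days", "hospital_los_days"),
                    intersect(names(members), names(others)))
  bin <- intersect(c("complication", "survived"), intersect(names(members), names(others)))
  rows <- list()
  for (v in cont) {
    r <- wilcox_contrast(members[[v]], others[[v]])
    rows[[length(rows) + 1]] <- tibble(outcome = v, test = "mann_whitney_u",
                                       statistic = r$statistic, p_value = r$p,
                                       note = r$note)
  }
  for (v in bin) {
    r <- chisq_contrast(as.logical(members[[v]]), as.logical(others[[v]]), yates)
    rows[[length(rows) + 1]] <- tibble(outcome = v, test = "chi_squared",
                                       statistic = r$statistic, p_value = r$p,
                                       note = r$note)
  }
  bind_rows(rows) %>%
    mutate(significant = !is.na(.data$p_value) & .data$p_value < alpha,
           .before = "note")
}
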