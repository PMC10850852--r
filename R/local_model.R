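#' Specification of the locally trained logistic model
#'
#' The personalised predictor is an L2-regularised logistic regression
#' (multinomial for the ventilation-class task) fitted only on the index
#' patient's similarity group. Small local samples need shrinkage, hence the
#' ridge penalty; `reg_strength` follows the inverse-regularisation
#' convention (larger = weaker penalty, glmnet lambda = 1 / (C * n)).
#'
#' @param target `"complication"` (binary) or `"ventilation_class"` (4-class).
#' @param reg_strength Inverse regularisation strength C (> 0), default 1.
#' @param max_iter Maximum solver iterations.
#' @param seed Seed used by [fit_random_baseline()] sampling.
#' @param features Optional subset of model feature columns.
#' @return An object of class `psn_model_spec`.
#' @export
local_model_spec <- function(target = c("complication", "ventilation_class"),
                             reg_strength = 1, max_iter = 1e5, seed = 1L,
                             features = NULL) {
  target <- match.arg(target)
  if (!is.numeric(reg_strength) || reg_strength <= 0) {
    psn_abort("reg_strength must be > 0", "psn_config_error")
  }
  structure(list(target = target, reg_strength = reg_strength,
                 max_iter = max_iter, seed = as.integer(seed), features = features),
            class = "psn_model_spec")
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# Numeric model matrix for the local LR: preprocessed indicator features
# (training-mean imputed), clinical and surgical numerics, encoded sex.
model_matrix_for <- function(psn, cohort, features = NULL) {
  cohort <- as_tibble(cohort)
  feat <- apply_preprocessor(psn$transform, cohort)
  X_ind <- as.matrix(feat[, psn$transform$features, drop = FALSE])
  if (ncol(X_ind) > 0) {
    for (j in seq_len(ncol(X_ind))) {
      miss <- is.na(X_ind[, j])
      if (any(miss)) X_ind[miss, j] <- psn$transform$impute[[colnames(X_ind)[j]]]
    }
  }
  base <- cbind(as.matrix(cohort[, c(CLINICAL_NUM, SURGICAL_NUM)]),
                sex_male = as.numeric(cohort$sex == "male"))
  for (j in seq_len(ncol(base))) {
    miss <- is.na(base[, j])
    if (any(miss)) {
      base[miss, j] <- mean(psn$cohort[[colnames(base)[j]]], na.rm = TRUE) %||% 0
    }
  }
  X <- cbind(X_ind, base)
  storage.mode(X) <- "double"
  rownames(X) <- cohort$patient_id
  if (!is.null(features)) X <- X[, intersect(features, colnames(X)), drop = FALSE]
  X
}

target_values <- function(cohort, target) {
  if (target == "complication") {
    factor(ifelse(cohort$complication, "yes", "no"), levels = c("no", "yes"))
  } else {
    factor(as.character(bin_ventilation(cohort$ventilation_hours)), levels = VENT_CLASSES)
  }
}

fit_lr <- function(X, y, spec) {
  observed <- levels(droplevels(y))
  if (length(observed) < 2) {
    return(structure(list(type = "constant", task = spec$target,
                          classes = levels(y), constant_class = observed,
                          features = colnames(X)),
                     class = "psn_local_model"))
  }
  # glmnet refuses classes with a single observation; fall back to a
  # prevalence model (scores = group class proportions, as in the vote)
  if (min(table(droplevels(y))) < 2) {
    props <- prop.table(table(factor(y, levels = levels(y))))
    return(structure(list(type = "prevalence", task = spec$target,
                          classes = levels(y), props = as.numeric(props),
                          features = colnames(X)),
                     class = "psn_local_model"))
  }
  # glmnet needs >= 2 columns; pad with an inert zero column if necessary
  padded <- FALSE
  if (ncol(X) < 2) {
    X <- cbind(X, .pad = 0)
    padded <- TRUE
  }
  yf <- droplevels(y)
  fam <- if (length(observed) == 2) "binomial" else "multinomial"
  lam <- 1 / (spec$reg_strength * nrow(X))
  fit <- suppressWarnings(
    glmnet::glmnet(X, yf, family = fam, alpha = 0, lambda = lam,
                   maxit = spec$max_iter, standardize = TRUE)
  )
  structure(list(type = "glmnet", task = spec$target, classes = levels(y),
                 observed = observed, fit = fit, padded = padded,
                 features = setdiff(colnames(X), ".pad")),
            class = "psn_local_model")
}

#' @export
print.psn_local_model <- function(x, ...) {
  cat("<psn_local_model> task '", x$task, "' (", x$type, "), ",
      length(x$features), " feature(s)\n", sep = "")
  invisible(x)
}

# Class-probability matrix (rows = cases, cols = model$classes).
predict_prob <- function(model, X) {
  K <- length(model$classes)
  n <- nrow(X)
  P <- matrix(0, n, K, dimnames = list(rownames(X), model$classes))
  if (model$type == "constant") {
    P[, model$constant_class] <- 1
    return(P)
  }
  if (model$type == "prevalence") {
    P[] <- rep(model$props, each = n)
    return(P)
  }
  if (model$padded) X <- cbind(X[, model$features, drop = FALSE], .pad = 0)
  else X <- X[, model$features, drop = FALSE]
  if (length(model$observed) == 2) {
    p2 <- as.numeric(predict(model$fit, X, type = "response"))
    P[, model$observed[2]] <- p2
    P[, model$observed[1]] <- 1 - p2
  } else {
    pr <- predict(model$fit, X, type = "response")[, , 1, drop = FALSE]
    P[, dimnames(pr)[[2]]] <- pr[, , 1]
  }
  P
}

#' Fit a logistic model on a similarity group (KNN+LR)
#'
#' Trains the [local_model_spec()] estimator on the group members only. If
#' every member shares one outcome class the model degenerates to a constant
#' predictor for that class (so vote and LR agree); if any observed class has
#' a single member the regression cannot be estimated and the model falls
#' back to predicting the group's class proportions; a group of fewer than
#' two members falls back to the same constant/vote behaviour with a warning.
#'
#' @param group A [knn_neighbors()] / [threshold_neighbors()] group.
#' @param psn The [build_psn()] the group was drawn from (supplies features
#'   and outcomes of the members).
#' @param spec A [local_model_spec()].
#' @return A fitted `psn_local_model`.
#' @export
fit_local_model <- function(group, psn, spec = local_model_spec()) {
  ids <- group$members$patient_id
  if (length(ids) == 0) psn_abort("empty similarity group", "psn_prediction_error")
  if (length(ids) < 2) warn("similarity group has < 2 members; falling back to a constant (vote) model")
  rows <- psn$cohort[match(ids, psn$cohort$patient_id), ]
  y <- target_values(rows, spec$target)
  X <- model_matrix_for(psn, rows, spec$features)
  fit_lr(X, y, spec)
}

#' Fit the size-matched random baseline (k-Random+LR)
#'
#' Same estimator as [fit_local_model()], trained on `k` patients sampled
#' uniformly without replacement from the cohort (excluding the index), so
#' the only difference from KNN+LR is how the training set was chosen.
#'
#' @param k Sample size (matches the similarity-group size).
#' @param psn A [build_psn()] object.
#' @param spec A [local_model_spec()] (its `seed` drives the sampling).
#' @param exclude Patient id(s) excluded from sampling (the index).
#' @return A fitted `psn_local_model` with the sampled ids in `$sample_ids`.
#' @export
fit_random_baseline <- function(k, psn, spec = local_model_spec(), exclude = NULL) {
  pool <- setdiff(psn$ids, exclude)
  if (k > length(pool)) psn_abort("k exceeds available cohort size", "psn_precondition_error")
  ids <- with_seed(spec$seed, sort(sample(pool, k)))
  rows <- psn$cohort[match(ids, psn$cohort$patient_id), ]
  y <- target_values(rows, spec$target)
  X <- model_matrix_for(psn, rows, spec$features)
  model <- fit_lr(X, y, spec)
  model$sample_ids <- ids
  model
}

criterion_group <- function(psn, index, criterion) {
  if (!is.null(criterion$k)) return(knn_neighbors(psn, index, criterion$k))
  if (!is.null(criterion$threshold)) return(threshold_neighbors(psn, index, criterion$threshold))
  psn_abort("criterion must supply k or threshold", "psn_config_error")
}

#' End-to-end prediction for one index patient
#'
#' Computes the index patient's distances to all training patients with the
#' training-fitted transforms, forms the similarity group under the given
#' criterion, and predicts by neighbourhood vote, by a logistic model trained
#' on the group (KNN+LR), or by the size-matched random baseline
#' (k-Random+LR). The index patient's own outcome is never read.
#'
#' @param psn A [build_psn()] object.
#' @param index A one-row cohort tibble (unseen patient) or a `patient_id`
#'   on the map (then excluded from its own group).
#' @param method `"vote"`, `"knn_lr"` or `"random_lr"`.
#' @param criterion List with `k` or `threshold`.
#' @param spec A [local_model_spec()] (task, regularisation, baseline seed).
#' @return One-row tibble: `index_id`, `task`, `method`, `label`, `score`
#'   (positive-class probability for the binary task), list-column `scores`
#'   (per-class probabilities), `group_size`, `criterion`.
#' @export
predict_case <- function(psn, index, method = c("vote", "knn_lr", "random_lr"),
                         criterion = list(k = 20), spec = local_model_spec()) {
  method <- match.arg(method)
  group <- criterion_group(psn, index, criterion)
  row <- if (is.character(index)) {
    psn$cohort[match(index, psn$cohort$patient_id), ]
  } else {
    as_tibble(index)
  }
  predict_from_group(psn, group, row, method, spec)
}

# Prediction given an already-formed similarity group; shared by
# predict_case() and the batched test-set path in run_benchmark().
predict_from_group <- function(psn, group, index_row, method, spec) {
  if (nrow(group$members) == 0) {
    psn_abort("empty similarity group: widen k or the threshold", "psn_prediction_error")
  }
  classes <- if (spec$target == "complication") c("no", "yes") else VENT_CLASSES

  if (method == "vote") {
    if (spec$target == "complication") {
      v <- vote_binary(group, psn$cohort)
      label <- ifelse(v$label, "yes", "no")
      scores <- c(no = 1 - v$score, yes = v$score)
    } else {
      prev <- bin_ventilation(psn$cohort$ventilation_hours)
      v <- vote_multiclass(group, psn$cohort, classes = VENT_CLASSES, prevalence = prev)
      label <- v$label
      scores <- v$scores
    }
  } else {
    model <- if (method == "knn_lr") {
      fit_local_model(group, psn, spec)
    } else {
      fit_random_baseline(nrow(group$members), psn, spec, exclude = group$index_id)
    }
    P <- predict_prob(model, model_matrix_for(psn, index_row, spec$features))[1, ]
    scores <- P
    label <- classes[which.max(P)]
  }
  tibble(
    index_id = group$index_id,
    task = spec$target,
    method = method,
    label = label,
    score = if (spec$target == "complication") unname(scores[["yes"]]) else unname(max(scores)),
    scores = list(scores),
    group_size = nrow(group$members),
    criterion = paste0(group$criterion$type, "=", group$criterion$value)
  )
}
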