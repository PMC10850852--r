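VENT_CLASSES <- c("I", "II", "III", "IV")

new_group <- function(index_id, member_ids, distances, criterion) {
  structure(
    list(index_id = index_id,
         members = tibble(patient_id = member_ids, distance = distances),
         criterion = criterion),
    class = "psn_group"
  )
}

#' @export
print.psn_group <- function(x, ...) {
  crit <- paste0(x$criterion$type, "=", x$criterion$value)
  cat("<psn_group> index '", x$index_id, "', ", nrow(x$members),
      " member(s), criterion ", crit, "\n", sep = "")
  invisible(x)
}

#' @method tidy psn_group
#' @export
tidy.psn_group <- function(x, ...) {
  mutate(x$members, index_id = x$index_id, .before = 1)
}

# Distances from an index to the training patients of a psn. `index` is
# either a patient_id already on the map (self excluded) or a one-row cohort
# tibble for an unseen patient (transformed with training statistics).
index_distances <- function(psn, index) {
  if (is.character(index) && length(index) == 1) {
    if (!index %in% psn$ids) {
      psn_abort(paste0("unknown patient_id: ", index), "psn_reference_error")
    }
    d <- psn$values[index, ]
    list(index_id = index, ids = setdiff(psn$ids, index),
         d = d[setdiff(psn$ids, index)])
  } else {
    index <- as_tibble(index)
    if (nrow(index) != 1) psn_abort("index must be a single patient", "psn_precondition_error")
    cd <- cross_distances(psn, index)
    list(index_id = as.character(index$patient_id), ids = psn$ids, d = cd$values[1, ])
  }
}

#' k-nearest-neighbour similarity group
#'
#' The `k` training patients closest to the index under the fused distance.
#' Ties at the k-th distance are broken by ascending patient id, so the group
#' is deterministic.
#'
#' @param psn A [build_psn()] object.
#' @param index A `patient_id` on the map (self excluded) or a one-row cohort
#'   tibble for an unseen patient.
#' @param k Number of neighbours (`k > n` is clamped with a warning).
#' @return A `psn_group`: index id, members sorted by ascending distance,
#'   and the criterion used.
#' @export
knn_neighbors <- function(psn, index, k) {
  if (!is.numeric(k) || length(k) != 1 || k < 1 || k != floor(k)) {
    psn_abort("k must be a positive integer", "psn_precondition_error")
  }
  di <- index_distances(psn, index)
  if (k > length(di$ids)) {
    warn(paste0("k = ", k, " exceeds cohort size; using all ", length(di$ids), " patients"))
    k <- length(di$ids)
  }
  ord <- order(di$d, di$ids)
  sel <- ord[seq_len(k)]
  new_group(di$index_id, di$ids[sel], unname(di$d[sel]), list(type = "k", value = k))
}

#' Threshold similarity group
#'
#' All training patients whose fused distance to the index is at most `t`;
#' may be empty (the interactive workflow then widens the threshold).
#'
#' @inheritParams knn_neighbors
#' @param t Distance threshold in `[0, 1]`.
#' @return A `psn_group`, members sorted by ascending distance.
#' @export
threshold_neighbors <- function(psn, index, t) {
  if (!is.numeric(t) || length(t) != 1 || t < 0 || t > 1) {
    psn_abort("threshold must be in [0, 1]", "psn_precondition_error")
  }
  di <- index_distances(psn, index)
  keep <- which(di$d <= t)
  ord <- keep[order(di$d[keep], di$ids[keep])]
  new_group(di$index_id, di$ids[ord], unname(di$d[ord]), list(type = "threshold", value = t))
}

member_outcomes <- function(group, outcomes, column) {
  if (is.data.frame(outcomes)) {
    v <- setNames(outcomes[[column]], outcomes$patient_id)
  } else {
    v <- outcomes
  }
  miss <- setdiff(group$members$patient_id, names(v))
  if (length(miss) > 0) {
    psn_abort(paste0("no outcome for member(s): ", paste(head(miss, 3), collapse = ", ")),
              "psn_prediction_error")
  }
  out <- v[group$members$patient_id]
  if (anyNA(out)) psn_abort("missing outcome among group members", "psn_prediction_error")
  out
}

#' Majority-vote binary prediction from a similarity group
#'
#' The score is the fraction of group members with the event; the label is
#' positive only if strictly more than 50% of members had it (an exact split
#' votes negative).
#'
#' @param group A [knn_neighbors()] / [threshold_neighbors()] group.
#' @param outcomes Cohort tibble (uses the `complication` column by default)
#'   or a named logical vector keyed by `patient_id`.
#' @param column Outcome column when `outcomes` is a data frame.
#' @return List with `label` (logical) and `score` (proportion in `[0, 1]`).
#' @export
vote_binary <- function(group, outcomes, column = "complication") {
  if (nrow(group$members) == 0) {
    psn_abort("empty similarity group: widen k or the threshold", "psn_prediction_error")
  }
  v <- as.logical(member_outcomes(group, outcomes, column))
  score <- mean(v)
  list(label = score > 0.5, score = score)
}

#' Plurality-vote multiclass prediction from a similarity group
#'
#' Scores are the per-class member proportions (summing to 1); the label is
#' the argmax. Ties go to the class more prevalent in the full training
#' cohort, then to the lower class index.
#'
#' @inheritParams vote_binary
#' @param classes Ordered class labels (default ventilation classes I-IV).
#' @param prevalence Optional full-cohort outcome vector (or named class
#'   counts) used for tie-breaking.
#' @param column Outcome column when `outcomes` is a data frame.
#' @return List with `label` and named `scores`.
#' @export
vote_multiclass <- function(group, outcomes, classes = VENT_CLASSES,
                            prevalence = NULL, column = "ventilation_class") {
  if (nrow(group$members) == 0) {
    psn_abort("empty similarity group: widen k or the threshold", "psn_prediction_error")
  }
  if (is.data.frame(outcomes) && !column %in% names(outcomes) &&
      "ventilation_hours" %in% names(outcomes)) {
    outcomes <- mutate(outcomes,
                       ventilation_class = as.character(bin_ventilation(.data$ventilation_hours)))
  }
  v <- as.character(member_outcomes(group, outcomes, column))
  scores <- map_dbl(classes, ~ mean(v == .x))
  names(scores) <- classes
  prev <- rep(0, length(classes))
  if (!is.null(prevalence)) {
    if (is.null(names(prevalence)) || is.character(prevalence) || is.factor(prevalence)) {
      tabp <- table(factor(as.character(prevalence), levels = classes))
      prev <- as.numeric(tabp)
    } else {
      prev <- as.numeric(prevalence[classes])
      prev[is.na(prev)] <- 0
    }
  }
  # argmax with ties broken by cohort prevalence, then class order
  ord <- order(-scores, -prev, seq_along(classes))
  list(label = classes[ord[1]], scores = scores)
}

#' Bin mechanical ventilation duration into the four reporting classes
#'
#' Half-open bins: `[0, 12) -> I`, `[12, 24) -> II`, `[24, 48) -> III`,
#' `[48, Inf) -> IV`.
#'
#' @param hours Non-negative numeric vector of ventilation hours.
#' @return Factor with levels `I`-`IV`.
#' @export
bin_ventilation <- function(hours) {
  if (any(is.na(hours)) || any(hours < 0)) {
    psn_abort("ventilation hours must be non-negative and non-missing",
              "psn_precondition_error")
  }
  cut(hours, breaks = c(0, 12, 24, 48, Inf), labels = VENT_CLASSES,
      right = FALSE, include.lowest = TRUE)
}
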