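GROUPS <- c("indicator", "diag", "pre", "surg")

#' Feature-group weights for the fused patient distance
#'
#' The patient distance is the weighted combination of four group distances -
#' echo indicators, diagnoses, preoperative clinical features and surgical
#' features - normalised by the sum of active weights so it stays in
#' `[0, 1]`. Weights are the clinician-adjustable dial of the method.
#'
#' @param indicator,diag,pre,surg Non-negative weights (default equal).
#' @return Named numeric vector of class `psn_weights`.
#' @export
weight_vector <- function(indicator = 1, diag = 1, pre = 1, surg = 1) {
  w <- c(indicator = indicator, diag = diag, pre = pre, surg = surg)
  if (any(!is.finite(w)) || any(w < 0)) {
    psn_abort("weights must be finite and non-negative", "psn_config_error")
  }
  if (sum(w) == 0) psn_abort("at least one weight must be positive", "psn_config_error")
  structure(w, class = c("psn_weights", "numeric"))
}

as_weights <- function(w) {
  if (inherits(w, "psn_weights")) return(w)
  if (is.numeric(w) && !is.null(names(w))) {
    return(do.call(weight_vector, as.list(w[GROUPS])))
  }
  if (is.list(w)) return(do.call(weight_vector, w[GROUPS]))
  psn_abort("cannot interpret weights; use weight_vector()", "psn_config_error")
}

#' Fuse the four group distances into one patient distance
#'
#' `d = (w_ind * d_ind + w_diag * d_diag + w_pre * d_pre + w_surg * d_surg) /
#' sum(active weights)`. A component may be `NULL` only if its weight is 0.
#' Inputs may be scalars or conformable matrices.
#'
#' @param d_indicator,d_diag,d_pre,d_surg Group distances in `[0, 1]`
#'   (scalar or matrix), or `NULL` for an inactive group.
#' @param weights A [weight_vector()].
#' @return Fused distance(s) in `[0, 1]`.
#' @export
fuse_distances <- function(d_indicator = NULL, d_diag = NULL, d_pre = NULL,
                           d_surg = NULL, weights = weight_vector()) {
  weights <- as_weights(weights)
  comps <- list(indicator = d_indicator, diag = d_diag, pre = d_pre, surg = d_surg)
  active <- weights > 0
  for (g in GROUPS[active]) {
    if (is.null(comps[[g]])) {
      psn_abort(paste0("weight on missing component: ", g), "psn_config_error")
    }
  }
  if (!any(active)) psn_abort("all weights are zero", "psn_config_error")
  num <- 0
  for (g in GROUPS[active]) num <- num + weights[[g]] * comps[[g]]
  num / sum(weights[active])
}

phase_mask <- function(phase) {
  switch(phase,
    screening = c(indicator = 0, diag = 1, pre = 0, surg = 0),
    echo      = c(indicator = 1, diag = 1, pre = 0, surg = 0),
    patient   = c(indicator = 1, diag = 1, pre = 1, surg = 0),
    surgery   = c(indicator = 1, diag = 1, pre = 1, surg = 1),
    psn_abort(paste0("unknown phase: ", phase), "psn_config_error")
  )
}

#' Build a patient similarity network (fused distance matrix) from a cohort
#'
#' Runs the full distance pipeline: fits the indicator preprocessing
#' transform and the clinical/surgical range scaling on the cohort, computes
#' the four per-group pairwise distance matrices, and fuses them with the
#' given weights. Per-group matrices are retained so the map can be re-fused
#' under new weights ([reweight()]) or restricted to a clinical phase
#' ([phase_submap()]) without recomputing distances.
#'
#' @param cohort Range-filtered cohort tibble (see [range_filter()]).
#' @param onto A [ontology()] for the diagnosis distance.
#' @param schema An [indicator_schema()].
#' @param method Indicator preprocessing: `"origin"`, `"zscore"`, `"combination"`.
#' @param mode Diagnosis-list mode: `"ungrade"` or `"grade"`.
#' @param weights A [weight_vector()] (default equal weights).
#' @param alpha Primary-diagnosis weight in grade mode.
#' @param phase Clinical phase restricting the active groups
#'   (`"screening"`, `"echo"`, `"patient"`, `"surgery"` = all groups).
#' @return An object of class `psn`: `$ids`, `$values` (fused symmetric
#'   matrix), `$components` (per-group matrices), fitted `$transform` and
#'   `$scaling`, and the run configuration.
#' @export
build_psn <- function(cohort, onto, schema,
                      method = c("origin", "zscore", "combination"),
                      mode = c("ungrade", "grade"),
                      weights = weight_vector(), alpha = 0.7,
                      phase = "surgery") {
  method <- match.arg(method)
  mode <- match.arg(mode)
  weights <- as_weights(weights)
  cohort <- as_tibble(cohort)
  if (nrow(cohort) < 2) psn_abort("need at least 2 patients", "psn_precondition_error")
  if (anyDuplicated(cohort$patient_id)) {
    psn_abort("duplicate patient_id in cohort", "psn_precondition_error")
  }
  transform <- fit_preprocessor(cohort, schema, method)
  features <- apply_preprocessor(transform, cohort)
  scaling <- fit_scaling(cohort)
  ids <- as.character(cohort$patient_id)
  components <- list(
    indicator = indicator_distance_matrix(features, transform),
    diag = diagnosis_distance_matrix(cohort$diagnoses, onto, mode = mode, alpha = alpha),
    pre = clinical_distance_matrix(cohort, scaling),
    surg = surgical_distance_matrix(cohort, scaling)
  )
  components <- map(components, function(m) {
    dimnames(m) <- list(ids, ids)
    m
  })
  obj <- structure(
    list(ids = ids, values = NULL, components = components,
         weights = weights, phase = NULL,
         cohort = cohort, onto = onto, schema = schema,
         transform = transform, features = features, scaling = scaling,
         method = method, mode = mode, alpha = alpha),
    class = "psn"
  )
  phase_submap(obj, phase)
}

refuse_matrix <- function(components, weights) {
  do.call(fuse_distances, c(
    setNames(map(GROUPS, function(g) components[[g]]),
             paste0("d_", c("indicator", "diag", "pre", "surg"))),
    list(weights = weights)
  ))
}

#' Re-fuse a patient similarity network under new weights
#'
#' Uses the cached per-group matrices, so this is instant - the interactive
#' re-weighting workflow.
#'
#' @param psn A [build_psn()] object.
#' @param weights New [weight_vector()].
#' @return The `psn` with refused `$values`.
#' @export
reweight <- function(psn, weights) {
  weights <- as_weights(weights)
  psn$weights <- weights
  mask <- phase_mask(psn$phase %||% "surgery")
  eff <- weight_vector(indicator = weights[["indicator"]] * mask[["indicator"]],
                       diag = weights[["diag"]] * mask[["diag"]],
                       pre = weights[["pre"]] * mask[["pre"]],
                       surg = weights[["surg"]] * mask[["surg"]])
  psn$values <- refuse_matrix(psn$components, eff)
  psn
}

#' Restrict a similarity network to a clinical phase
#'
#' Each phase zeroes the weights of feature groups not yet available:
#' `screening` uses diagnoses only, `echo` adds the indicators, `patient`
#' adds the preoperative clinical features, and `surgery` uses all four.
#'
#' @param psn A [build_psn()] object.
#' @param phase `"screening"`, `"echo"`, `"patient"` or `"surgery"`.
#' @return The `psn` refused for that phase.
#' @export
phase_submap <- function(psn, phase = c("surgery", "screening", "echo", "patient")) {
  phase <- match.arg(phase)
  mask <- phase_mask(phase)
  if (mask[["indicator"]] > 0 && length(psn$transform$features) == 0 &&
      phase != "surgery") {
    psn_abort(paste0("phase '", phase, "' needs echo indicators but the cohort has none"),
              "psn_data_error")
  }
  psn$phase <- phase
  reweight(psn, psn$weights)
}

#' @export
print.psn <- function(x, ...) {
  cat("<psn> ", length(x$ids), " patients | phase ", x$phase,
      " | preprocessing ", x$method, " | diagnosis mode ", x$mode, "\n", sep = "")
  cat("  weights:", paste(GROUPS, round(as.numeric(x$weights), 3),
                          sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Tidy a patient similarity network into a long pair table
#'
#' @param x A [build_psn()] object.
#' @param ... Unused.
#' @return Tibble with one row per unordered patient pair: `id_a`, `id_b`,
#'   `distance`, and the four component distances.
#' @method tidy psn
#' @export
tidy.psn <- function(x, ...) {
  n <- length(x$ids)
  idx <- which(upper.tri(x$values), arr.ind = TRUE)
  tibble(
    id_a = x$ids[idx[, 1]],
    id_b = x$ids[idx[, 2]],
    distance = x$values[idx],
    d_indicator = x$components$indicator[idx],
    d_diag = x$components$diag[idx],
    d_pre = x$components$pre[idx],
    d_surg = x$components$surg[idx]
  )
}

#' One-row summary of a similarity network
#'
#' @inheritParams tidy.psn
#' @return Tibble with cohort size, configuration and distance summaries.
#' @method glance psn
#' @export
glance.psn <- function(x, ...) {
  off <- x$values[upper.tri(x$values)]
  tibble(
    n_patients = length(x$ids), phase = x$phase, method = x$method,
    mode = x$mode, mean_distance = mean(off), median_distance = stats::median(off)
  )
}

# Distances from unseen (index) patients to every training patient, using
# the training-fitted transform and scaling only.
cross_distances <- function(psn, new_cohort) {
  new_cohort <- as_tibble(new_cohort)
  feats <- apply_preprocessor(psn$transform, new_cohort)
  comp <- list(
    indicator = indicator_distance_cross(feats, psn$features, psn$transform),
    diag = diagnosis_distance_cross(new_cohort$diagnoses, psn$cohort$diagnoses,
                                    psn$onto, mode = psn$mode, alpha = psn$alpha),
    pre = gower_core(clinical_matrix(new_cohort), clinical_matrix(psn$cohort),
                     clinical_ranges(psn$scaling)),
    surg = gower_core(surgical_matrix(new_cohort), surgical_matrix(psn$cohort),
                      ranges_vec(psn$scaling$surgical, SURGICAL_NUM))
  )
  comp <- map(comp, function(m) {
    dimnames(m) <- list(new_cohort$patient_id, psn$ids)
    m
  })
  mask <- phase_mask(psn$phase %||% "surgery")
  eff <- weight_vector(indicator = psn$weights[["indicator"]] * mask[["indicator"]],
                       diag = psn$weights[["diag"]] * mask[["diag"]],
                       pre = psn$weights[["pre"]] * mask[["pre"]],
                       surg = psn$weights[["surg"]] * mask[["surg"]])
  list(values = refuse_matrix(comp, eff), components = comp)
}

#' Write / read a distance matrix as TSV
#'
#' Header row and first column carry patient ids.
#'
#' @param psn A [build_psn()] object (or a plain matrix with dimnames).
#' @param path Output path.
#' @export
write_distance_tsv <- function(psn, path) {
  m <- if (inherits(psn, "psn")) psn$values else psn
  df <- data.frame(patient_id = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_distance_tsv
#' @export
read_distance_tsv <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}
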