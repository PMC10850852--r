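# Core (non-indicator) cohort columns; anything else is an echo indicator.
CORE_COLS <- c(
  "patient_id", "sex", "age_months", "height_cm", "weight_kg", "preop_spo2_pct",
  "surgery_min", "cpb_min", "clamp_min",
  "complication", "ventilation_hours", "icu_los_days", "hospital_los_days",
  "survived", "diagnoses"
)
CLINICAL_NUM <- c("age_months", "height_cm", "weight_kg", "preop_spo2_pct")
SURGICAL_NUM <- c("surgery_min", "cpb_min", "clamp_min")

indicator_cols <- function(cohort) setdiff(names(cohort), CORE_COLS)

#' Define an echocardiographic indicator schema
#'
#' The schema names the quantitative indicators a cohort may carry, their
#' plausible ranges for quality control, and the configured combination-ratio
#' pairs (derived features `ratio_name = numerator / denominator`).
#'
#' @param indicators Data frame with columns `name`, `low`, `high`.
#' @param ratio_pairs Optional data frame with columns `ratio_name`,
#'   `numerator`, `denominator`; both members must be schema indicators.
#' @return An object of class `psn_schema`.
#' @export
indicator_schema <- function(indicators, ratio_pairs = NULL) {
  indicators <- as_tibble(indicators)
  stopifnot(all(c("name", "low", "high") %in% names(indicators)))
  if (any(indicators$low >= indicators$high)) {
    bad <- indicators$name[indicators$low >= indicators$high]
    psn_abort(paste0("plausible range must have low < high: ", paste(bad, collapse = ", ")),
              "psn_schema_error")
  }
  if (anyDuplicated(indicators$name)) psn_abort("duplicate indicator names", "psn_schema_error")
  if (!is.null(ratio_pairs)) {
    ratio_pairs <- as_tibble(ratio_pairs)
    stopifnot(all(c("ratio_name", "numerator", "denominator") %in% names(ratio_pairs)))
    miss <- setdiff(c(ratio_pairs$numerator, ratio_pairs$denominator), indicators$name)
    if (length(miss) > 0) {
      psn_abort(paste0("ratio pair member not in schema: ", paste(miss, collapse = ", ")),
                "psn_schema_error")
    }
  } else {
    ratio_pairs <- tibble(ratio_name = character(), numerator = character(),
                          denominator = character())
  }
  structure(list(indicators = indicators, ratio_pairs = ratio_pairs),
            class = "psn_schema")
}

#' @export
print.psn_schema <- function(x, ...) {
  cat("<psn_schema> ", nrow(x$indicators), " indicators, ",
      nrow(x$ratio_pairs), " ratio pairs\n", sep = "")
  invisible(x)
}

check_schema_covers <- function(cohort, schema) {
  extra <- setdiff(indicator_cols(cohort), schema$indicators$name)
  if (length(extra) > 0) {
    psn_abort(paste0("indicator(s) absent from schema: ", paste(extra, collapse = ", ")),
              "psn_schema_error")
  }
  invisible(TRUE)
}

#' Quality-filter indicator values against their plausible ranges
#'
#' Automatically extracted echo measurements can carry gross errors; any value
#' outside its schema range is treated as implausible. Under
#' `policy = "null"` the value is set missing; under `policy = "drop"` the
#' whole patient record is removed. Missing values are never flagged.
#'
#' @param cohort Cohort tibble (indicators as columns).
#' @param schema An [indicator_schema()].
#' @param policy `"null"` (blank the value) or `"drop"` (drop the record).
#' @return A list with `cohort` (filtered) and `report`, a tibble of every
#'   change (`patient_id`, `indicator`, `value`, `action`).
#' @export
range_filter <- function(cohort, schema, policy = c("null", "drop")) {
  policy <- match.arg(policy)
  cohort <- as_tibble(cohort)
  check_schema_covers(cohort, schema)
  cols <- indicator_cols(cohort)
  report <- list()
  bad_patients <- character()
  for (col in cols) {
    rng <- schema$indicators[schema$indicators$name == col, ]
    v <- cohort[[col]]
    out <- !is.na(v) & (v < rng$low | v > rng$high)
    if (any(out)) {
      report[[col]] <- tibble(
        patient_id = cohort$patient_id[out], indicator = col, value = v[out],
        action = if (policy == "null") "set_missing" else "record_dropped"
      )
      if (policy == "null") cohort[[col]][out] <- NA_real_
      else bad_patients <- union(bad_patients, cohort$patient_id[out])
    }
  }
  if (policy == "drop" && length(bad_patients) > 0) {
    cohort <- cohort %>% filter(!.data$patient_id %in% bad_patients)
  }
  report <- if (length(report) > 0) bind_rows(report) else
    tibble(patient_id = character(), indicator = character(),
           value = double(), action = character())
  list(cohort = cohort, report = report)
}

#' Fit an indicator preprocessing transform on a training cohort
#'
#' Three preprocessings of the echo indicator space are supported:
#' * `origin` - values pass through unchanged;
#' * `zscore` - `(x - mean) / sd` with cohort sample statistics (sd with the
#'   `n - 1` convention); a column with fewer than two observed values is left
#'   unscaled (mean 0, sd 1) and noted;
#' * `combination` - the origin table augmented with the schema's ratio
#'   columns, computed only where both members are present.
#'
#' The fitted object stores the training statistics and per-feature training
#' ranges (for distance scaling), so an unseen index patient is always
#' transformed with training statistics - no leakage.
#'
#' @param cohort Range-filtered training cohort.
#' @param schema An [indicator_schema()].
#' @param method `"origin"`, `"zscore"` or `"combination"`.
#' @return An object of class `psn_transform`.
#' @export
fit_preprocessor <- function(cohort, schema, method = c("origin", "zscore", "combination")) {
  method <- match.arg(method)
  cohort <- as_tibble(cohort)
  check_schema_covers(cohort, schema)
  cols <- intersect(schema$indicators$name, names(cohort))
  stats <- tibble(feature = cols, mean = 0, sd = 1, note = NA_character_)
  if (method == "zscore") {
    for (i in seq_along(cols)) {
      v <- cohort[[cols[i]]]
      n_obs <- sum(!is.na(v))
      if (n_obs < 2) {
        stats$note[i] <- "fewer than 2 observed values; left unscaled"
        next
      }
      s <- sd(v, na.rm = TRUE)
      if (s == 0) {
        psn_abort(paste0("zero standard deviation, cannot z-score: ", cols[i]),
                  "psn_transform_error")
      }
      stats$mean[i] <- mean(v, na.rm = TRUE)
      stats$sd[i] <- s
    }
  }
  tr <- structure(
    list(method = method, schema = schema, features = NULL, stats = stats,
         ranges = NULL, impute = NULL),
    class = "psn_transform"
  )
  feat <- apply_preprocessor(tr, cohort)
  fcols <- setdiff(names(feat), "patient_id")
  tr$features <- fcols
  tr$ranges <- tibble(
    feature = fcols,
    min = map_dbl(fcols, ~ suppressWarnings(min(feat[[.x]], na.rm = TRUE))),
    max = map_dbl(fcols, ~ suppressWarnings(max(feat[[.x]], na.rm = TRUE)))
  ) %>%
    mutate(min = ifelse(is.finite(.data$min), .data$min, NA_real_),
           max = ifelse(is.finite(.data$max), .data$max, NA_real_))
  tr$impute <- map_dbl(fcols, function(f) {
    m <- mean(feat[[f]], na.rm = TRUE)
    if (is.nan(m)) 0 else m
  }) %>% setNames(fcols)
  tr
}

#' @export
print.psn_transform <- function(x, ...) {
  cat("<psn_transform> method '", x$method, "', ", length(x$features),
      " feature(s)\n", sep = "")
  invisible(x)
}

#' Apply a fitted preprocessing transform
#'
#' @param transform A [fit_preprocessor()] object.
#' @param cohort Cohort tibble (training or unseen records).
#' @return Tibble of `patient_id` plus one column per transformed feature;
#'   ratios with a zero denominator are set missing and recorded in the
#'   `"notes"` attribute.
#' @export
apply_preprocessor <- function(transform, cohort) {
  cohort <- as_tibble(cohort)
  base_cols <- intersect(transform$schema$indicators$name, names(cohort))
  out <- tibble(patient_id = as.character(cohort$patient_id))
  notes <- character()
  for (col in base_cols) {
    v <- as.numeric(cohort[[col]])
    if (transform$method == "zscore") {
      st <- transform$stats[transform$stats$feature == col, ]
      if (nrow(st) == 1) v <- (v - st$mean) / st$sd
    }
    out[[col]] <- v
  }
  if (transform$method == "combination") {
    rp <- transform$schema$ratio_pairs
    for (i in seq_len(nrow(rp))) {
      num <- cohort[[rp$numerator[i]]]
      den <- cohort[[rp$denominator[i]]]
      if (is.null(num) || is.null(den)) {
        out[[rp$ratio_name[i]]] <- NA_real_
        next
      }
      zero <- !is.na(den) & den == 0
      if (any(zero)) {
        notes <- c(notes, paste0("zero denominator for ", rp$ratio_name[i], " in ",
                                 paste(cohort$patient_id[zero], collapse = ", "),
                                 "; ratio set missing"))
        den[zero] <- NA_real_
      }
      out[[rp$ratio_name[i]]] <- as.numeric(num) / as.numeric(den)
    }
  }
  # features fitted but absent in this table come back all-missing
  for (f in setdiff(transform$features, names(out))) out[[f]] <- NA_real_
  if (!is.null(transform$features)) {
    out <- out[, c("patient_id", transform$features), drop = FALSE]
  }
  attr(out, "notes") <- notes
  out
}

#' One-step indicator preprocessing
#'
#' Convenience wrapper: fits the transform on `cohort` and applies it, with
#' the fitted [fit_preprocessor()] object in the `"transform"` attribute so it
#' can be reused on unseen index patients.
#'
#' @inheritParams fit_preprocessor
#' @return Feature tibble with a `"transform"` attribute.
#' @export
preprocess_indicators <- function(cohort, schema, method = c("origin", "zscore", "combination")) {
  tr <- fit_preprocessor(cohort, schema, method)
  feat <- apply_preprocessor(tr, cohort)
  attr(feat, "transform") <- tr
  feat
}

# ---- Gower-style distance core -------------------------------------------

# Pairwise mean of range-normalised absolute differences over features
# observed in BOTH rows; no shared feature -> distance 1; a zero-range shared
# feature contributes 0 if equal, 1 otherwise.
gower_core <- function(Xa, Xb, ranges) {
  na_ <- nrow(Xa); nb_ <- nrow(Xb)
  S <- matrix(0, na_, nb_)
  Cnt <- matrix(0L, na_, nb_)
  for (f in seq_len(ncol(Xa))) {
    xa <- Xa[, f]; xb <- Xb[, f]
    oa <- !is.na(xa); ob <- !is.na(xb)
    if (!any(oa) || !any(ob)) next
    obs <- outer(oa, ob, "&")
    D <- abs(outer(xa, xb, "-"))
    r <- ranges[f]
    Dv <- if (is.na(r) || r == 0) (D > 0) + 0 else pmin(D / r, 1)
    Dv[!obs] <- 0
    S <- S + Dv
    Cnt <- Cnt + obs
  }
  out <- S / Cnt
  out[Cnt == 0] <- 1
  out
}

feature_matrix <- function(feat, features) {
  m <- as.matrix(feat[, features, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- feat$patient_id
  m
}

ranges_vec <- function(ranges_tbl, features) {
  r <- ranges_tbl$max - ranges_tbl$min
  setNames(r, ranges_tbl$feature)[features]
}

#' Distance between two preprocessed indicator rows
#'
#' Gower-style mean of per-feature normalised absolute differences
#' `|x_f - y_f| / range_f` (clipped to 1), averaged over the features observed
#' in both rows; 1 if no feature is shared.
#'
#' @param x,y Single-row feature tibbles from the same fitted transform (or
#'   named numeric vectors).
#' @param transform The [fit_preprocessor()] object supplying feature ranges.
#' @return Distance in `[0, 1]`.
#' @export
indicator_distance <- function(x, y, transform) {
  to_row <- function(z) {
    if (is.data.frame(z)) z <- unlist(z[1, intersect(transform$features, names(z)), drop = FALSE])
    full <- setNames(rep(NA_real_, length(transform$features)), transform$features)
    full[names(z)] <- as.numeric(z)
    matrix(full, nrow = 1, dimnames = list(NULL, transform$features))
  }
  gower_core(to_row(x), to_row(y), ranges_vec(transform$ranges, transform$features))[1, 1]
}

indicator_distance_matrix <- function(feat, transform) {
  X <- feature_matrix(feat, transform$features)
  d <- gower_core(X, X, ranges_vec(transform$ranges, transform$features))
  diag(d) <- 0
  dimnames(d) <- list(feat$patient_id, feat$patient_id)
  d
}

indicator_distance_cross <- function(feat_q, feat_r, transform) {
  rv <- ranges_vec(transform$ranges, transform$features)
  gower_core(feature_matrix(feat_q, transform$features),
             feature_matrix(feat_r, transform$features), rv)
}

# ---- Clinical / surgical group distances ---------------------------------

#' Fit range scaling for the clinical and surgical feature groups
#'
#' Records per-feature training-cohort ranges used to normalise the
#' preoperative clinical distance (age, height, weight, oxygen saturation,
#' sex) and the surgical distance (surgery, bypass and cross-clamp times).
#'
#' @param cohort Training cohort tibble.
#' @return An object of class `psn_scaling`.
#' @export
fit_scaling <- function(cohort) {
  rng <- function(cols) {
    tibble(feature = cols,
           min = map_dbl(cols, ~ suppressWarnings(min(cohort[[.x]], na.rm = TRUE))),
           max = map_dbl(cols, ~ suppressWarnings(max(cohort[[.x]], na.rm = TRUE)))) %>%
      mutate(min = ifelse(is.finite(.data$min), .data$min, NA_real_),
             max = ifelse(is.finite(.data$max), .data$max, NA_real_))
  }
  structure(list(clinical = rng(CLINICAL_NUM), surgical = rng(SURGICAL_NUM)),
            class = "psn_scaling")
}

clinical_matrix <- function(cohort) {
  m <- cbind(as.matrix(cohort[, CLINICAL_NUM]),
             sex_male = as.numeric(cohort$sex == "male"))
  storage.mode(m) <- "double"
  rownames(m) <- cohort$patient_id
  m
}

clinical_ranges <- function(scaling) {
  c(ranges_vec(scaling$clinical, CLINICAL_NUM), sex_male = 1)
}

surgical_matrix <- function(cohort) {
  m <- as.matrix(cohort[, SURGICAL_NUM])
  storage.mode(m) <- "double"
  rownames(m) <- cohort$patient_id
  m
}

#' Preoperative clinical distance between two patients
#'
#' Gower mean over age, height, weight and preoperative oxygen saturation
#' (range-normalised absolute differences) plus sex (0 if equal, else 1).
#'
#' @param a,b Single-row cohort tibbles.
#' @param scaling A [fit_scaling()] object.
#' @return Distance in `[0, 1]`.
#' @export
clinical_distance <- function(a, b, scaling) {
  gower_core(clinical_matrix(as_tibble(a)), clinical_matrix(as_tibble(b)),
             clinical_ranges(scaling))[1, 1]
}

#' Surgical distance between two patients
#'
#' Gower mean over surgery, cardiopulmonary-bypass and aortic cross-clamp
#' durations, range-normalised on the training cohort.
#'
#' @inheritParams clinical_distance
#' @return Distance in `[0, 1]`.
#' @export
surgical_distance <- function(a, b, scaling) {
  gower_core(surgical_matrix(as_tibble(a)), surgical_matrix(as_tibble(b)),
             ranges_vec(scaling$surgical, SURGICAL_NUM))[1, 1]
}

clinical_distance_matrix <- function(cohort, scaling) {
  X <- clinical_matrix(cohort)
  d <- gower_core(X, X, clinical_ranges(scaling))
  diag(d) <- 0
  d
}

surgical_distance_matrix <- function(cohort, scaling) {
  X <- surgical_matrix(cohort)
  d <- gower_core(X, X, ranges_vec(scaling$surgical, SURGICAL_NUM))
  diag(d) <- 0
  d
}
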