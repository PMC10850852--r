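#' Default lesion mixture for the synthetic cohort
#'
#' Six diagnostic labels with prevalences of the order seen in large surgical
#' CHD cohorts (septal defects dominate), a severity shift per lesion, and
#' the ontology terms emitted for each label (primary term flagged `*`).
#'
#' @return Tibble: `label`, `prevalence`, `severity_shift`, `terms`.
#' @export
default_lesion_mix <- function() {
  tibble(
    label = c("ASD+VSD", "VSD", "ASD", "PFO", "PDA", "others"),
    prevalence = c(0.348, 0.319, 0.257, 0.028, 0.026, 0.022),
    severity_shift = c(0.3, 0.1, -0.2, -0.6, -0.3, 0.8),
    terms = c("VSD*;ASD", "VSD*", "ASD*", "PFO*", "PDA*", "TOF*")
  )
}

#' Default echocardiographic indicator schema for the synthetic cohort
#'
#' Four routine cardiac-structure indicators observed for every patient plus
#' lesion-specific measurements (defect sizes, shunt velocities, pressure
#' gradients) observed only when the lesion is present, with physiologically
#' plausible quality-control ranges and the combination-ratio pairs (defect
#' size over the aortic annulus, pulmonary artery over aorta).
#'
#' @return An [indicator_schema()].
#' @export
default_indicator_schema <- function() {
  indicator_schema(
    indicators = tibble::tribble(
      ~name,                   ~low,  ~high,
      "lvedd_mm",                10,     70,
      "la_diameter_mm",           5,     50,
      "aortic_annulus_mm",        4,     30,
      "pa_diameter_mm",           4,     40,
      "vsd_diameter_mm",          1,     30,
      "vsd_shunt_velocity_ms",  0.5,      7,
      "vsd_gradient_mmhg",        1,    150,
      "asd_diameter_mm",          1,     40,
      "asd_shunt_velocity_ms",  0.2,      4,
      "pfo_diameter_mm",        0.3,     10,
      "pda_diameter_mm",        0.5,     15,
      "pda_shunt_velocity_ms",  0.5,      6,
      "rvot_gradient_mmhg",       5,    150,
      "aorta_override_pct",       5,     95
    ),
    ratio_pairs = tibble::tribble(
      ~ratio_name,       ~numerator,        ~denominator,
      "vsd_aorta_ratio", "vsd_diameter_mm", "aortic_annulus_mm",
      "asd_aorta_ratio", "asd_diameter_mm", "aortic_annulus_mm",
      "pda_aorta_ratio", "pda_diameter_mm", "aortic_annulus_mm",
      "pa_aorta_ratio",  "pa_diameter_mm",  "aortic_annulus_mm"
    )
  )
}

#' Specification for the synthetic surgical CHD cohort
#'
#' The generator plants the minimal statistical structure the similarity
#' method assumes: a latent per-patient severity score drives the echo
#' indicators, the surgical times and the outcomes, so that similar patients
#' (under the fused distance) have similar outcomes. Outcome signal strength
#' is controlled by `complication_slope` (log-odds of complication per
#' severity unit) and `vent_slope` (log-hours of ventilation per severity
#' unit); setting both to 0 removes the planted signal entirely.
#'
#' @param n_patients Cohort size.
#' @param seed Mandatory integer seed.
#' @param lesion_mix Tibble as [default_lesion_mix()]; prevalences may sum to
#'   less than 1 (remainder goes to the last, catch-all row).
#' @param complication_slope Severity slope on the complication logit
#'   (default 2, a strong planted signal).
#' @param complication_rate Target marginal complication rate (intercept is
#'   calibrated on the realised severities; default 0.257).
#' @param vent_slope Severity slope on log ventilation hours (default 0.9).
#' @param vent_sd Residual sd of log ventilation hours (default 0.6).
#' @param vent_short_rate Target share of ventilations under 12 h
#'   (calibrates the intercept; default 0.63).
#' @param indicator_loading Multiplier on every indicator's severity loading.
#' @param indicator_noise Multiplier on every indicator's residual sd.
#' @param dropout Uniform random missingness added on observed indicators.
#' @param secondary_rate Probability of an incidental secondary diagnosis.
#' @return An object of class `psn_synth_spec`.
#' @export
synthetic_spec <- function(n_patients = 1000, seed, lesion_mix = default_lesion_mix(),
                           complication_slope = 2, complication_rate = 0.257,
                           vent_slope = 0.9, vent_sd = 0.6, vent_short_rate = 0.63,
                           indicator_loading = 1, indicator_noise = 1,
                           dropout = 0.05, secondary_rate = 0.15) {
  if (missing(seed)) psn_abort("a seed is mandatory for the synthetic generator",
                               "psn_validation_error")
  lesion_mix <- as_tibble(lesion_mix)
  if (n_patients < 1) psn_abort("n_patients must be positive", "psn_validation_error")
  if (any(lesion_mix$prevalence < 0) || sum(lesion_mix$prevalence) > 1 + 1e-9) {
    psn_abort("lesion prevalences must be non-negative and sum to at most 1",
              "psn_validation_error")
  }
  if (vent_sd <= 0) psn_abort("vent_sd must be positive", "psn_validation_error")
  structure(
    list(n_patients = as.integer(n_patients), seed = as.integer(seed),
         lesion_mix = lesion_mix, complication_slope = complication_slope,
         complication_rate = complication_rate, vent_slope = vent_slope,
         vent_sd = vent_sd, vent_short_rate = vent_short_rate,
         indicator_loading = indicator_loading, indicator_noise = indicator_noise,
         dropout = dropout, secondary_rate = secondary_rate),
    class = "psn_synth_spec"
  )
}

#' Generate the toy diagnosis ontology
#'
#' A fixed 3-4 level hierarchy (root, lesion families, lesions, subtypes)
#' covering the common surgical CHD lesions; a stand-in for a full clinical
#' CHD ontology, sized for testing. Deterministic (the seed is accepted for
#' interface symmetry but the structure is constant).
#'
#' @param seed Ignored; the ontology is fixed.
#' @return A [ontology()] object (24 terms, root `CHD`).
#' @export
generate_toy_ontology <- function(seed = 1L) {
  edges <- tibble::tribble(
    ~child_id,            ~parent_id,
    "septal_defect",      "CHD",
    "vascular_anomaly",   "CHD",
    "conotruncal_defect", "CHD",
    "valvar_lesion",      "CHD",
    "VSD",                "septal_defect",
    "ASD",                "septal_defect",
    "PFO",                "septal_defect",
    "AVSD",               "septal_defect",
    "PDA",                "vascular_anomaly",
    "COA",                "vascular_anomaly",
    "TOF",                "conotruncal_defect",
    "TGA",                "conotruncal_defect",
    "PS",                 "valvar_lesion",
    "BAV",                "valvar_lesion",
    "VSD_perimembranous", "VSD",
    "VSD_muscular",       "VSD",
    "VSD_subarterial",    "VSD",
    "ASD_secundum",       "ASD",
    "ASD_primum",         "ASD",
    "PDA_tubular",        "PDA",
    "PDA_window",         "PDA",
    "TOF_classic",        "TOF",
    "PS_valvar",          "PS"
  )
  labels <- tibble(
    term_id = c("CHD", "VSD", "ASD", "PFO", "PDA", "TOF", "TGA"),
    label = c("congenital heart disease", "ventricular septal defect",
              "atrial septal defect", "patent foramen ovale",
              "patent ductus arteriosus", "tetralogy of Fallot",
              "transposition of the great arteries")
  )
  ontology(edges, labels = labels)
}

# Emission model: per lesion label, which indicators are observed and their
# (base, age coefficient on sqrt(age), severity loading, residual sd).
indicator_emissions <- function() {
  routine <- tibble::tribble(
    ~name,               ~base, ~age_coef, ~load, ~sd,
    "lvedd_mm",             24,      1.2,   2.0,  1.0,
    "la_diameter_mm",       14,      0.8,   1.2,  0.8,
    "aortic_annulus_mm",     8,      0.5,   0.4,  0.5,
    "pa_diameter_mm",        9,      0.5,   1.0,  0.6
  )
  lesion <- list(
    VSD = tibble::tribble(
      ~name,                   ~base, ~age_coef, ~load,  ~sd,
      "vsd_diameter_mm",           5,         0,   2.0,  1.0,
      "vsd_shunt_velocity_ms",     4,         0,  -0.4,  0.3,
      "vsd_gradient_mmhg",        64,         0, -12.0,  8.0
    ),
    ASD = tibble::tribble(
      ~name,                   ~base, ~age_coef, ~load,  ~sd,
      "asd_diameter_mm",           8,         0,   2.5,  1.2,
      "asd_shunt_velocity_ms",   1.2,         0,  0.15, 0.15
    ),
    PFO = tibble::tribble(
      ~name,               ~base, ~age_coef, ~load, ~sd,
      "pfo_diameter_mm",     2.5,         0,   0.8, 0.4
    ),
    PDA = tibble::tribble(
      ~name,                   ~base, ~age_coef, ~load,  ~sd,
      "pda_diameter_mm",         3.5,         0,   1.5,  0.6,
      "pda_shunt_velocity_ms",     4,         0,  -0.4,  0.3
    ),
    TOF = tibble::tribble(
      ~name,                  ~base, ~age_coef, ~load, ~sd,
      "rvot_gradient_mmhg",      70,         0,    15,  10,
      "aorta_override_pct",      40,         0,     8,   5
    )
  )
  list(routine = routine, lesion = lesion)
}

label_lesions <- function(label) {
  switch(label,
         "ASD+VSD" = c("VSD", "ASD"),
         "VSD" = "VSD", "ASD" = "ASD", "PFO" = "PFO", "PDA" = "PDA",
         "others" = "TOF",
         character())
}

#' Generate a synthetic surgical CHD cohort
#'
#' Samples a lesion label per patient, a latent severity score (standard
#' normal shifted by lesion), demographics from paediatric growth-curve-like
#' distributions, echo indicators emitted only for lesions actually present
#' (plus routine cardiac-structure measurements), surgical times increasing
#' in severity, and outcomes coupled to severity: complication from a
#' logistic model (intercept calibrated to the target rate on the realised
#' severities) and ventilation hours log-normal in severity (intercept
#' calibrated so the target share falls under 12 h). Primary diagnoses use
#' ontology subtype terms where available; incidental secondary diagnoses
#' are added at `secondary_rate`.
#'
#' @param spec A [synthetic_spec()].
#' @param onto A [generate_toy_ontology()] (terms must cover the lesion mix).
#' @return List with `cohort` (tibble, one row per patient) and `truth`
#'   (tibble of the latent generating state: label, severity, true outcome
#'   probabilities) - the truth table is never read by the pipeline.
#' @export
generate_cohort <- function(spec, onto = generate_toy_ontology()) {
  if (!inherits(spec, "psn_synth_spec")) psn_abort("spec must be a synthetic_spec()",
                                                   "psn_validation_error")
  em <- indicator_emissions()
  schema <- default_indicator_schema()
  mix <- spec$lesion_mix
  check_terms(onto, unlist(map(parse_diagnoses(mix$terms), "term_id")))

  with_seed(spec$seed, {
    n <- spec$n_patients
    lab_idx <- sample.int(nrow(mix), n, replace = TRUE,
                          prob = mix$prevalence / sum(mix$prevalence))
    label <- mix$label[lab_idx]
    severity <- mix$severity_shift[lab_idx] + rnorm(n)

    age <- pmin(pmax(rlnorm(n, log(12), 1.5), 0.5), 192)
    height <- pmin(pmax(52 + 6.3 * sqrt(age) * exp(rnorm(n, 0, 0.05)), 45), 185)
    weight <- 0.0025 * height^1.9 * exp(rnorm(n, 0, 0.12))
    spo2_base <- ifelse(label == "others", 90, 98)
    spo2 <- pmin(pmax(spo2_base - 0.6 * pmax(severity, 0) + rnorm(n, 0, 0.8), 60), 100)

    surgery <- exp(log(119) + 0.22 * severity + rnorm(n, 0, 0.18))
    cpb <- exp(log(60) + 0.28 * severity + rnorm(n, 0, 0.20))
    clampt <- exp(log(40) + 0.28 * severity + rnorm(n, 0, 0.22))

    # diagnosis lists: subtype as primary where the ontology has subtypes
    subtype_of <- function(lesion) {
      switch(lesion,
        VSD = sample(c("VSD_perimembranous", "VSD_muscular", "VSD_subarterial"),
                     1, prob = c(0.6, 0.3, 0.1)),
        ASD = sample(c("ASD_secundum", "ASD_primum"), 1, prob = c(0.8, 0.2)),
        lesion)
    }
    diagnoses <- vapply(seq_len(n), function(i) {
      base <- parse_diagnoses(mix$terms[match(label[i], mix$label)])[[1]]
      base$term_id <- vapply(seq_len(nrow(base)), function(j) {
        if (base$is_primary[j]) subtype_of(base$term_id[j]) else base$term_id[j]
      }, character(1))
      if (runif(1) < spec$secondary_rate) {
        extra <- setdiff(c("PFO", "PDA"), c(base$term_id, label_lesions(label[i])))
        if (length(extra) > 0) {
          base <- bind_rows(base, tibble(term_id = sample(extra, 1), is_primary = FALSE))
        }
      }
      format_diagnoses(base)
    }, character(1))

    # indicators: routine for everyone, lesion-specific when present
    ind_names <- schema$indicators$name
    X <- matrix(NA_real_, n, length(ind_names), dimnames = list(NULL, ind_names))
    emit <- function(rows, tbl) {
      for (r in seq_len(nrow(tbl))) {
        nm <- tbl$name[r]
        rng <- schema$indicators[schema$indicators$name == nm, ]
        v <- tbl$base[r] + tbl$age_coef[r] * sqrt(age[rows]) +
          tbl$load[r] * spec$indicator_loading * severity[rows] +
          rnorm(length(rows), 0, tbl$sd[r] * spec$indicator_noise)
        X[rows, nm] <<- round(pmin(pmax(v, rng$low + 0.01), rng$high - 0.01), 2)
      }
    }
    emit(seq_len(n), em$routine)
    for (les in names(em$lesion)) {
      rows <- which(vapply(label, function(l) les %in% label_lesions(l), logical(1)))
      if (length(rows) > 0) emit(rows, em$lesion[[les]])
    }
    if (spec$dropout > 0) {
      drop_mask <- matrix(runif(length(X)) < spec$dropout, nrow(X))
      X[drop_mask] <- NA_real_
    }

    # outcomes coupled to severity
    b <- spec$complication_slope
    a <- uniroot(function(a) mean(plogis(a + b * severity)) - spec$complication_rate,
                 c(-30, 30))$root
    p_comp <- plogis(a + b * severity)
    complication <- runif(n) < p_comp

    eta <- spec$vent_slope * severity + rnorm(n, 0, spec$vent_sd)
    c0 <- log(12) - as.numeric(quantile(eta, spec$vent_short_rate))
    vent_hours <- round(exp(c0 + eta), 1)

    icu <- round(exp(log(3) + 0.45 * severity + rnorm(n, 0, 0.5)), 1)
    hosp <- round(exp(log(9) + 0.30 * severity + rnorm(n, 0, 0.35)), 1)
    p_death <- plogis(-5 + 0.9 * severity)
    survived <- runif(n) >= p_death

    cohort <- tibble(
      patient_id = sprintf("P%05d", seq_len(n)),
      sex = sample(c("male", "female"), n, replace = TRUE, prob = c(0.489, 0.511)),
      age_months = round(age, 1), height_cm = round(height, 1),
      weight_kg = round(weight, 1), preop_spo2_pct = round(spo2, 1),
      surgery_min = round(surgery, 1), cpb_min = round(cpb, 1),
      clamp_min = round(clampt, 1),
      complication = complication, ventilation_hours = vent_hours,
      icu_los_days = icu, hospital_los_days = hosp, survived = survived,
      diagnoses = diagnoses
    ) %>%
      bind_cols(as_tibble(X))

    truth <- tibble(
      patient_id = cohort$patient_id, lesion_label = label, severity = severity,
      p_complication = p_comp, expected_log_vent_hours = c0 + spec$vent_slope * severity
    )
    list(cohort = cohort, truth = truth)
  })
}
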