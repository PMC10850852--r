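mini_schema <- function() {
  indicator_schema(
    indicators = data.frame(name = c("a", "b"), low = c(0, 0), high = c(10, 5)),
    ratio_pairs = data.frame(ratio_name = "r", numerator = "a", denominator = "b")
  )
}

mini_cohort <- function() {
  tibble::tibble(
    patient_id = c("p1", "p2", "p3"),
    sex = c("male", "female", "male"),
    age_months = c(12, 24, 6), height_cm = c(75, 88, 66),
    weight_kg = c(9.5, 12, 7.5), preop_spo2_pct = c(98, 97, 99),
    surgery_min = c(120, 150, 100), cpb_min = c(60, 80, 50),
    clamp_min = c(40, 55, 30),
    complication = c(FALSE, TRUE, FALSE),
    ventilation_hours = c(6, 30, 4), icu_los_days = c(2, 5, 1),
    hospital_los_days = c(8, 12, 7), survived = c(TRUE, TRUE, TRUE),
    diagnoses = c("VSD*", "ASD*", "VSD*"),
    a = c(2, 8, NA), b = c(1, 4, 2)
  )
}

test_that("schema validation rejects bad ranges and unknown ratio members", {
  expect_error(indicator_schema(data.frame(name = "a", low = 5, high = 5)),
               class = "psn_schema_error")
  expect_error(
    indicator_schema(data.frame(name = "a", low = 0, high = 1),
                     ratio_pairs = data.frame(ratio_name = "r", numerator = "a",
                                              denominator = "zz")),
    class = "psn_schema_error")
})

test_that("range_filter nulls or drops out-of-range values and reports them", {
  co <- mini_cohort()
  co$a[1] <- 99  # above the plausible high of 10
  rf <- range_filter(co, mini_schema(), policy = "null")
  expect_true(is.na(rf$cohort$a[1]))
  expect_equal(nrow(rf$cohort), 3)
  expect_equal(rf$report$patient_id, "p1")
  expect_equal(rf$report$value, 99)
  expect_equal(rf$report$action, "set_missing")

  rf2 <- range_filter(co, mini_schema(), policy = "drop")
  expect_equal(rf2$cohort$patient_id, c("p2", "p3"))
  expect_equal(rf2$report$action, "record_dropped")
  # missing values are never flagged
  expect_false("p3" %in% rf$report$patient_id)
})

test_that("cohort indicators outside the schema are rejected", {
  co <- mini_cohort()
  co$mystery <- 1
  expect_error(range_filter(co, mini_schema()), "mystery", class = "psn_schema_error")
})

test_that("origin preprocessing passes values through", {
  feat <- preprocess_indicators(mini_cohort(), mini_schema(), "origin")
  expect_equal(feat$a, mini_cohort()$a)
  expect_equal(feat$b, mini_cohort()$b)
})

test_that("zscore uses cohort sample statistics (n - 1 sd)", {
  co <- mini_cohort()
  feat <- preprocess_indicators(co, mini_schema(), "zscore")
  expect_equal(feat$a, (co$a - mean(co$a, na.rm = TRUE)) / sd(co$a, na.rm = TRUE))
  # zero variance cannot be z-scored
  co$b <- c(2, 2, 2)
  expect_error(preprocess_indicators(co, mini_schema(), "zscore"),
               class = "psn_transform_error")
})

test_that("combination adds ratio columns and flags zero denominators", {
  co <- mini_cohort()
  co$b[1] <- 0
  feat <- preprocess_indicators(co, mini_schema(), "combination")
  expect_true("r" %in% names(feat))
  expect_true(is.na(feat$r[1]))
  expect_equal(feat$r[2], 8 / 4)
  expect_match(attr(feat, "notes"), "zero denominator")
})

test_that("unseen patients are transformed with training statistics only", {
  co <- mini_cohort()
  tr <- fit_preprocessor(co, mini_schema(), "zscore")
  new <- co[1, ]
  new$a <- 5
  out <- apply_preprocessor(tr, new)
  st <- tr$stats[tr$stats$feature == "a", ]
  expect_equal(out$a, (5 - st$mean) / st$sd)
})

test_that("indicator distance matches the brute-force Gower oracle", {
  co <- small_cohort(10, seed = 5)
  schema <- default_indicator_schema()
  tr <- fit_preprocessor(co, schema, "origin")
  feat <- apply_preprocessor(tr, co)
  ranges <- setNames(tr$ranges$max - tr$ranges$min, tr$ranges$feature)
  X <- as.matrix(feat[, tr$features])
  for (i in 1:9) for (j in (i + 1):10) {
    expect_equal(indicator_distance(feat[i, ], feat[j, ], tr),
                 bf_gower(X[i, ], X[j, ], ranges[tr$features]), tolerance = 1e-12)
  }
})

test_that("Gower core handles no shared features and zero ranges", {
  tr <- fit_preprocessor(mini_cohort(), mini_schema(), "origin")
  # p3 has a missing; make a pair with no overlap at all
  x <- c(a = 1, b = NA)
  y <- c(a = NA, b = 3)
  expect_equal(indicator_distance(x, y, tr), 1)
  # zero-range feature: distance contribution is 0/1 on equality
  ranges0 <- c(a = 0)
  expect_equal(bf_gower(c(a = 3), c(a = 3), ranges0), 0)
  expect_equal(bf_gower(c(a = 3), c(a = 4), ranges0), 1)
})

test_that("indicator distances are symmetric, bounded and zero on identity", {
  co <- small_cohort(15, seed = 6)
  tr <- fit_preprocessor(co, default_indicator_schema(), "zscore")
  feat <- apply_preprocessor(tr, co)
  D <- psnmap:::indicator_distance_matrix(feat, tr)
  expect_true(isSymmetric(unname(D)))
  expect_true(all(D >= 0 & D <= 1))
  expect_true(all(diag(D) == 0))
})

test_that("clinical and surgical distances match the Gower oracle", {
  co <- mini_cohort()
  sc <- fit_scaling(co)
  crng <- c(sapply(c("age_months", "height_cm", "weight_kg", "preop_spo2_pct"),
                   function(f) diff(range(co[[f]]))), sex_male = 1)
  x <- c(co$age_months[1], co$height_cm[1], co$weight_kg[1], co$preop_spo2_pct[1], 1)
  y <- c(co$age_months[2], co$height_cm[2], co$weight_kg[2], co$preop_spo2_pct[2], 0)
  expect_equal(clinical_distance(co[1, ], co[2, ], sc), bf_gower(x, y, crng),
               tolerance = 1e-12)
  srng <- sapply(c("surgery_min", "cpb_min", "clamp_min"),
                 function(f) diff(range(co[[f]])))
  xs <- c(co$surgery_min[1], co$cpb_min[1], co$clamp_min[1])
  ys <- c(co$surgery_min[3], co$cpb_min[3], co$clamp_min[3])
  expect_equal(surgical_distance(co[1, ], co[3, ], sc), bf_gower(xs, ys, srng),
               tolerance = 1e-12)
})
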