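test_that("weight vectors are validated", {
  w <- weight_vector(2, 1, 1, 0)
  expect_s3_class(w, "psn_weights")
  expect_error(weight_vector(-1, 1, 1, 1), class = "psn_config_error")
  expect_error(weight_vector(0, 0, 0, 0), class = "psn_config_error")
})

test_that("fuse_distances implements the normalised weighted combination", {
  d <- fuse_distances(0.2, 0.4, 0.6, 0.8, weight_vector(1, 1, 1, 1))
  expect_equal(d, mean(c(0.2, 0.4, 0.6, 0.8)))
  d2 <- fuse_distances(0.2, 0.4, 0.6, 0.8, weight_vector(2, 1, 1, 0))
  expect_equal(d2, (2 * 0.2 + 0.4 + 0.6) / 4)
  # zero-weight component may be NULL; weighted missing component errors
  expect_equal(fuse_distances(0.2, 0.4, 0.6, NULL, weight_vector(1, 1, 1, 0)),
               mean(c(0.2, 0.4, 0.6)))
  expect_error(fuse_distances(0.2, NULL, 0.6, 0.8, weight_vector(1, 1, 1, 1)),
               "diag", class = "psn_config_error")
})

test_that("fusion is scale-invariant in the weights and component-monotone", {
  set.seed(3)
  for (trial in 1:20) {
    comp <- runif(4)
    w <- runif(4, 0.1, 2)
    d1 <- fuse_distances(comp[1], comp[2], comp[3], comp[4], do.call(weight_vector, as.list(w)))
    d2 <- fuse_distances(comp[1], comp[2], comp[3], comp[4], do.call(weight_vector, as.list(7 * w)))
    expect_equal(d1, d2, tolerance = 1e-12)
    # raising any component never lowers the fused distance
    bump <- comp; bump[1] <- min(bump[1] + 0.1, 1)
    d3 <- fuse_distances(bump[1], bump[2], bump[3], bump[4], do.call(weight_vector, as.list(w)))
    expect_gte(d3, d1)
  }
})

test_that("build_psn yields a symmetric, bounded, zero-diagonal matrix", {
  co <- small_cohort(25, seed = 21)
  psn <- build_psn(co, generate_toy_ontology(), default_indicator_schema(),
                   method = "zscore", mode = "grade")
  expect_s3_class(psn, "psn")
  expect_true(isSymmetric(unname(psn$values)))
  expect_true(all(psn$values >= 0 & psn$values <= 1))
  expect_true(all(diag(psn$values) == 0))
  for (m in psn$components) {
    expect_true(all(m >= 0 & m <= 1))
    expect_true(all(diag(m) == 0))
  }
})

test_that("fused matrix equals a brute-force double loop on a small cohort", {
  co <- small_cohort(8, seed = 22)
  onto <- generate_toy_ontology()
  schema <- default_indicator_schema()
  w <- weight_vector(2, 1, 1.5, 0.5)
  psn <- build_psn(co, onto, schema, method = "origin", mode = "ungrade", weights = w)
  tr <- psn$transform
  feat <- apply_preprocessor(tr, co)
  sc <- psn$scaling
  for (i in 1:7) for (j in (i + 1):8) {
    di <- indicator_distance(feat[i, ], feat[j, ], tr)
    dd <- diagnosis_distance(co$diagnoses[i], co$diagnoses[j], onto, mode = "ungrade")
    dp <- clinical_distance(co[i, ], co[j, ], sc)
    ds <- surgical_distance(co[i, ], co[j, ], sc)
    expect_equal(psn$values[i, j],
                 (2 * di + 1 * dd + 1.5 * dp + 0.5 * ds) / 5, tolerance = 1e-12)
  }
})

test_that("duplicate ids and sub-minimal cohorts are rejected", {
  co <- small_cohort(5, seed = 23)
  co$patient_id[2] <- co$patient_id[1]
  expect_error(build_psn(co, generate_toy_ontology(), default_indicator_schema()),
               class = "psn_precondition_error")
  expect_error(build_psn(small_cohort(5)[1, ], generate_toy_ontology(),
                         default_indicator_schema()),
               class = "psn_precondition_error")
})

test_that("reweight re-fuses from cached components without recomputation", {
  co <- small_cohort(15, seed = 24)
  psn <- build_psn(co, generate_toy_ontology(), default_indicator_schema())
  psn2 <- reweight(psn, weight_vector(0, 1, 0, 0))
  expect_equal(unname(psn2$values), unname(psn$components$diag))
  psn3 <- reweight(psn2, weight_vector(1, 1, 1, 1))
  expect_equal(psn3$values, psn$values)
})

test_that("phase submaps activate the documented feature groups", {
  co <- small_cohort(15, seed = 25)
  psn <- build_psn(co, generate_toy_ontology(), default_indicator_schema())
  scr <- phase_submap(psn, "screening")
  expect_equal(unname(scr$values), unname(psn$components$diag))
  echo <- phase_submap(psn, "echo")
  expect_equal(unname(echo$values),
               unname((psn$components$indicator + psn$components$diag) / 2))
  # screening and surgery maps differ when surgical features differ
  expect_false(isTRUE(all.equal(scr$values, psn$values)))
})

test_that("tidy and glance summarise the network", {
  co <- small_cohort(10, seed = 26)
  psn <- build_psn(co, generate_toy_ontology(), default_indicator_schema())
  td <- generics::tidy(psn)
  expect_equal(nrow(td), choose(10, 2))
  expect_true(all(c("id_a", "id_b", "distance", "d_indicator", "d_diag",
                    "d_pre", "d_surg") %in% names(td)))
  gl <- generics::glance(psn)
  expect_equal(gl$n_patients, 10)
  expect_equal(gl$phase, "surgery")
})

test_that("distance matrix TSV round-trips", {
  co <- small_cohort(8, seed = 27)
  psn <- build_psn(co, generate_toy_ontology(), default_indicator_schema())
  f <- tempfile(fileext = ".tsv")
  write_distance_tsv(psn, f)
  m <- read_distance_tsv(f)
  expect_equal(rownames(m), psn$ids)
  expect_equal(unname(m), unname(psn$values), tolerance = 1e-12)
})

test_that("cross distances for a training record match its map row", {
  co <- small_cohort(12, seed = 28)
  psn <- build_psn(co, generate_toy_ontology(), default_indicator_schema(),
                   method = "zscore", mode = "grade")
  cd <- psnmap:::cross_distances(psn, co[3, ])
  expect_equal(unname(cd$values[1, ]), unname(psn$values[3, ]), tolerance = 1e-10)
})
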