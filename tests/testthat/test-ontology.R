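test_that("ontology builds from an edge list with correct depths", {
  onto <- toy_tree()
  expect_s3_class(onto, "psn_ontology")
  expect_identical(onto$root_id, "CHD")
  expect_equal(term_depth(onto, c("CHD", "SeptalDefect", "VSD", "ASD")), c(1, 2, 3, 3))
})

test_that("single term with no edges is a valid degenerate ontology", {
  onto <- ontology(data.frame(child_id = character(), parent_id = character()),
                   terms = "CHD")
  expect_identical(onto$root_id, "CHD")
  expect_equal(term_depth(onto, "CHD"), 1)
})

test_that("structural errors are detected and named", {
  expect_error(
    ontology(data.frame(child_id = c("B", "C", "B"), parent_id = c("A", "B", "C"))),
    "cycle", class = "psn_structure_error")
  expect_error(
    ontology(data.frame(child_id = c("B", "D"), parent_id = c("A", "C"))),
    "multiple roots.*A.*C", class = "psn_structure_error")
  expect_error(ontology(data.frame(child_id = "A", parent_id = "A")),
               class = "psn_structure_error")
})

test_that("multi-parent depth is min over parents plus one", {
  onto <- ontology(data.frame(
    child_id  = c("B", "C", "D", "D"),
    parent_id = c("A", "B", "A", "C")
  ))
  # D has parents A (depth 1) and C (depth 3): shallowest path wins
  expect_equal(term_depth(onto, "D"), 2)
})

test_that("lowest common ancestor matches hand computation with tie-break", {
  onto <- toy_tree()
  expect_identical(lowest_common_ancestor(onto, "VSD", "ASD"), "SeptalDefect")
  expect_identical(lowest_common_ancestor(onto, "VSD", "VSD"), "VSD")
  expect_identical(lowest_common_ancestor(onto, "VSD", "CHD"), "CHD")
  expect_error(lowest_common_ancestor(onto, "VSD", "nope"),
               class = "psn_reference_error")
})

test_that("Wu-Palmer similarity reproduces the hand-computed toy values", {
  onto <- toy_tree()
  expect_equal(term_similarity(onto, "VSD", "VSD"), 1)
  expect_equal(term_similarity(onto, "VSD", "ASD"), 2 * 2 / (3 + 3))
  expect_equal(term_similarity(onto, "VSD", "CHD"), 2 * 1 / (3 + 1))
})

test_that("term similarity is symmetric and bounded on the full toy ontology", {
  onto <- generate_toy_ontology()
  m <- term_similarity_matrix(onto)
  expect_true(isSymmetric(m))
  expect_true(all(m > 0 & m <= 1))
  expect_true(all(diag(m) == 1))
})

test_that("similarity is monotone: deeper within-branch pairs beat cross-branch", {
  onto <- generate_toy_ontology()
  # two VSD subtypes share a deep LCA; VSD vs ASD splits at septal_defect
  expect_gt(term_similarity(onto, "VSD_muscular", "VSD_perimembranous"),
            term_similarity(onto, "VSD", "ASD"))
})

test_that("diagnosis strings parse and format round-trip", {
  d <- parse_diagnoses("VSD*;PDA")[[1]]
  expect_equal(d$term_id, c("VSD", "PDA"))
  expect_equal(d$is_primary, c(TRUE, FALSE))
  expect_identical(format_diagnoses(d), "VSD*;PDA")
})

test_that("diagnosis list distance matches hand values on the toy tree", {
  onto <- toy_tree()
  expect_equal(diagnosis_distance("VSD*", "VSD*", onto, mode = "ungrade"), 0)
  expect_equal(diagnosis_distance("VSD", "ASD", onto, mode = "ungrade"),
               1 - 2 / 3, tolerance = 1e-12)
  # grade with no secondary terms: primary part takes full weight
  expect_equal(diagnosis_distance("VSD*", "ASD*", onto, mode = "grade"),
               1 - 2 / 3, tolerance = 1e-12)
})

test_that("grade mode mixes primary and secondary parts with alpha", {
  onto <- generate_toy_ontology()
  a <- "VSD*;PDA"
  b <- "ASD*;PFO"
  dp <- diagnosis_distance("VSD", "ASD", onto, mode = "ungrade")
  ds <- diagnosis_distance("PDA", "PFO", onto, mode = "ungrade")
  expect_equal(diagnosis_distance(a, b, onto, mode = "grade", alpha = 0.7),
               0.7 * dp + 0.3 * ds, tolerance = 1e-12)
  # one side without a primary flag falls back to ungrade
  expect_equal(diagnosis_distance("VSD;PDA", b, onto, mode = "grade"),
               diagnosis_distance("VSD;PDA", b, onto, mode = "ungrade"))
})

test_that("list distance is symmetric, zero on identity, in [0,1], and matches the brute-force oracle", {
  onto <- generate_toy_ontology()
  terms <- onto$terms$term_id
  set.seed(11)
  for (trial in 1:25) {
    ta <- sample(terms, sample(1:3, 1))
    tb <- sample(terms, sample(1:3, 1))
    a <- tibble::tibble(term_id = ta, is_primary = FALSE)
    b <- tibble::tibble(term_id = tb, is_primary = FALSE)
    d <- diagnosis_distance(a, b, onto, mode = "ungrade")
    expect_equal(d, diagnosis_distance(b, a, onto, mode = "ungrade"))
    expect_gte(d, 0); expect_lte(d, 1)
    expect_equal(d, bf_list_distance(ta, tb, onto), tolerance = 1e-12)
    expect_equal(diagnosis_distance(a, a, onto, mode = "ungrade"), 0)
  }
})

test_that("empty diagnosis lists and unknown terms error", {
  onto <- toy_tree()
  expect_error(diagnosis_distance("", "VSD", onto), class = "psn_precondition_error")
  expect_error(diagnosis_distance("XYZ", "VSD", onto), class = "psn_reference_error")
})

test_that("TSV and OBO readers produce the same hierarchy", {
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("SeptalDefect\tCHD", "VSD\tSeptalDefect", "ASD\tSeptalDefect"), tsv)
  o1 <- read_ontology(tsv)
  obo <- tempfile(fileext = ".obo")
  writeLines(c(
    "[Term]", "id: CHD", "name: congenital heart disease",
    "[Term]", "id: SeptalDefect", "is_a: CHD ! congenital heart disease",
    "[Term]", "id: VSD", "is_a: SeptalDefect",
    "[Term]", "id: ASD", "is_a: SeptalDefect"), obo)
  o2 <- read_ontology(obo)
  expect_setequal(o1$terms$term_id, o2$terms$term_id)
  expect_equal(term_depth(o2, "VSD"), 3)
  expect_identical(o2$terms$label[o2$terms$term_id == "CHD"],
                   "congenital heart disease")
})

test_that("malformed ontology files error with location", {
  bad <- tempfile(fileext = ".tsv")
  writeLines(c("A\tB", "loose_token"), bad)
  expect_error(read_ontology(bad), "line 2", class = "psn_io_error")
  expect_error(read_ontology(tempfile()), "not found", class = "psn_io_error")
})
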