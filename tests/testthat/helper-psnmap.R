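# Shared builders for the test suite.

# Minimal 4-term tree: CHD <- SeptalDefect <- {VSD, ASD}.
toy_tree <- function() {
  ontology(data.frame(
    child_id  = c("SeptalDefect", "VSD", "ASD"),
    parent_id = c("CHD", "SeptalDefect", "SeptalDefect")
  ))
}

# Small deterministic cohort from the synthetic generator.
small_cohort <- function(n = 40, seed = 101, ...) {
  generate_cohort(synthetic_spec(n_patients = n, seed = seed, ...),
                  generate_toy_ontology())$cohort
}

# Brute-force symmetric best-match diagnosis-list distance (independent of
# the package implementation; plain loops).
bf_list_distance <- function(ta, tb, onto) {
  simfun <- function(a, b) term_similarity(onto, a, b)
  best_a <- sapply(ta, function(a) max(sapply(tb, function(b) simfun(a, b))))
  best_b <- sapply(tb, function(b) max(sapply(ta, function(a) simfun(a, b))))
  1 - 0.5 * (mean(best_a) + mean(best_b))
}

# Brute-force Gower distance between two numeric vectors with given ranges.
bf_gower <- function(x, y, ranges) {
  num <- 0; cnt <- 0
  for (f in seq_along(x)) {
    if (is.na(x[f]) || is.na(y[f])) next
    r <- ranges[f]
    d <- if (is.na(r) || r == 0) as.numeric(x[f] != y[f]) else min(abs(x[f] - y[f]) / r, 1)
    num <- num + d; cnt <- cnt + 1
  }
  if (cnt == 0) 1 else num / cnt
}

# Brute-force pairwise AUC: P(score_pos > score_neg) + 0.5 * P(tie).
bf_auc <- function(scores, labels) {
  pos <- scores[labels]; neg <- scores[!labels]
  tot <- 0
  for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}
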