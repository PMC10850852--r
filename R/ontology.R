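#' Build a diagnosis ontology from a parent-child edge table
#'
#' The ontology is a rooted directed acyclic graph of diagnosis terms; it is
#' the backbone for depth-based semantic similarity between diagnoses.
#' Depth is defined so that the root has depth 1 and every other term has
#' depth one more than its shallowest parent.
#'
#' @param edges Data frame with columns `child_id` and `parent_id` (or any
#'   two columns, taken positionally), one row per is-a edge.
#' @param labels Optional data frame with columns `term_id` and `label`.
#' @param terms Optional character vector of extra term ids that carry no
#'   edges (needed e.g. for a single-term ontology).
#' @return An object of class `psn_ontology`: term table (id, label, depth),
#'   parent map, precomputed ancestor-or-self sets, and `root_id`.
#' @examples
#' onto <- ontology(data.frame(
#'   child_id  = c("SeptalDefect", "VSD", "ASD"),
#'   parent_id = c("CHD", "SeptalDefect", "SeptalDefect")
#' ))
#' term_depth(onto, "VSD") # 3
#' @export
ontology <- function(edges, labels = NULL, terms = NULL) {
  edges <- as_tibble(edges)
  if (ncol(edges) < 2) psn_abort("`edges` needs child and parent columns", "psn_structure_error")
  if (!all(c("child_id", "parent_id") %in% names(edges))) {
    names(edges)[1:2] <- c("child_id", "parent_id")
  }
  edges <- edges %>%
    transmute(child_id = as.character(.data$child_id),
              parent_id = as.character(.data$parent_id)) %>%
    distinct()
  if (nrow(edges) > 0 && any(!nzchar(edges$child_id) | !nzchar(edges$parent_id))) {
    psn_abort("empty term id in edge list", "psn_structure_error")
  }
  ids <- unique(c(edges$child_id, edges$parent_id, as.character(terms %||% character()),
                  if (!is.null(labels)) as.character(labels$term_id)))
  if (length(ids) == 0) psn_abort("ontology has no terms", "psn_structure_error")

  parents <- split(edges$parent_id, factor(edges$child_id, levels = ids))
  children <- split(edges$child_id, factor(edges$parent_id, levels = ids))

  roots <- ids[lengths(parents) == 0]
  if (length(roots) == 0) {
    psn_abort("no root term: every term has a parent (cycle through the whole graph?)",
              "psn_structure_error")
  }
  if (length(roots) > 1) {
    psn_abort(paste0("multiple roots: ", paste(sort(roots), collapse = ", ")),
              "psn_structure_error")
  }
  root_id <- roots

  # Kahn's algorithm: finalises a term once all parents are done, yielding both
  # a cycle check and depths (min over parents) in one pass.
  n_wait <- lengths(parents)
  depth <- setNames(rep(NA_real_, length(ids)), ids)
  depth[root_id] <- 1
  anc <- setNames(vector("list", length(ids)), ids)
  anc[[root_id]] <- root_id
  queue <- root_id
  done <- character()
  while (length(queue) > 0) {
    u <- queue[[1]]; queue <- queue[-1]
    done <- c(done, u)
    for (ch in children[[u]]) {
      n_wait[[ch]] <- n_wait[[ch]] - 1L
      if (n_wait[[ch]] == 0L) {
        ps <- parents[[ch]]
        depth[[ch]] <- min(depth[ps]) + 1
        anc[[ch]] <- unique(c(ch, unlist(anc[ps], use.names = FALSE)))
        queue <- c(queue, ch)
      }
    }
  }
  if (length(done) < length(ids)) {
    left <- setdiff(ids, done)
    bad <- edges %>% filter(.data$child_id %in% left, .data$parent_id %in% left)
    hint <- if (nrow(bad) > 0) {
      paste0("cycle detected involving edge ", bad$child_id[1], " -> ", bad$parent_id[1])
    } else {
      paste0("terms unreachable from root: ", paste(sort(left), collapse = ", "))
    }
    psn_abort(hint, "psn_structure_error")
  }

  lab <- setNames(ids, ids)
  if (!is.null(labels)) {
    labels <- as_tibble(labels)
    if (!all(c("term_id", "label") %in% names(labels))) names(labels)[1:2] <- c("term_id", "label")
    lab[as.character(labels$term_id)] <- as.character(labels$label)
  }

  structure(
    list(
      terms = tibble(term_id = ids, label = unname(lab[ids]), depth = unname(depth[ids])),
      parents = parents,
      ancestors = anc,
      root_id = root_id
    ),
    class = "psn_ontology"
  )
}

#' @export
print.psn_ontology <- function(x, ...) {
  cat("<psn_ontology> ", nrow(x$terms), " terms, root '", x$root_id,
      "', max depth ", max(x$terms$depth), "\n", sep = "")
  invisible(x)
}

#' Read an ontology from a TSV edge list or an OBO-flavoured file
#'
#' A TSV source has two columns `child_id<TAB>parent_id` (a header row with
#' exactly those names is allowed); an OBO-flavoured source consists of
#' `[Term]` stanzas with `id:`, `name:` and `is_a:` lines. The format is
#' detected from the content.
#'
#' @param path Path to the ontology file.
#' @param labels_path Optional TSV `term_id<TAB>label`.
#' @return A [ontology()] object.
#' @export
read_ontology <- function(path, labels_path = NULL) {
  if (!file.exists(path)) psn_abort(paste0("ontology file not found: ", path), "psn_io_error")
  lines <- readLines(path, warn = FALSE)
  labels <- NULL
  if (!is.null(labels_path)) {
    lt <- read.table(labels_path, sep = "\t", header = FALSE, quote = "",
                     col.names = c("term_id", "label"), stringsAsFactors = FALSE)
    labels <- as_tibble(lt)
  }
  if (any(grepl("^\\[Term\\]", lines))) {
    return(parse_obo(lines))
  }
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) psn_abort(paste0("empty ontology file: ", path), "psn_io_error")
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 2)) {
    bad <- which(lengths(parts) < 2)[1]
    psn_abort(paste0("malformed edge at line ", bad, " of ", path), "psn_io_error")
  }
  df <- tibble(child_id = map_chr(parts, 1), parent_id = map_chr(parts, 2))
  if (identical(df$child_id[1], "child_id")) df <- df[-1, ]
  ontology(df, labels = labels)
}

parse_obo <- function(lines) {
  term_starts <- grep("^\\[Term\\]", lines)
  if (length(term_starts) == 0) psn_abort("no [Term] stanza found", "psn_io_error")
  bounds <- c(term_starts, length(lines) + 1L)
  recs <- map(seq_along(term_starts), function(i) {
    chunk <- lines[(bounds[i] + 1L):(bounds[i + 1L] - 1L)]
    chunk <- chunk[!grepl("^\\[", chunk)]
    get <- function(key) {
      hits <- grep(paste0("^", key, ":"), chunk, value = TRUE)
      trimws(sub("!.*$", "", sub(paste0("^", key, ":\\s*"), "", hits)))
    }
    list(id = get("id"), name = get("name"), is_a = get("is_a"))
  })
  ids <- map_chr(recs, function(r) if (length(r$id)) r$id[1] else NA_character_)
  if (anyNA(ids)) psn_abort("[Term] stanza without an id", "psn_io_error")
  edges <- purrr::map2_dfr(recs, ids, function(r, id) {
    if (length(r$is_a) == 0) return(tibble(child_id = character(), parent_id = character()))
    tibble(child_id = id, parent_id = r$is_a)
  })
  labels <- tibble(
    term_id = ids,
    label = map_chr(recs, function(r) if (length(r$name)) r$name[1] else r$id[1])
  )
  ontology(edges, labels = labels, terms = ids)
}

check_terms <- function(onto, ids) {
  missing <- setdiff(ids, onto$terms$term_id)
  if (length(missing) > 0) {
    psn_abort(paste0("unknown ontology term(s): ", paste(missing, collapse = ", ")),
              "psn_reference_error")
  }
  invisible(TRUE)
}

#' Depth of ontology terms
#'
#' @param onto A [ontology()] object.
#' @param ids Character vector of term ids.
#' @return Numeric vector of depths (root = 1).
#' @export
term_depth <- function(onto, ids) {
  check_terms(onto, ids)
  d <- setNames(onto$terms$depth, onto$terms$term_id)
  unname(d[ids])
}

#' Lowest common ancestor of two terms
#'
#' The deepest term that is an ancestor-or-self of both; depth ties are broken
#' by lexicographic term id so the result is deterministic on DAGs.
#'
#' @inheritParams term_depth
#' @param a,b Term ids.
#' @return A term id.
#' @export
lowest_common_ancestor <- function(onto, a, b) {
  check_terms(onto, c(a, b))
  common <- intersect(onto$ancestors[[a]], onto$ancestors[[b]])
  d <- term_depth(onto, common)
  cands <- sort(common[d == max(d)])
  cands[1]
}

#' Depth-based (Wu-Palmer) similarity between two diagnosis terms
#'
#' `sim(a, b) = 2 * depth(LCA(a, b)) / (depth(a) + depth(b))`, bounded in
#' (0, 1], symmetric, and 1 exactly on identical terms in a tree.
#'
#' @inheritParams lowest_common_ancestor
#' @return Similarity in (0, 1].
#' @export
term_similarity <- function(onto, a, b) {
  lca <- lowest_common_ancestor(onto, a, b)
  2 * term_depth(onto, lca) / (term_depth(onto, a) + term_depth(onto, b))
}

#' Pairwise term similarity matrix
#'
#' @inheritParams term_depth
#' @param ids Terms to compare (default: all).
#' @return Symmetric matrix of Wu-Palmer similarities with dimnames `ids`.
#' @export
term_similarity_matrix <- function(onto, ids = onto$terms$term_id) {
  check_terms(onto, ids)
  n <- length(ids)
  m <- diag(1, n)
  dimnames(m) <- list(ids, ids)
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        s <- term_similarity(onto, ids[i], ids[j])
        m[i, j] <- s
        m[j, i] <- s
      }
    }
  }
  m
}

#' Parse and format encoded diagnosis lists
#'
#' Diagnosis lists travel in cohort tables as strings like `"VSD*;PDA"`:
#' `;`-separated term ids with `*` marking the primary ("basic") diagnosis.
#'
#' @param x Character vector of encoded diagnosis lists.
#' @return A list of tibbles with columns `term_id`, `is_primary`.
#' @export
parse_diagnoses <- function(x) {
  map(as.character(x), function(s) {
    if (is.na(s) || !nzchar(trimws(s))) {
      return(tibble(term_id = character(), is_primary = logical()))
    }
    toks <- trimws(strsplit(s, ";", fixed = TRUE)[[1]])
    toks <- toks[nzchar(toks)]
    tibble(term_id = sub("\\*$", "", toks),
           is_primary = grepl("\\*$", toks))
  })
}

#' @rdname parse_diagnoses
#' @param diag A diagnosis tibble (`term_id`, `is_primary`) or list of them.
#' @export
format_diagnoses <- function(diag) {
  one <- function(d) paste0(d$term_id, ifelse(d$is_primary, "*", ""), collapse = ";")
  if (is.data.frame(diag)) one(diag) else map_chr(diag, one)
}

as_diag_tbl <- function(x) {
  if (is.character(x)) x <- parse_diagnoses(x)[[1]]
  if (!is.data.frame(x) || !all(c("term_id", "is_primary") %in% names(x))) {
    psn_abort("diagnosis list must have term_id and is_primary", "psn_precondition_error")
  }
  as_tibble(x)
}

# Symmetric best-match average distance between two term sets, given a
# precomputed similarity lookup (matrix with dimnames covering both sets).
best_match_distance <- function(ta, tb, simmat) {
  sub <- simmat[ta, tb, drop = FALSE]
  1 - 0.5 * (mean(apply(sub, 1, max)) + mean(apply(sub, 2, max)))
}

#' Distance between two diagnosis lists
#'
#' `mode = "ungrade"` treats all diagnoses equally: a symmetric best-match
#' average of pairwise term similarities,
#' `d = 1 - (mean_a max_b sim + mean_b max_a sim) / 2`.
#' `mode = "grade"` distinguishes primary ("basic") from secondary diagnoses:
#' `d = alpha * d_primary + (1 - alpha) * d_secondary`, each part the same
#' best-match construction restricted to that flag. If either record has no
#' secondary terms the primary part gets full weight; if either record has no
#' primary terms the pair falls back to ungrade.
#'
#' @param a,b Diagnosis lists: tibbles (`term_id`, `is_primary`) or encoded
#'   strings such as `"VSD*;PDA"`.
#' @param onto A [ontology()] object.
#' @param mode `"grade"` or `"ungrade"`.
#' @param alpha Weight of the primary part in grade mode (default 0.7).
#' @param simmat Optional precomputed [term_similarity_matrix()].
#' @return Distance in `[0, 1]`; 0 for identical term sets.
#' @export
diagnosis_distance <- function(a, b, onto, mode = c("ungrade", "grade"),
                               alpha = 0.7, simmat = NULL) {
  mode <- match.arg(mode)
  a <- as_diag_tbl(a); b <- as_diag_tbl(b)
  if (nrow(a) == 0 || nrow(b) == 0) {
    psn_abort("diagnosis list is empty", "psn_precondition_error")
  }
  check_terms(onto, c(a$term_id, b$term_id))
  if (is.null(simmat)) simmat <- term_similarity_matrix(onto, unique(c(a$term_id, b$term_id)))
  if (mode == "ungrade") return(best_match_distance(a$term_id, b$term_id, simmat))

  pa <- a$term_id[a$is_primary]; sa <- a$term_id[!a$is_primary]
  pb <- b$term_id[b$is_primary]; sb <- b$term_id[!b$is_primary]
  if (length(pa) == 0 || length(pb) == 0) {
    return(best_match_distance(a$term_id, b$term_id, simmat))
  }
  dp <- best_match_distance(pa, pb, simmat)
  if (length(sa) == 0 || length(sb) == 0) return(dp)
  ds <- best_match_distance(sa, sb, simmat)
  alpha * dp + (1 - alpha) * ds
}

# Pairwise diagnosis distance over a cohort, collapsed over identical encoded
# signatures (few distinct diagnosis lists in practice, so this is cheap).
diagnosis_distance_matrix <- function(diag_strings, onto, mode = "ungrade", alpha = 0.7) {
  sigs <- as.character(diag_strings)
  usig <- unique(sigs)
  terms <- unique(unlist(map(parse_diagnoses(usig), "term_id")))
  check_terms(onto, terms)
  simmat <- term_similarity_matrix(onto, terms)
  k <- length(usig)
  dm <- matrix(0, k, k)
  if (k > 1) {
    tbls <- parse_diagnoses(usig)
    for (i in seq_len(k - 1)) {
      for (j in (i + 1):k) {
        d <- diagnosis_distance(tbls[[i]], tbls[[j]], onto, mode = mode,
                                alpha = alpha, simmat = simmat)
        dm[i, j] <- d
        dm[j, i] <- d
      }
    }
  }
  idx <- match(sigs, usig)
  out <- dm[idx, idx, drop = FALSE]
  diag(out) <- 0
  out
}

# Cross distances (rows = query signatures, cols = reference signatures).
diagnosis_distance_cross <- function(query_strings, ref_strings, onto,
                                     mode = "ungrade", alpha = 0.7) {
  all_sigs <- c(as.character(query_strings), as.character(ref_strings))
  big <- diagnosis_distance_matrix(all_sigs, onto, mode = mode, alpha = alpha)
  nq <- length(query_strings)
  big[seq_len(nq), nq + seq_along(ref_strings), drop = FALSE]
}
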