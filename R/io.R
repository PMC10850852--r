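COHORT_CHR <- c("patient_id", "sex", "diagnoses")
COHORT_LGL <- c("complication", "survived")

coerce_cohort_types <- function(df) {
  df <- as_tibble(df)
  need <- setdiff(c(COHORT_CHR, COHORT_LGL), names(df))
  if (length(need) > 0) {
    psn_abort(paste0("cohort is missing column(s): ", paste(need, collapse = ", ")),
              "psn_io_error")
  }
  for (col in intersect(COHORT_CHR, names(df))) df[[col]] <- as.character(df[[col]])
  for (col in intersect(COHORT_LGL, names(df))) df[[col]] <- as.logical(df[[col]])
  for (col in setdiff(names(df), c(COHORT_CHR, COHORT_LGL))) {
    df[[col]] <- as.numeric(df[[col]])
  }
  df
}

#' Write and read cohort tables (CSV and JSON-lines)
#'
#' The CSV layout is flat: one row per patient, indicators as columns,
#' diagnosis lists encoded `term_id[*]` (`*` = primary) and `;`-separated.
#' The JSON-lines layout nests `indicators` as a map (missing values simply
#' absent) and `diagnoses` as objects with `term_id` / `is_primary`.
#'
#' @param cohort Cohort tibble.
#' @param path Output file; `read_cohort()` detects the format from the
#'   `.csv` / `.jsonl` extension (falling back to content sniffing).
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
write_cohort_jsonl <- function(cohort, path) {
  cohort <- as_tibble(cohort)
  ind_cols <- indicator_cols(cohort)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(cohort))) {
    rec <- as.list(cohort[i, setdiff(names(cohort), c(ind_cols, "diagnoses"))])
    ind <- as.list(cohort[i, ind_cols])
    rec$indicators <- ind[!vapply(ind, is.na, logical(1))]
    d <- parse_diagnoses(cohort$diagnoses[i])[[1]]
    rec$diagnoses <- map(seq_len(nrow(d)), function(j) {
      list(term_id = d$term_id[j], is_primary = d$is_primary[j])
    })
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA, null = "null"), con)
  }
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) psn_abort(paste0("cohort file not found: ", path), "psn_io_error")
  first <- readLines(path, n = 1, warn = FALSE)
  is_jsonl <- grepl("\\.jsonl$", path) || grepl("^\\s*\\{", first)
  if (is_jsonl) read_cohort_jsonl(path) else read_cohort_csv(path)
}

read_cohort_csv <- function(path) {
  df <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE),
    error = function(e) psn_abort(paste0("malformed CSV ", path, ": ", conditionMessage(e)),
                                  "psn_io_error"),
    warning = function(w) psn_abort(paste0("malformed CSV ", path, ": ", conditionMessage(w)),
                                    "psn_io_error")
  )
  coerce_cohort_types(df)
}

read_cohort_jsonl <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  recs <- map(seq_along(lines), function(i) {
    tryCatch(jsonlite::fromJSON(lines[i], simplifyVector = TRUE),
             error = function(e) psn_abort(
               paste0("malformed JSON at line ", i, " of ", path, ": ", conditionMessage(e)),
               "psn_io_error"))
  })
  ind_names <- unique(unlist(map(recs, ~ names(.x$indicators))))
  rows <- map(recs, function(r) {
    d <- r$diagnoses
    diag_str <- if (is.data.frame(d)) {
      format_diagnoses(tibble(term_id = d$term_id, is_primary = as.logical(d$is_primary)))
    } else if (length(d) > 0) {
      format_diagnoses(tibble(term_id = map_chr(d, "term_id"),
                              is_primary = map_lgl(d, "is_primary")))
    } else ""
    base <- r[setdiff(names(r), c("indicators", "diagnoses"))]
    ind <- setNames(rep(NA_real_, length(ind_names)), ind_names)
    if (length(r$indicators) > 0) ind[names(r$indicators)] <- unlist(r$indicators)
    c(base, list(diagnoses = diag_str), as.list(ind))
  })
  coerce_cohort_types(bind_rows(map(rows, as_tibble)))
}

#' Write an ontology as a TSV edge list (plus labels)
#'
#' @param onto A [ontology()] object.
#' @param path Edge-list path (`child_id<TAB>parent_id`).
#' @param labels_path Optional labels TSV (`term_id<TAB>label`).
#' @export
write_ontology_tsv <- function(onto, path, labels_path = NULL) {
  edges <- purrr::imap_dfr(onto$parents, function(ps, child) {
    if (length(ps) == 0) return(tibble(child_id = character(), parent_id = character()))
    tibble(child_id = child, parent_id = ps)
  })
  write.table(edges, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  if (!is.null(labels_path)) {
    write.table(onto$terms[, c("term_id", "label")], labels_path, sep = "\t",
                quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Write a complete synthetic fixture set
#'
#' Cohort as CSV and JSON-lines, ontology as TSV edge list with labels, and
#' an echo of the generating specification as JSON - exactly the formats the
#' package readers consume.
#'
#' @param cohort Cohort tibble.
#' @param onto A [ontology()].
#' @param dir Output directory (created if needed).
#' @param spec Optional [synthetic_spec()] echoed to `spec.json`.
#' @return Named paths of the written files.
#' @export
write_fixture <- function(cohort, onto, dir, spec = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    cohort_csv = file.path(dir, "cohort.csv"),
    cohort_jsonl = file.path(dir, "cohort.jsonl"),
    ontology = file.path(dir, "ontology.tsv"),
    labels = file.path(dir, "labels.tsv")
  )
  write_cohort_csv(cohort, paths[["cohort_csv"]])
  write_cohort_jsonl(cohort, paths[["cohort_jsonl"]])
  write_ontology_tsv(onto, paths[["ontology"]], paths[["labels"]])
  if (!is.null(spec)) {
    paths <- c(paths, spec = file.path(dir, "spec.json"))
    sp <- spec
    class(sp) <- NULL
    jsonlite::write_json(sp, paths[["spec"]], auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  }
  invisible(paths)
}

#' Read and validate a run configuration (YAML or JSON)
#'
#' Recognised keys: `weights.{indicator,diag,pre,surg}`,
#' `preprocessing.method`, `diagnosis.mode`, `diagnosis.alpha`, `phase`,
#' `criterion.k` / `criterion.threshold`, `task`, `k_grid`, `seed`. Unknown
#' keys are rejected; missing keys take package defaults.
#'
#' @param path Config file path, or `NULL` for all defaults.
#' @return A validated list of class `psn_config`.
#' @export
read_run_config <- function(path = NULL) {
  raw <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) psn_abort(paste0("config not found: ", path), "psn_io_error")
    raw <- if (grepl("\\.(ya?ml)$", path)) yaml::read_yaml(path) else
      jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
  known <- c("weights", "preprocessing", "diagnosis", "phase", "criterion",
             "task", "k_grid", "seed")
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    psn_abort(paste0("unknown config key(s): ", paste(unknown, collapse = ", ")),
              "psn_config_error")
  }
  cfg <- list(
    weights = do.call(weight_vector, modifyList(
      list(indicator = 1, diag = 1, pre = 1, surg = 1), raw$weights %||% list())),
    method = raw$preprocessing$method %||% "origin",
    mode = raw$diagnosis$mode %||% "ungrade",
    alpha = raw$diagnosis$alpha %||% 0.7,
    phase = raw$phase %||% "surgery",
    criterion = raw$criterion %||% list(k = 20),
    task = raw$task %||% "complication",
    k_grid = raw$k_grid %||% c(3, 5, 10, 15, 20, 30, 50, 75, 100, 150, 200),
    seed = as.integer(raw$seed %||% 1L)
  )
  if (!cfg$method %in% c("origin", "zscore", "combination")) {
    psn_abort("preprocessing.method must be origin|zscore|combination", "psn_config_error")
  }
  if (!cfg$mode %in% c("ungrade", "grade")) {
    psn_abort("diagnosis.mode must be ungrade|grade", "psn_config_error")
  }
  if (!cfg$phase %in% c("screening", "echo", "patient", "surgery")) {
    psn_abort("phase must be screening|echo|patient|surgery", "psn_config_error")
  }
  structure(cfg, class = "psn_config")
}

write_resolved_config <- function(cfg, path) {
  out <- unclass(cfg)
  out$weights <- as.list(unclass(out$weights))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
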