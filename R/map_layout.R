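# Deterministic 31-bit string hash (Horner scheme) for per-point seeding.
id_hash <- function(x) {
  vapply(x, function(s) {
    h <- 0
    for (code in utf8ToInt(s)) h <- (h * 31 + code) %% 2147483647
    h
  }, numeric(1))
}

# Conditional-probability row for t-SNE: binary search the Gaussian precision
# so the row entropy matches log(perplexity).
tsne_p_row <- function(d2, perplexity, tol = 1e-5, max_tries = 50) {
  beta <- 1; beta_min <- -Inf; beta_max <- Inf
  target <- log(perplexity)
  for (i in seq_len(max_tries)) {
    p <- exp(-d2 * beta)
    sum_p <- sum(p)
    if (sum_p == 0) { h <- 0; p[] <- 0 } else {
      h <- log(sum_p) + beta * sum(d2 * p) / sum_p
      p <- p / sum_p
    }
    diff <- h - target
    if (abs(diff) < tol) break
    if (diff > 0) { beta_min <- beta; beta <- if (is.finite(beta_max)) (beta + beta_max) / 2 else beta * 2 }
    else { beta_max <- beta; beta <- if (is.finite(beta_min)) (beta + beta_min) / 2 else beta / 2 }
  }
  p
}

#' Embed a patient distance matrix into 2D with t-SNE
#'
#' t-distributed stochastic neighbour embedding run directly on the
#' precomputed fused distances (no re-featurisation): Gaussian input
#' affinities calibrated per point to the target perplexity, Student-t output
#' kernel, gradient descent with momentum, early exaggeration and adaptive
#' gains. Initial coordinates are drawn per point from a seed derived from
#' the patient id (combined with `seed`), and patients are processed in a
#' canonical id order, so the layout does not depend on cohort row order.
#'
#' @param psn A [build_psn()] object, or a symmetric distance matrix with
#'   patient ids as dimnames.
#' @param perplexity Target perplexity (default 30, capped at `(n - 1) / 3`);
#'   must be `< n`.
#' @param n_iter Gradient-descent iterations (default 1000).
#' @param seed Integer seed for the initialisation.
#' @param learning_rate Gradient step size.
#' @return A `psn_layout`: tibble `patient_id`, `x`, `y` (input row order)
#'   with the embedding parameters in attributes.
#' @export
tsne_embed <- function(psn, perplexity = 30, n_iter = 1000, seed = 1L,
                       learning_rate = 200) {
  D <- if (inherits(psn, "psn")) psn$values else as.matrix(psn)
  ids <- rownames(D) %||% as.character(seq_len(nrow(D)))
  n <- nrow(D)
  if (n < 4) psn_abort("need at least 4 patients to embed", "psn_precondition_error")
  if (perplexity >= n) psn_abort("perplexity must be smaller than the number of patients",
                                 "psn_parameter_error")
  perplexity <- min(perplexity, (n - 1) / 3)

  ord <- order(ids)
  D <- D[ord, ord]
  cids <- ids[ord]

  P <- matrix(0, n, n)
  D2 <- D^2
  for (i in seq_len(n)) {
    p <- tsne_p_row(D2[i, -i], perplexity)
    P[i, -i] <- p
  }
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, 1e-12)

  Y <- t(vapply(cids, function(id) {
    with_seed((id_hash(id) + as.numeric(seed) * 1e6) %% 2147483647,
              rnorm(2, sd = 1e-4))
  }, numeric(2)))

  dY <- matrix(0, n, 2)
  gains <- matrix(1, n, 2)
  momentum <- 0.5
  exaggeration <- 12
  for (iter in seq_len(n_iter)) {
    Peff <- if (iter <= 250) P * exaggeration else P
    sum_Y2 <- rowSums(Y^2)
    num <- 1 / (1 + outer(sum_Y2, sum_Y2, "+") - 2 * tcrossprod(Y))
    diag(num) <- 0
    Q <- pmax(num / sum(num), 1e-12)
    L <- (Peff - Q) * num
    grad <- 4 * (diag(rowSums(L)) - L) %*% Y
    gains <- pmax(ifelse(sign(grad) != sign(dY), gains + 0.2, gains * 0.8), 0.01)
    dY <- momentum * dY - learning_rate * gains * grad
    Y <- Y + dY
    Y <- sweep(Y, 2, colMeans(Y))
    if (iter == 250) momentum <- 0.8
  }

  back <- match(ids, cids)
  out <- tibble(patient_id = ids, x = Y[back, 1], y = Y[back, 2])
  attr(out, "params") <- list(perplexity = perplexity, n_iter = n_iter,
                              seed = as.integer(seed), learning_rate = learning_rate)
  attr(out, "fingerprint") <- c(n = n, sum = round(sum(D), 9))
  class(out) <- c("psn_layout", class(out))
  out
}

#' Plot a map layout coloured by an annotation
#'
#' @param object A [tsne_embed()] layout.
#' @param annotation Named vector (by `patient_id`) or tibble
#'   (`patient_id`, `annotation`) used for point colour; optional.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot psn_layout
#' @export
autoplot.psn_layout <- function(object, annotation = NULL, ...) {
  df <- as_tibble(object)
  if (!is.null(annotation)) {
    if (is.data.frame(annotation)) {
      ann <- setNames(annotation[[2]], annotation[[1]])
    } else {
      ann <- annotation
    }
    df$annotation <- ann[df$patient_id]
    ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, colour = .data$annotation)) +
      ggplot2::geom_point(alpha = 0.8) +
      ggplot2::labs(x = "t-SNE 1", y = "t-SNE 2", colour = NULL) +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y)) +
      ggplot2::geom_point(alpha = 0.8) +
      ggplot2::labs(x = "t-SNE 1", y = "t-SNE 2") +
      ggplot2::theme_minimal()
  }
}

#' @rdname autoplot.psn_layout
#' @param layout A [tsne_embed()] layout.
#' @export
plot_map <- function(layout, annotation = NULL) autoplot.psn_layout(layout, annotation)

#' Export a map layout as a scatter figure and a TSV
#'
#' @param layout A [tsne_embed()] layout.
#' @param annotations Tibble keyed by `patient_id`; `annotation_col` selects
#'   the colouring column.
#' @param annotation_col Column of `annotations` to colour by.
#' @param tsv_path,plot_path Output paths (`plot_path` optional; PNG or SVG
#'   by extension).
#' @return Invisibly, the tibble written to TSV (`patient_id`, `x`, `y`,
#'   `annotation`).
#' @export
export_layout <- function(layout, annotations, annotation_col, tsv_path,
                          plot_path = NULL) {
  annotations <- as_tibble(annotations)
  if (!annotation_col %in% names(annotations)) {
    psn_abort(paste0("unknown annotation column: ", annotation_col), "psn_reference_error")
  }
  df <- as_tibble(layout) %>%
    left_join(annotations %>%
                transmute(patient_id = as.character(.data$patient_id),
                          annotation = as.character(.data[[annotation_col]])),
              by = "patient_id")
  write.table(df, tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(plot_path)) {
    p <- autoplot.psn_layout(layout, annotation = setNames(df$annotation, df$patient_id))
    ggplot2::ggsave(plot_path, p, width = 6, height = 5, dpi = 120)
  }
  invisible(df)
}
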