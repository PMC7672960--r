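#' Default phenotype agreement thresholds
#'
#' Agreement windows for the non-imaging measures gating the population
#' graph: sex 1 (an equality test for 0/1 coding), age 2 years, MMSE 2
#' points.
#'
#' @return Named numeric vector `c(sex = 1, age = 2, mmse = 2)`.
#' @export
default_epsilons <- function() c(sex = 1, age = 2, mmse = 2)

#' Imaging similarity between two subjects
#'
#' Gaussian kernel on the correlation distance between feature vectors:
#' `exp(-l^2 / (2 sigma^2))` with `l = 1 - Pearson(f_i, f_j)`. Identical
#' (non-constant) vectors give 1; anti-correlated vectors give
#' `exp(-2/sigma^2)`.
#'
#' @param f_i,f_j Equal-length feature vectors with nonzero variance.
#' @param sigma Kernel width, > 0.
#' @return Similarity in (0, 1].
#' @export
correlation_similarity <- function(f_i, f_j, sigma = 1) {
  if (length(f_i) != length(f_j)) {
    abort("Feature vectors differ in length.", class = "braingcn_data_error")
  }
  if (sigma <= 0) {
    abort("`sigma` must be positive.", class = "braingcn_config_error")
  }
  if (sd(f_i) == 0 || sd(f_j) == 0) {
    abort("Zero-variance feature vector; correlation distance undefined.",
          class = "braingcn_data_error")
  }
  l <- 1 - cor(f_i, f_j)
  exp(-l^2 / (2 * sigma^2))
}

#' Phenotype agreement indicator
#'
#' 1 when two subjects' values of a non-imaging measure lie strictly
#' within `eps` of each other, 0 otherwise. With `eps = 1` on 0/1-coded
#' sex this is an equality test.
#'
#' @param h_i,h_j Numeric phenotype codes (vectorized).
#' @param eps Agreement window, > 0.
#' @return Integer 0/1, same length as the inputs.
#' @export
phenotype_agreement <- function(h_i, h_j, eps) {
  if (any(eps <= 0)) {
    abort("`eps` must be positive.", class = "braingcn_config_error")
  }
  if (anyNA(h_i) || anyNA(h_j)) {
    abort("Missing phenotype values are not imputed; remove the subject.",
          class = "braingcn_data_error")
  }
  as.integer(abs(h_i - h_j) < eps)
}

#' Build the population (subject) graph
#'
#' Every subject is a node carrying its combined feature vector. The
#' adjacency between subjects i and j is the imaging similarity
#' [correlation_similarity()] multiplied by the number of non-imaging
#' measures (sex, age, MMSE by default) on which the two subjects agree
#' within their epsilon windows — so subjects who disagree on every
#' measure are disconnected no matter how similar their imaging features
#' look, and the maximum weight is the number of measures D. The
#' diagonal is 0; self-similarity is handled by the GCN's Laplacian, not
#' here.
#'
#' @param features A `feature_matrix` (modality `"C"`) or numeric matrix
#'   with >= 2 columns, one row per subject.
#' @param phenotypes Tibble/data frame with `subject_id` and one column
#'   per measure named in `epsilons`.
#' @param labels Class labels per subject (factor, NC/EMCI).
#' @param labelled_mask Logical vector marking training (labelled)
#'   nodes; defaults to all labelled.
#' @param sigma Kernel width; `NULL` (default) uses the mean pairwise
#'   correlation distance over labelled-node pairs — a scale-free choice
#'   that adapts to the feature block at hand.
#' @param epsilons Named agreement windows, default [default_epsilons()].
#' @return An object of class `subject_graph`: adjacency `C` (N-by-N,
#'   entries in [0, D]), `features`, `phenotypes`, `labels`, `mask`,
#'   `sigma`.
#' @export
build_subject_graph <- function(features, phenotypes, labels,
                                labelled_mask = NULL, sigma = NULL,
                                epsilons = default_epsilons()) {
  fm <- if (inherits(features, "feature_matrix")) features$values
        else as.matrix(features)
  n <- nrow(fm)
  if (ncol(fm) < 2) {
    abort("Need at least 2 features per subject for correlation similarity.",
          class = "braingcn_data_error")
  }
  if (!is.null(sigma) && sigma <= 0) {
    abort("`sigma` must be positive.", class = "braingcn_config_error")
  }
  if (is.null(labelled_mask)) labelled_mask <- rep(TRUE, n)
  stopifnot(nrow(phenotypes) == n, length(labels) == n,
            length(labelled_mask) == n)
  measures <- names(epsilons)
  missing_cols <- setdiff(measures, names(phenotypes))
  if (length(missing_cols)) {
    abort(paste0("Phenotype table lacks column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "braingcn_data_error")
  }
  ph <- as.matrix(as.data.frame(phenotypes)[measures])
  if (anyNA(ph)) {
    bad <- unique(which(is.na(ph), arr.ind = TRUE)[, 1])
    abort(paste0("Missing phenotype values for subject(s): ",
                 paste(head(phenotypes$subject_id[bad], 5), collapse = ", ")),
          class = "braingcn_data_error")
  }
  v <- apply(fm, 1, sd)
  if (any(v == 0)) {
    abort(paste0("Zero-variance feature vector for subject(s): ",
                 paste(head(rownames(fm)[v == 0], 5), collapse = ", ")),
          class = "braingcn_data_error")
  }

  corr_dist <- 1 - cor(t(fm))
  if (is.null(sigma)) {
    tr_pairs <- corr_dist[labelled_mask, labelled_mask, drop = FALSE]
    sigma <- mean(tr_pairs[upper.tri(tr_pairs)])
    if (!is.finite(sigma) || sigma <= 0) sigma <- 1
  }
  corr_sim <- exp(-corr_dist^2 / (2 * sigma^2))

  gates <- matrix(0, n, n)
  for (d in measures) {
    hd <- ph[, d]
    gates <- gates +
      (abs(outer(hd, hd, "-")) < epsilons[[d]])
  }
  C <- corr_sim * gates
  C <- (C + t(C)) / 2
  diag(C) <- 0
  dimnames(C) <- list(rownames(fm), rownames(fm))

  structure(list(C = C, features = fm, phenotypes = phenotypes,
                 labels = labels, mask = labelled_mask, sigma = sigma,
                 epsilons = epsilons),
            class = "subject_graph")
}

#' @export
print.subject_graph <- function(x, ...) {
  cat("<subject_graph> ", nrow(x$C), " subjects, ",
      sum(x$mask), " labelled, sigma = ", format(x$sigma, digits = 4),
      ", density = ",
      format(mean(x$C[upper.tri(x$C)] > 0), digits = 3), "\n", sep = "")
  invisible(x)
}

#' @export
autoplot.subject_graph <- function(object, ...) {
  n <- nrow(object$C)
  df <- tidyr::expand_grid(i = seq_len(n), j = seq_len(n))
  df$weight <- as.numeric(object$C[cbind(df$i, df$j)])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$j, y = .data$i,
                                   fill = .data$weight)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(limits = c(0, length(object$epsilons))) +
    ggplot2::labs(x = "subject", y = "subject", fill = "edge weight",
                  title = "Population-graph adjacency") +
    ggplot2::theme_minimal()
}
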