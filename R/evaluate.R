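#' Cross-validation plan
#'
#' @param n_folds Folds per repeat (default 5).
#' @param n_repeats Repeats of the whole CV (default 5 at desk scale; 50
#'   matches the full evaluation protocol).
#' @param seed Seed driving every split.
#' @return An object of class `cv_plan`.
#' @export
cv_plan <- function(n_folds = 5L, n_repeats = 5L, seed = 1L) {
  stopifnot(n_folds >= 2, n_repeats >= 1)
  structure(list(n_folds = as.integer(n_folds),
                 n_repeats = as.integer(n_repeats),
                 seed = as.integer(seed)),
            class = "cv_plan")
}

#' Stratified fold assignment
#'
#' Subjects are shuffled within class (seeded) and dealt round-robin, so
#' each fold's class ratio is within one subject of the global ratio.
#'
#' @param labels Class labels (coerced to factor).
#' @param n_folds Number of folds.
#' @param seed Split seed.
#' @return Integer fold ids, one per subject.
#' @export
make_folds <- function(labels, n_folds = 5L, seed = 1L) {
  labels <- as.factor(labels)
  if (any(table(labels) < n_folds)) {
    abort("Each class needs at least `n_folds` subjects for stratified folds.",
          class = "braingcn_data_error")
  }
  folds <- integer(length(labels))
  withr::with_seed(seed, {
    for (cls in levels(labels)) {
      idx <- which(labels == cls)
      idx <- sample(idx)
      folds[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
  })
  folds
}

#' Classification metrics with EMCI as the positive class
#'
#' ACC = (TP+TN)/N, SEN = TP/(TP+FN), SPE = TN/(TN+FP), and AUC from the
#' rank-sum (Mann-Whitney) statistic with average ranks, so tied scores
#' earn half credit.
#'
#' @param y_true True labels (factor; second level, or `positive`, is the
#'   positive class).
#' @param y_pred Predicted labels.
#' @param scores Positive-class scores for AUC (optional).
#' @param positive Positive-class label (default `"EMCI"` when present,
#'   else the second factor level).
#' @return One-row tibble with `acc`, `sen`, `spe`, `auc`. A class absent
#'   from `y_true` leaves its rate `NaN` with a warning.
#' @export
classification_metrics <- function(y_true, y_pred, scores = NULL,
                                   positive = NULL) {
  y_true <- as.factor(y_true)
  if (is.null(positive)) {
    positive <- if ("EMCI" %in% levels(y_true)) "EMCI"
                else levels(y_true)[nlevels(y_true)]
  }
  pos <- as.character(y_true) == positive
  pred_pos <- as.character(y_pred) == positive
  tp <- sum(pos & pred_pos); fn <- sum(pos & !pred_pos)
  tn <- sum(!pos & !pred_pos); fp <- sum(!pos & pred_pos)
  acc <- (tp + tn) / length(pos)
  sen <- if (tp + fn > 0) tp / (tp + fn) else NaN
  spe <- if (tn + fp > 0) tn / (tn + fp) else NaN
  if (is.nan(sen) || is.nan(spe)) {
    warn("A class is absent from y_true; its rate is NaN and excluded from summaries.")
  }
  auc <- NA_real_
  if (!is.null(scores)) {
    n1 <- sum(pos); n0 <- sum(!pos)
    auc <- if (n1 > 0 && n0 > 0) {
      r <- rank(scores)
      (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
    } else NaN
  }
  tibble::tibble(acc = acc, sen = sen, spe = spe, auc = auc)
}

#' Bundle a dataset for cross-validated evaluation
#'
#' @param gmv,spl `feature_matrix` objects (modalities GMV and SPL).
#' @param phenotypes Tibble with `subject_id`, `sex`, `age`, `mmse`.
#' @param labels Factor of class labels (levels NC, EMCI).
#' @return An object of class `braingcn_dataset`.
#' @export
braingcn_dataset <- function(gmv, spl, phenotypes, labels) {
  stopifnot(inherits(gmv, "feature_matrix"), inherits(spl, "feature_matrix"))
  ids <- gmv$subjects
  if (!identical(ids, spl$subjects) ||
      !identical(ids, phenotypes$subject_id)) {
    abort("Subject sets/order differ across GMV, SPL and phenotypes.",
          class = "braingcn_data_error")
  }
  labels <- factor(as.character(labels), levels = c("NC", "EMCI"))
  stopifnot(length(labels) == length(ids), !anyNA(labels))
  structure(list(gmv = gmv, spl = spl, phenotypes = phenotypes,
                 labels = labels, subjects = ids),
            class = "braingcn_dataset")
}

#' @export
print.braingcn_dataset <- function(x, ...) {
  cat("<braingcn_dataset> ", length(x$subjects), " subjects (",
      paste(table(x$labels), collapse = "/"), "), ",
      ncol(x$gmv$values), " GMV + ", ncol(x$spl$values),
      " SPL features\n", sep = "")
  invisible(x)
}

#' Convenience: dataset straight from a synthetic cohort
#'
#' @param cohort A [generate_cohort()] result.
#' @param scheme Brain-network scheme for the SPL features.
#' @return A [braingcn_dataset()].
#' @export
as_dataset <- function(cohort, scheme = "proportional:0.2") {
  feats <- extract_features(cohort, scheme = scheme)
  braingcn_dataset(feats$gmv, feats$spl, cohort$phenotypes, cohort$labels)
}

# Selection for one training split; returns per-modality index vectors
# plus bookkeeping. Falls back to the strongest rows when fewer than
# `min_features` survive, because the graph's correlation similarity
# needs at least two feature columns.
fit_selection <- function(x_list, y_train, selector, lambda_grid,
                          inner_folds, seed, min_features = 2L) {
  lambda <- NA_real_
  if (selector == "mtfs-glasso") {
    prob <- selection_problem(x_list, y_train)
    lambda <- choose_lambda(prob, grid = lambda_grid,
                            inner_folds = inner_folds, seed = seed)$lambda
    fit <- fit_mtfs_glasso(prob, lambda = lambda)
    sel <- fit$selected
    if (length(unique(unlist(sel))) < min_features) {
      rn <- sqrt(rowSums(fit$W^2))
      top <- order(rn, decreasing = TRUE)[seq_len(min_features)]
      sel <- lapply(sel, function(s) sort(top))
    }
  } else if (selector == "ttest") {
    sel <- alt_select_ttest(x_list, y_train)
  } else if (selector == "lasso") {
    sel <- alt_select_lasso(x_list, y_train, seed = seed)
  } else {
    abort(paste0("Unknown selector: ", selector),
          class = "braingcn_config_error")
  }
  if (length(unique(unlist(sel))) < min_features) {
    # degenerate selection: keep every feature rather than an empty graph
    warn(paste0("Selector `", selector, "` kept fewer than ", min_features,
                " features; falling back to all features for this fold."))
    sel <- lapply(sel, function(s) seq_len(ncol(x_list[[1]])))
  }
  list(selected = sel, lambda = lambda)
}

#' Repeated stratified cross-validation of the full pipeline
#'
#' Per fold, strictly on training subjects: feature scaling is fitted,
#' the regularization weight is chosen by inner cross-validation, and
#' features are selected. One transductive population graph is then
#' built over all subjects — test nodes contribute features but their
#' labels are masked — the GCN is trained on the labelled nodes, and the
#' test nodes are scored. Per-fold fitted-on and test ids are recorded
#' so train/test disjointness can be audited after the fact.
#'
#' @param dataset A [braingcn_dataset()].
#' @param plan A [cv_plan()].
#' @param selector `"mtfs-glasso"` (default), `"ttest"` or `"lasso"`.
#' @param lambda_grid Grid for [choose_lambda()] (default 0, 5, ..., 100).
#' @param inner_folds Inner folds for the lambda choice.
#' @param epsilons Phenotype agreement windows ([default_epsilons()]).
#' @param sigma Kernel width; `NULL` recomputes it per fold from
#'   training-node pairs.
#' @param hyper A [gcn_hyperparams()].
#' @return An object of class `cv_report`: per-fold metrics tibble
#'   (`folds`), summary tibble, leakage-audit records, and the
#'   configuration used.
#' @export
run_cv <- function(dataset, plan = cv_plan(),
                   selector = c("mtfs-glasso", "ttest", "lasso"),
                   lambda_grid = seq(0, 100, by = 5), inner_folds = 3L,
                   epsilons = default_epsilons(), sigma = NULL,
                   hyper = gcn_hyperparams()) {
  stopifnot(inherits(dataset, "braingcn_dataset"), inherits(plan, "cv_plan"))
  selector <- match.arg(selector)
  labels <- dataset$labels
  ids <- dataset$subjects
  rows <- list()
  audits <- list()
  for (r in seq_len(plan$n_repeats)) {
    folds <- make_folds(labels, n_folds = plan$n_folds,
                        seed = plan$seed + 7919L * r)
    for (f in seq_len(plan$n_folds)) {
      train <- folds != f
      if (length(unique(labels[train])) < 2) {
        abort(sprintf("Repeat %d fold %d has a single-class training set.",
                      r, f), class = "braingcn_data_error")
      }
      fold_seed <- (plan$seed + 104729L * r + 1299709L * f) %% 2147483647L

      sc_gmv <- fit_scaler(subset_rows(dataset$gmv, train))
      sc_spl <- fit_scaler(subset_rows(dataset$spl, train))
      gmv_s <- apply_scaler(sc_gmv, dataset$gmv)
      spl_s <- apply_scaler(sc_spl, dataset$spl)

      x_train <- list(gmv = gmv_s$values[train, , drop = FALSE],
                      spl = spl_s$values[train, , drop = FALSE])
      selres <- fit_selection(x_train, labels[train], selector,
                              lambda_grid, inner_folds, fold_seed)
      f_c <- concatenate_selected(
        subset_selected(gmv_s, selres$selected[[1]]),
        subset_selected(spl_s, selres$selected[[2]]))

      graph <- build_subject_graph(f_c, dataset$phenotypes, labels,
                                   labelled_mask = train, sigma = sigma,
                                   epsilons = epsilons)
      hy <- hyper
      hy$seed <- fold_seed
      model <- train_gcn(graph, hy)
      pred <- predict_gcn(model, graph)
      test_idx <- pred$node
      met <- classification_metrics(labels[test_idx], pred$predicted,
                                    scores = pred$score)
      rows[[length(rows) + 1L]] <- dplyr::bind_cols(
        tibble::tibble(repeat_ = r, fold = f,
                       lambda = selres$lambda,
                       n_selected = ncol(f_c$values)),
        met)
      audits[[length(audits) + 1L]] <- tibble::tibble(
        repeat_ = r, fold = f,
        fitted_on = list(sort(ids[train])),
        scaler_fitted_on = list(sort(sc_gmv$fitted_on)),
        test_ids = list(sort(ids[!train])))
    }
  }
  folds_tbl <- dplyr::bind_rows(rows)
  summary_tbl <- folds_tbl |>
    tidyr::pivot_longer(dplyr::all_of(c("acc", "sen", "spe", "auc")),
                        names_to = "metric", values_to = "value") |>
    dplyr::group_by(.data$metric) |>
    dplyr::summarise(mean = mean(.data$value, na.rm = TRUE),
                     sd = sd(.data$value, na.rm = TRUE),
                     .groups = "drop")
  structure(list(folds = folds_tbl, summary = summary_tbl,
                 audit = dplyr::bind_rows(audits),
                 config = list(plan = plan, selector = selector,
                               lambda_grid = lambda_grid,
                               inner_folds = inner_folds,
                               epsilons = epsilons, sigma = sigma,
                               hyper = hyper)),
            class = "cv_report")
}

subset_rows <- function(fm, keep) {
  feature_matrix(fm$values[keep, , drop = FALSE], fm$modality,
                 provenance = fm$provenance)
}

#' Audit a cross-validation report for train/test leakage
#'
#' Checks, fold by fold, that the subject ids the scalers and selectors
#' were fitted on are disjoint from the test ids.
#'
#' @param report A [run_cv()] result.
#' @return `TRUE` invisibly if clean; otherwise aborts naming the fold.
#' @export
audit_leakage <- function(report) {
  stopifnot(inherits(report, "cv_report"))
  for (i in seq_len(nrow(report$audit))) {
    row <- report$audit[i, ]
    overlap <- union(
      intersect(row$fitted_on[[1]], row$test_ids[[1]]),
      intersect(row$scaler_fitted_on[[1]], row$test_ids[[1]]))
    if (length(overlap)) {
      abort(sprintf("Leakage in repeat %d fold %d: %s",
                    row$repeat_, row$fold,
                    paste(head(overlap, 5), collapse = ", ")),
            class = "braingcn_leakage_error")
    }
  }
  invisible(TRUE)
}

#' @export
print.cv_report <- function(x, ...) {
  cat("<cv_report> ", max(x$folds$repeat_), " repeat(s) x ",
      max(x$folds$fold), " folds, selector = ", x$config$selector, "\n",
      sep = "")
  print(x$summary)
  invisible(x)
}

#' @export
tidy.cv_report <- function(x, ...) x$summary

#' @export
glance.cv_report <- function(x, ...) {
  wide <- stats::setNames(x$summary$mean, x$summary$metric)
  tibble::tibble(acc = wide[["acc"]], sen = wide[["sen"]],
                 spe = wide[["spe"]], auc = wide[["auc"]],
                 n_folds = x$config$plan$n_folds,
                 n_repeats = x$config$plan$n_repeats,
                 selector = x$config$selector)
}

#' @export
autoplot.cv_report <- function(object, ...) {
  long <- tidyr::pivot_longer(object$folds,
                              dplyr::all_of(c("acc", "sen", "spe", "auc")),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = toupper(.data$metric),
                                     y = .data$value)) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = "grey85") +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.5, size = 1) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "value",
                  title = "Cross-validated classification performance",
                  subtitle = paste0(object$config$plan$n_repeats,
                                    " repeats of ",
                                    object$config$plan$n_folds,
                                    "-fold stratified CV")) +
    ggplot2::theme_minimal()
}

#' Demographic group tests
#'
#' Chi-square test (2x2, with continuity correction) for sex; two-sample
#' t-tests (equal variances by default) for age and MMSE.
#'
#' @param phenotypes Tibble with `sex`, `age`, `mmse`.
#' @param labels Two-class factor.
#' @param var_equal Pooled-variance t-test (default `TRUE`).
#' @return Tibble with `measure`, `test`, `statistic`, `p_value`.
#' @export
demographics_tests <- function(phenotypes, labels, var_equal = TRUE) {
  labels <- as.factor(labels)
  if (nlevels(droplevels(labels)) != 2) {
    abort("Exactly two groups are required.", class = "braingcn_data_error")
  }
  g1 <- labels == levels(labels)[1]
  chs <- suppressWarnings(chisq.test(table(phenotypes$sex, labels)))
  tt_age <- t.test(phenotypes$age[g1], phenotypes$age[!g1],
                   var.equal = var_equal)
  tt_mmse <- t.test(phenotypes$mmse[g1], phenotypes$mmse[!g1],
                    var.equal = var_equal)
  tibble::tibble(
    measure = c("sex", "age", "mmse"),
    test = c("chi-square", "t-test", "t-test"),
    statistic = c(unname(chs$statistic), unname(tt_age$statistic),
                  unname(tt_mmse$statistic)),
    p_value = c(chs$p.value, tt_age$p.value, tt_mmse$p.value)
  )
}
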