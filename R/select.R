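#' Multi-task group-LASSO selection problem
#'
#' Bundles the per-task design matrices (here typically T = 2: scaled
#' grey-matter-volume and shortest-path-length features), the shared
#' label vector coded -1/+1, and the regularization weight for the
#' objective
#' \deqn{\min_W \sum_t \|y - X_t w_t\|_2^2 + \lambda \|W\|_{2,1},}
#' where the l2,1 norm sums the Euclidean norms of the rows of the P-by-T
#' matrix W, zeroing whole rows and thereby selecting features jointly
#' across tasks.
#'
#' @param x_list List of T numeric matrices, all N-by-P.
#' @param y Labels: a factor (second level = positive), a -1/+1 numeric
#'   vector, or 0/1.
#' @param lambda Nonnegative regularization weight.
#' @return An object of class `selection_problem`.
#' @export
selection_problem <- function(x_list, y, lambda = 0) {
  if (inherits(x_list, "feature_matrix")) x_list <- list(x_list)
  x_list <- lapply(x_list, function(x) {
    if (inherits(x, "feature_matrix")) x$values else as.matrix(x)
  })
  dims <- vapply(x_list, dim, integer(2))
  if (length(unique(dims[1, ])) != 1 || length(unique(dims[2, ])) != 1) {
    abort("All task matrices must share N and P.",
          class = "braingcn_data_error")
  }
  y <- code_labels(y)
  if (length(y) != dims[1, 1]) {
    abort("Label length does not match the number of rows.",
          class = "braingcn_data_error")
  }
  if (lambda < 0) {
    abort("`lambda` must be nonnegative.", class = "braingcn_config_error")
  }
  structure(list(x_list = x_list, y = y, lambda = lambda,
                 n = dims[1, 1], p = dims[2, 1], n_tasks = length(x_list)),
            class = "selection_problem")
}

code_labels <- function(y) {
  if (is.factor(y)) return(ifelse(y == levels(y)[2], 1, -1))
  if (is.character(y)) return(code_labels(factor(y, levels = sort(unique(y)))))
  u <- sort(unique(y))
  if (identical(u, c(0, 1))) return(2 * y - 1)
  if (!all(y %in% c(-1, 1))) {
    abort("Labels must be a factor, 0/1, or -1/+1.",
          class = "braingcn_data_error")
  }
  as.numeric(y)
}

#' Evaluate the group-LASSO objective
#'
#' @param W P-by-T numeric matrix.
#' @param problem A [selection_problem()].
#' @param lambda Override of the problem's lambda.
#' @return List with `objective`, `loss` (summed squared residuals across
#'   tasks) and `penalty` (lambda times the l2,1 norm).
#' @export
glasso_objective <- function(W, problem, lambda = problem$lambda) {
  stopifnot(inherits(problem, "selection_problem"))
  W <- as.matrix(W)
  stopifnot(nrow(W) == problem$p, ncol(W) == problem$n_tasks)
  if (lambda < 0) {
    abort("`lambda` must be nonnegative.", class = "braingcn_config_error")
  }
  loss <- sum(vapply(seq_len(problem$n_tasks), function(t) {
    r <- problem$y - problem$x_list[[t]] %*% W[, t]
    sum(r^2)
  }, numeric(1)))
  penalty <- lambda * sum(sqrt(rowSums(W^2)))
  list(objective = loss + penalty, loss = loss, penalty = penalty)
}

# Row-wise group soft-threshold: prox of thr * ||.||_{2,1}.
row_soft_threshold <- function(M, thr) {
  rn <- sqrt(rowSums(M^2))
  scale <- ifelse(rn > 0, pmax(0, 1 - thr / rn), 0)
  M * scale
}

#' The smallest lambda that zeroes the whole solution
#'
#' From the zero-subgradient condition at W = 0: the row-wise norm of the
#' stacked gradients 2 X_t' y must not exceed lambda, so
#' `lambda_max = 2 max_p || (X_1'y)_p, ..., (X_T'y)_p ||_2`.
#'
#' @param problem A [selection_problem()].
#' @return Scalar lambda_max.
#' @export
glasso_lambda_max <- function(problem) {
  g <- vapply(problem$x_list, function(x) drop(crossprod(x, problem$y)),
              numeric(problem$p))
  2 * max(sqrt(rowSums(as.matrix(g)^2)))
}

#' Fit the l2,1 multi-task group LASSO
#'
#' Accelerated proximal-gradient (FISTA) minimization with a row-wise
#' group soft-threshold proximal step and a monotone safeguard: whenever
#' the accelerated candidate would raise the objective, a plain proximal
#' step from the current iterate is taken instead, so the recorded
#' objective trace is non-increasing. The step size is 1/L with
#' L = 2 max_t sigma_max(X_t)^2, the Lipschitz constant of the smooth
#' part (the loss separates over tasks).
#'
#' @param problem A [selection_problem()].
#' @param lambda Optional override of the problem's lambda.
#' @param tol Relative objective change declaring convergence.
#' @param max_iter Iteration cap; hitting it flags the fit non-converged.
#' @param w_init Optional P-by-T warm start.
#' @param select_tol Magnitude below which a weight counts as zero when
#'   reading off the selected features.
#' @return An object of class `mtfs_glasso` with `W`, `objective_trace`,
#'   `selected` (per-task index lists), `lambda`, `converged`,
#'   `iterations`.
#' @export
fit_mtfs_glasso <- function(problem, lambda = NULL, tol = 1e-9,
                            max_iter = 5000L, w_init = NULL,
                            select_tol = 1e-8) {
  stopifnot(inherits(problem, "selection_problem"))
  if (!is.null(lambda)) problem$lambda <- lambda
  lam <- problem$lambda
  p <- problem$p; tt <- problem$n_tasks
  lip <- 2 * max(vapply(problem$x_list,
                        function(x) norm(x, type = "2")^2, numeric(1)))
  if (lip == 0) lip <- 1
  step <- 1 / lip

  grad <- function(V) {
    vapply(seq_len(tt), function(t) {
      x <- problem$x_list[[t]]
      drop(2 * crossprod(x, x %*% V[, t] - problem$y))
    }, numeric(p))
  }

  W <- if (is.null(w_init)) matrix(0, p, tt) else as.matrix(w_init)
  Z <- W
  tk <- 1
  obj <- glasso_objective(W, problem, lam)$objective
  trace <- obj
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    W_new <- row_soft_threshold(Z - step * grad(Z), step * lam)
    obj_new <- glasso_objective(W_new, problem, lam)$objective
    if (obj_new > obj) {
      # monotone safeguard: fall back to a plain proximal step at W
      W_new <- row_soft_threshold(W - step * grad(W), step * lam)
      obj_new <- glasso_objective(W_new, problem, lam)$objective
      tk <- 1
    }
    tk_new <- (1 + sqrt(1 + 4 * tk^2)) / 2
    Z <- W_new + ((tk - 1) / tk_new) * (W_new - W)
    tk <- tk_new
    rel <- abs(obj - obj_new) / max(1, abs(obj))
    W <- W_new
    obj <- min(obj, obj_new)
    trace <- c(trace, obj)
    if (rel < tol) { converged <- TRUE; break }
  }
  rownames(W) <- colnames(problem$x_list[[1]])
  fit <- structure(
    list(W = W, objective_trace = trace, lambda = lam,
         converged = converged, iterations = iter,
         task_names = names(problem$x_list) %||%
           paste0("task", seq_len(tt))),
    class = "mtfs_glasso")
  fit$selected <- select_features(fit, tol = select_tol)
  fit
}

#' Read selected features off a fitted discriminant matrix
#'
#' Feature p is selected for task t when |W[p, t]| exceeds `tol` — the
#' floating-point rendering of "non-zero". With the l2,1 penalty rows are
#' jointly zero or nonzero, so the per-task sets normally coincide.
#'
#' @param fit A [fit_mtfs_glasso()] result.
#' @param tol Zero threshold on |W| entries.
#' @return Named list of integer index vectors, one per task.
#' @export
select_features <- function(fit, tol = 1e-8) {
  stopifnot(inherits(fit, "mtfs_glasso"))
  sel <- lapply(seq_len(ncol(fit$W)),
                function(t) which(abs(fit$W[, t]) > tol))
  names(sel) <- fit$task_names
  sel
}

#' Regularization path with warm starts
#'
#' @param problem A [selection_problem()].
#' @param grid Increasing lambda grid.
#' @param ... Passed to [fit_mtfs_glasso()].
#' @return Tibble with one row per lambda: selected-row count, objective,
#'   convergence flag; fits attached as a list column.
#' @export
glasso_path <- function(problem, grid = seq(0, 100, by = 5), ...) {
  fits <- vector("list", length(grid))
  w <- NULL
  for (i in seq_along(grid)) {
    fits[[i]] <- fit_mtfs_glasso(problem, lambda = grid[i], w_init = w, ...)
    w <- fits[[i]]$W
  }
  tibble::tibble(
    lambda = grid,
    n_selected = vapply(fits, function(f)
      length(unique(unlist(f$selected))), integer(1)),
    objective = vapply(fits, function(f)
      f$objective_trace[length(f$objective_trace)], numeric(1)),
    converged = vapply(fits, `[[`, logical(1), "converged"),
    fit = fits
  )
}

# Least-squares linear scorer on the concatenated selected columns;
# used only to rank lambdas in the inner CV.
ls_score <- function(x_train, y_train, x_val) {
  xt <- cbind(1, x_train)
  b <- tryCatch(qr.coef(qr(xt), y_train), error = function(e) NULL)
  if (is.null(b)) return(rep(0, nrow(x_val)))
  b[is.na(b)] <- 0
  drop(cbind(1, x_val) %*% b)
}

#' Choose lambda by inner cross-validation
#'
#' For each lambda on the grid the group LASSO is fitted on the inner
#' training split (warm-started along the grid), the selected features
#' feed a least-squares linear scorer, and validation accuracy is
#' averaged over inner folds. The lambda maximizing mean accuracy wins;
#' ties go to the largest (sparsest) lambda. If every lambda selects
#' nothing, lambda = 0 is returned with a warning.
#'
#' @param problem A [selection_problem()] built on training subjects.
#' @param grid Candidate lambdas (default 0, 5, ..., 100).
#' @param inner_folds Number of inner folds (default 3).
#' @param seed Seed for the inner split.
#' @return List with `lambda` and the per-lambda `path` tibble
#'   (mean accuracy, mean selected count).
#' @export
choose_lambda <- function(problem, grid = seq(0, 100, by = 5),
                          inner_folds = 3L, seed = 1L) {
  stopifnot(inherits(problem, "selection_problem"), length(grid) >= 1)
  grid <- sort(unique(grid))
  if (length(grid) == 1) {
    return(list(lambda = grid,
                path = tibble::tibble(lambda = grid, accuracy = NA_real_,
                                      n_selected = NA_integer_)))
  }
  folds <- make_folds(factor(problem$y), n_folds = inner_folds, seed = seed)
  acc <- matrix(NA_real_, length(grid), inner_folds)
  nsel <- matrix(NA_integer_, length(grid), inner_folds)
  for (f in seq_len(inner_folds)) {
    tr <- folds != f
    sub <- selection_problem(lapply(problem$x_list, function(x) x[tr, , drop = FALSE]),
                             problem$y[tr])
    w <- NULL
    for (i in seq_along(grid)) {
      fit <- fit_mtfs_glasso(sub, lambda = grid[i], w_init = w,
                             tol = 1e-7, max_iter = 2000L)
      w <- fit$W
      sel <- sort(unique(unlist(fit$selected)))
      nsel[i, f] <- length(sel)
      if (!length(sel)) next
      xtr <- do.call(cbind, lapply(problem$x_list,
                                   function(x) x[tr, sel, drop = FALSE]))
      xva <- do.call(cbind, lapply(problem$x_list,
                                   function(x) x[!tr, sel, drop = FALSE]))
      sc <- ls_score(xtr, problem$y[tr], xva)
      acc[i, f] <- mean(sign(sc) == problem$y[!tr])
    }
  }
  mean_acc <- rowMeans(acc)
  path <- tibble::tibble(lambda = grid, accuracy = mean_acc,
                         n_selected = rowMeans(nsel))
  if (all(is.na(mean_acc))) {
    warn("Every lambda on the grid selected no features; falling back to lambda = 0.")
    return(list(lambda = 0, path = path))
  }
  best <- max(mean_acc, na.rm = TRUE)
  lam <- max(grid[!is.na(mean_acc) & mean_acc >= best - 1e-12])
  list(lambda = lam, path = path)
}

#' Univariate t-test feature selection (comparison backend)
#'
#' Per-feature two-sample t-test on training subjects; features with
#' p < `p_threshold` are kept, per modality.
#'
#' @param x_list List of N-by-P training matrices (one per modality).
#' @param labels Two-class labels (factor or -1/+1).
#' @param p_threshold Keep threshold on the p-value (default 0.1).
#' @return Named list of integer index vectors, one per modality.
#' @export
alt_select_ttest <- function(x_list, labels, p_threshold = 0.1) {
  if (!is.list(x_list)) x_list <- list(x_list)
  x_list <- lapply(x_list, function(x) {
    if (inherits(x, "feature_matrix")) x$values else as.matrix(x)
  })
  y <- code_labels(labels)
  if (min(table(y)) < 2) {
    abort("Each class needs at least 2 training subjects for t-tests.",
          class = "braingcn_data_error")
  }
  sel <- lapply(x_list, function(x) {
    p <- apply(x, 2, function(col) {
      if (sd(col[y == 1]) == 0 && sd(col[y == -1]) == 0) return(1)
      t.test(col[y == 1], col[y == -1], var.equal = TRUE)$p.value
    })
    which(p < p_threshold)
  })
  names(sel) <- names(x_list) %||% paste0("task", seq_along(sel))
  sel
}

#' Single-task LASSO feature selection (comparison backend)
#'
#' One l1-penalized least-squares fit per modality (coordinate descent
#' via glmnet, no intercept/standardization so the objective is the bare
#' penalized residual sum); features with nonzero weights are kept.
#'
#' @param x_list List of N-by-P training matrices (one per modality).
#' @param labels Two-class labels.
#' @param lambda Penalty per modality; `NULL` picks lambda.min by
#'   seeded cross-validation.
#' @param seed Seed for the internal CV split.
#' @return Named list of integer index vectors, one per modality.
#' @export
alt_select_lasso <- function(x_list, labels, lambda = NULL, seed = 1L) {
  if (!is.list(x_list)) x_list <- list(x_list)
  x_list <- lapply(x_list, function(x) {
    if (inherits(x, "feature_matrix")) x$values else as.matrix(x)
  })
  y <- code_labels(labels)
  sel <- lapply(x_list, function(x) {
    if (is.null(lambda)) {
      cv <- withr::with_seed(seed,
        glmnet::cv.glmnet(x, y, alpha = 1, nfolds = 5,
                          standardize = FALSE, intercept = FALSE))
      lam <- cv$lambda.min
      fitted <- cv$glmnet.fit
    } else {
      fitted <- glmnet::glmnet(x, y, alpha = 1, lambda = lambda,
                               standardize = FALSE, intercept = FALSE)
      lam <- lambda
    }
    b <- as.numeric(glmnet::coef.glmnet(fitted, s = lam))[-1]
    which(abs(b) > 1e-8)
  })
  names(sel) <- names(x_list) %||% paste0("task", seq_along(sel))
  sel
}

#' Concatenate the selected feature blocks
#'
#' Builds the combined representation: the selected grey-matter-volume
#' columns followed by the selected shortest-path-length columns, with
#' provenance recording which source columns each block came from.
#'
#' @param gmvs,spls `feature_matrix` objects holding the selected columns
#'   (modalities `GMVS` and `SPLS`, aligned subjects).
#' @return A `feature_matrix` with modality `"C"`.
#' @export
concatenate_selected <- function(gmvs, spls) {
  stopifnot(inherits(gmvs, "feature_matrix"), inherits(spls, "feature_matrix"))
  if (!identical(gmvs$subjects, spls$subjects)) {
    abort("Subject order differs between the two selected blocks.",
          class = "braingcn_data_error")
  }
  prefix <- function(p, m) {
    if (ncol(m) == 0) return(character(0))
    paste0(p, colnames(m) %||% seq_len(ncol(m)))
  }
  vals <- cbind(gmvs$values, spls$values)
  colnames(vals) <- c(prefix("gmv.", gmvs$values),
                      prefix("spl.", spls$values))
  feature_matrix(vals, "C",
                 provenance = list(gmv_columns = gmvs$feature_names,
                                   spl_columns = spls$feature_names,
                                   gmv_provenance = gmvs$provenance,
                                   spl_provenance = spls$provenance))
}

#' Keep selected columns of a feature matrix
#'
#' @param fm A `feature_matrix` (modality GMV or SPL).
#' @param idx Integer column indices to keep.
#' @return A `feature_matrix` with the selected-variant modality tag.
#' @export
subset_selected <- function(fm, idx) {
  stopifnot(inherits(fm, "feature_matrix"))
  modality <- switch(fm$modality, GMV = "GMVS", SPL = "SPLS", fm$modality)
  feature_matrix(fm$values[, idx, drop = FALSE], modality,
                 provenance = c(fm$provenance, list(selected = idx)))
}

#' @export
tidy.mtfs_glasso <- function(x, ...) {
  tibble::tibble(
    feature = rep(rownames(x$W) %||% as.character(seq_len(nrow(x$W))),
                  times = ncol(x$W)),
    task = rep(x$task_names, each = nrow(x$W)),
    weight = as.numeric(x$W),
    selected = as.numeric(abs(x$W)) > 1e-8
  )
}

#' @export
glance.mtfs_glasso <- function(x, ...) {
  tibble::tibble(
    lambda = x$lambda,
    n_selected = length(unique(unlist(x$selected))),
    objective = x$objective_trace[length(x$objective_trace)],
    iterations = x$iterations,
    converged = x$converged
  )
}

#' @export
print.mtfs_glasso <- function(x, ...) {
  cat("<mtfs_glasso> lambda = ", format(x$lambda), ", ",
      length(unique(unlist(x$selected))), "/", nrow(x$W),
      " features selected, ",
      if (x$converged) "converged" else "NOT converged",
      " in ", x$iterations, " iterations\n", sep = "")
  invisible(x)
}
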