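test_that("the objective evaluates exactly on hand-traceable cases", {
  pr <- random_problem(1, n = 4, p = 3, tt = 2)
  w0 <- matrix(0, 3, 2)
  expect_equal(glasso_objective(w0, pr, lambda = 7)$objective,
               2 * sum(pr$y^2))
  # lambda = 0: pure loss
  w <- matrix(c(0.5, -1, 2, 0, 3, -0.25), 3, 2)
  obj0 <- glasso_objective(w, pr, lambda = 0)
  expect_equal(obj0$objective, obj0$loss)
  expect_equal(obj0$penalty, 0)
  # long-hand arithmetic oracle
  loss <- sum((pr$y - pr$x_list[[1]] %*% w[, 1])^2) +
    sum((pr$y - pr$x_list[[2]] %*% w[, 2])^2)
  pen <- 3 * (sqrt(sum(w[1, ]^2)) + sqrt(sum(w[2, ]^2)) + sqrt(sum(w[3, ]^2)))
  expect_equal(glasso_objective(w, pr, lambda = 3)$objective, loss + pen,
               tolerance = 1e-12)
  expect_error(glasso_objective(w, pr, lambda = -1), "nonnegative")
})

test_that("the solver is exact in both penalty limits", {
  for (s in 1:5) {
    pr <- random_problem(100 + s)
    # above the analytic lambda_max the solution is exactly zero
    lam_max <- glasso_lambda_max(pr)
    fit <- fit_mtfs_glasso(pr, lambda = lam_max * (1 + 1e-10))
    expect_true(all(fit$W == 0))
    # unpenalized: per-task normal-equation least squares
    fit0 <- fit_mtfs_glasso(pr, lambda = 0, tol = 0, max_iter = 20000)
    for (t in 1:2) {
      x <- pr$x_list[[t]]
      wls <- solve(crossprod(x), crossprod(x, pr$y))
      expect_equal(unname(fit0$W[, t]), drop(wls), tolerance = 1e-8)
    }
  }
})

test_that("objective traces never increase and task order does not matter", {
  for (s in 1:5) {
    pr <- random_problem(200 + s, lambda = 10)
    fit <- fit_mtfs_glasso(pr)
    expect_true(all(diff(fit$objective_trace) <= 1e-10))
    swapped <- selection_problem(rev(pr$x_list), pr$y, lambda = 10)
    fit2 <- fit_mtfs_glasso(swapped)
    expect_equal(unname(fit$W[, 1]), unname(fit2$W[, 2]), tolerance = 1e-6)
    expect_equal(unname(fit$W[, 2]), unname(fit2$W[, 1]), tolerance = 1e-6)
  }
})

test_that("selection reads nonzero rows jointly across tasks", {
  pr <- random_problem(7)
  fit <- fit_mtfs_glasso(pr, lambda = glasso_lambda_max(pr) * 2)
  expect_equal(unname(lengths(fit$selected)), c(0L, 0L))
  fake <- fit
  fake$W <- matrix(0, 15, 2); fake$W[4, ] <- c(0.3, -0.2)
  sel <- select_features(fake)
  expect_equal(unname(sel[[1]]), 4L)
  expect_equal(unname(sel[[2]]), 4L)
  # moderate penalty: per-task sets coincide (row-wise zeros)
  fit2 <- fit_mtfs_glasso(pr, lambda = glasso_lambda_max(pr) * 0.5)
  expect_identical(unname(fit2$selected[[1]]), unname(fit2$selected[[2]]))
})

test_that("with one task the solver agrees with coordinate-descent LASSO", {
  for (s in 1:5) {
    withr::with_seed(300 + s, {
      n <- 50; p <- 15
      x <- matrix(rnorm(n * p), n, p)
      y <- sample(c(-1, 1), n, replace = TRUE)
    })
    lam <- 8
    pr <- selection_problem(list(x), y, lambda = lam)
    fit <- fit_mtfs_glasso(pr, tol = 1e-13, max_iter = 20000)
    # glmnet minimizes 1/(2N) RSS + lambda_g * l1; ours is RSS + lam * l1
    g <- glmnet::glmnet(x, y, alpha = 1, lambda = lam / (2 * n),
                        standardize = FALSE, intercept = FALSE,
                        thresh = 1e-14)
    b <- as.numeric(glmnet::coef.glmnet(g, s = lam / (2 * n)))[-1]
    o_ours <- glasso_objective(fit$W, pr)$objective
    o_glm <- glasso_objective(matrix(b, p, 1), pr)$objective
    expect_lt(abs(o_ours - o_glm) / abs(o_glm), 1e-6)
  }
})

test_that("selected-row counts shrink along a warm-started path", {
  pr <- random_problem(42, n = 60, p = 20, tt = 2)
  path <- glasso_path(pr, grid = seq(0, 100, by = 10))
  expect_true(all(diff(path$n_selected) <= 0))
  expect_true(all(path$converged))
})

test_that("choose_lambda prefers sparsity and finds planted signal", {
  pr <- random_problem(55)
  expect_equal(choose_lambda(pr, grid = 0)$lambda, 0)

  hits <- vapply(1:50, function(s) {
    inst <- planted_instance(400 + s, n = 120, snr = 6)
    choose_lambda(inst$problem, grid = seq(0, 100, by = 10),
                  inner_folds = 3, seed = s)$lambda > 0
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("t-test selection keeps shifted features at the stated rate", {
  withr::with_seed(60, {
    # null features: keep-rate near the p threshold
    rates <- vapply(1:40, function(s) {
      x <- matrix(rnorm(60 * 20), 60, 20)
      y <- rep(c(-1, 1), each = 30)
      length(alt_select_ttest(list(x), y)[[1]]) / 20
    }, numeric(1))
    expect_lt(abs(mean(rates) - 0.1), 0.05)
    # a planted shift is kept
    x <- matrix(rnorm(60 * 5), 60, 5)
    y <- rep(c(-1, 1), each = 30)
    x[y == 1, 3] <- x[y == 1, 3] + 2
    expect_true(3 %in% alt_select_ttest(list(x), y)[[1]])
  })
  expect_error(alt_select_ttest(list(matrix(rnorm(6), 3, 2)), c(-1, 1, 1)),
               "at least 2")
})

test_that("single-task LASSO selection spans its penalty limits", {
  withr::with_seed(61, {
    x <- matrix(rnorm(50 * 10), 50, 10)
    y <- sample(c(-1, 1), 50, replace = TRUE)
  })
  expect_equal(length(alt_select_lasso(list(x), y, lambda = 1e6)[[1]]), 0)
  expect_equal(length(alt_select_lasso(list(x), y, lambda = 1e-10)[[1]]), 10)
})

test_that("concatenation preserves block order and provenance", {
  withr::with_seed(62, {
    ids <- c("a", "b", "c")
    g <- matrix(rnorm(9), 3, 3, dimnames = list(ids, c("r1", "r2", "r3")))
    s <- matrix(rnorm(6), 3, 2, dimnames = list(ids, c("r4", "r5")))
  })
  fc <- concatenate_selected(feature_matrix(g, "GMVS"),
                             feature_matrix(s, "SPLS"))
  expect_equal(ncol(fc$values), 5)
  expect_equal(fc$modality, "C")
  expect_identical(fc$provenance$gmv_columns, c("r1", "r2", "r3"))
  expect_identical(fc$provenance$spl_columns, c("r4", "r5"))
  empty <- feature_matrix(g[, integer(0), drop = FALSE], "GMVS")
  expect_equal(ncol(concatenate_selected(empty,
                                         feature_matrix(s, "SPLS"))$values), 2)
})
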