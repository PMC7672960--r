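test_that("stratified folds partition subjects and balance classes", {
  labels <- factor(rep(c("NC", "EMCI"), each = 5), levels = c("NC", "EMCI"))
  f <- make_folds(labels, n_folds = 5, seed = 3)
  expect_equal(sort(unique(f)), 1:5)
  for (k in 1:5) {
    expect_equal(as.vector(table(labels[f == k])), c(1, 1))
  }
  expect_identical(f, make_folds(labels, n_folds = 5, seed = 3))
  expect_false(identical(f, make_folds(labels, n_folds = 5, seed = 4)))
  # class ratio within one subject of global for uneven sizes
  labs2 <- factor(c(rep("NC", 13), rep("EMCI", 9)), levels = c("NC", "EMCI"))
  f2 <- make_folds(labs2, n_folds = 4, seed = 1)
  tab <- table(labs2, f2)
  expect_true(all(abs(tab["NC", ] - 13 / 4) < 1))
  expect_true(all(abs(tab["EMCI", ] - 9 / 4) < 1))
  expect_error(make_folds(factor(c("NC", "EMCI")), n_folds = 5), "at least")
})

test_that("confusion-matrix metrics are exact arithmetic", {
  y_true <- factor(c(rep("EMCI", 50), rep("NC", 50)),
                   levels = c("NC", "EMCI"))
  y_pred <- factor(c(rep("EMCI", 40), rep("NC", 10),    # TP 40, FN 10
                     rep("EMCI", 15), rep("NC", 35)),   # FP 15, TN 35
                   levels = c("NC", "EMCI"))
  m <- classification_metrics(y_true, y_pred)
  expect_equal(m$acc, 0.75)
  expect_equal(m$sen, 0.80)
  expect_equal(m$spe, 0.70)
  # perfectly separating scores give AUC 1
  sc <- c(runif(50, 0.6, 1), runif(50, 0, 0.4))
  expect_equal(classification_metrics(y_true, y_pred, scores = sc)$auc, 1)
  # absent class flags NaN with a warning
  expect_warning(
    m2 <- classification_metrics(factor(rep("NC", 4), levels = c("NC", "EMCI")),
                                 factor(rep("NC", 4), levels = c("NC", "EMCI"))),
    "absent")
  expect_true(is.nan(m2$sen))
})

test_that("AUC equals the all-pairs Mann-Whitney oracle, ties included", {
  withr::with_seed(17, {
    for (i in 1:30) {
      n <- 12
      pos <- sample(c(TRUE, FALSE), n, replace = TRUE, prob = c(0.5, 0.5))
      if (!any(pos) || all(pos)) next
      scores <- sample(seq(0, 1, by = 0.25), n, replace = TRUE)  # forces ties
      y <- factor(ifelse(pos, "EMCI", "NC"), levels = c("NC", "EMCI"))
      m <- classification_metrics(y, y, scores = scores)
      expect_equal(m$auc, auc_pairs_oracle(scores, pos))
    }
  })
})

test_that("random scores give chance-level AUC on average", {
  withr::with_seed(18, {
    aucs <- vapply(1:200, function(i) {
      y <- factor(rep(c("NC", "EMCI"), each = 20), levels = c("NC", "EMCI"))
      classification_metrics(y, y, scores = runif(40))$auc
    }, numeric(1))
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.03)
})

test_that("repeated CV is deterministic, leak-free, and self-consistent", {
  coh <- tiny_cohort(seed = 71, n_per_class = 10, n_regions = 16,
                     n_timepoints = 30, d = 1.5)
  ds <- as_dataset(coh)
  plan <- cv_plan(n_folds = 5, n_repeats = 2, seed = 19)
  hy <- gcn_hyperparams(epochs = 80, n_hidden_layers = 2, hidden_width = 8)
  r1 <- run_cv(ds, plan, lambda_grid = c(0, 10, 20), hyper = hy)
  r2 <- run_cv(ds, plan, lambda_grid = c(0, 10, 20), hyper = hy)
  expect_equal(r1$folds, r2$folds)
  expect_true(audit_leakage(r1))
  expect_true(all(r1$folds$acc >= 0 & r1$folds$acc <= 1))
  # reported means equal the arithmetic mean of stored per-fold values
  expect_equal(r1$summary$mean[r1$summary$metric == "acc"],
               mean(r1$folds$acc))
  expect_equal(r1$summary$mean[r1$summary$metric == "auc"],
               mean(r1$folds$auc))
  # every fold recorded scaler provenance disjoint from its test set
  expect_equal(nrow(r1$audit), 10)
  g <- glance(r1)
  expect_equal(g$n_repeats, 2)
  expect_s3_class(autoplot(r1), "ggplot")
})

test_that("alternative selectors run through the same protocol", {
  coh <- tiny_cohort(seed = 72, n_per_class = 8, n_regions = 12,
                     n_timepoints = 25, d = 1.5)
  ds <- as_dataset(coh)
  plan <- cv_plan(n_folds = 4, n_repeats = 1, seed = 20)
  hy <- gcn_hyperparams(epochs = 50, n_hidden_layers = 2, hidden_width = 8)
  for (sel in c("ttest", "lasso")) {
    r <- suppressWarnings(run_cv(ds, plan, selector = sel, hyper = hy))
    expect_true(audit_leakage(r))
    expect_true(all(r$folds$auc >= 0 & r$folds$auc <= 1, na.rm = TRUE))
  }
})

test_that("demographic tests match hand formulas and detect shifts", {
  ph <- tibble::tibble(subject_id = as.character(1:8),
                       sex = c(1, 0, 1, 0, 1, 0, 1, 0),
                       age = c(70, 72, 68, 75, 70, 72, 68, 75),
                       mmse = c(29, 28, 27, 30, 29, 28, 27, 30))
  labels <- factor(rep(c("NC", "EMCI"), each = 4), levels = c("NC", "EMCI"))
  out <- demographics_tests(ph, labels)
  # identical groups duplicated: t = 0, p = 1
  expect_equal(out$statistic[out$measure == "age"], 0)
  expect_equal(out$p_value[out$measure == "age"], 1)
  expect_equal(out$p_value[out$measure == "mmse"], 1)

  # textbook 2x2 chi-square with continuity correction, hand formula
  ph2 <- tibble::tibble(
    subject_id = as.character(1:100),
    sex = c(rep(1, 30), rep(0, 20), rep(1, 15), rep(0, 35)),
    age = rnorm(100, 70), mmse = rnorm(100, 28))
  lab2 <- factor(rep(c("NC", "EMCI"), each = 50), levels = c("NC", "EMCI"))
  out2 <- demographics_tests(ph2, lab2)
  a <- 20; b <- 35; cc <- 30; d <- 15  # sex=0/1 by group
  nn <- 100
  hand <- nn * (abs(a * d - b * cc) - nn / 2)^2 /
    ((a + b) * (cc + d) * (a + cc) * (b + d))
  expect_equal(out2$statistic[out2$measure == "sex"], hand,
               tolerance = 1e-12)

  # planted 5-point MMSE shift at n = 105 per class: overwhelming evidence
  withr::with_seed(21, {
    ph3 <- tibble::tibble(subject_id = as.character(1:210),
                          sex = rbinom(210, 1, 0.5),
                          age = rnorm(210, 75, 6),
                          mmse = c(rnorm(105, 29, 1.5), rnorm(105, 24, 1.5)))
  })
  lab3 <- factor(rep(c("NC", "EMCI"), each = 105), levels = c("NC", "EMCI"))
  out3 <- demographics_tests(ph3, lab3)
  expect_lt(out3$p_value[out3$measure == "mmse"], 0.001)
})
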