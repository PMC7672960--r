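random_adjacency <- function(n, density = 0.4) {
  a <- matrix(0, n, n)
  ut <- which(upper.tri(a))
  on <- sample(ut, ceiling(density * length(ut)))
  a[on] <- runif(length(on), 0.1, 2)
  a + t(a)
}

toy_graph <- function(seed = 5, n = 6, f = 3) {
  withr::with_seed(seed, {
    feats <- matrix(rnorm(n * f), n, f,
                    dimnames = list(sprintf("s%d", seq_len(n)), NULL))
    C <- random_adjacency(n)
  })
  ph <- tibble::tibble(subject_id = rownames(feats),
                       sex = rep(1, n), age = rep(70, n), mmse = rep(29, n))
  labels <- factor(rep(c("NC", "EMCI"), length.out = n),
                   levels = c("NC", "EMCI"))
  g <- build_subject_graph(feats, ph, labels,
                           labelled_mask = seq_len(n) <= n - 2, sigma = 1)
  g$C <- C  # replace by the raw random adjacency for mechanics tests
  g
}

test_that("the normalized Laplacian has the expected spectrum", {
  expect_equal(normalized_laplacian(matrix(0, 4, 4)), diag(4))
  # 4-cycle: eigenvalues 0, 1, 1, 2
  ring <- matrix(0, 4, 4)
  ring[cbind(1:4, c(2, 3, 4, 1))] <- 1
  ring <- ring + t(ring)
  ev <- eigen(normalized_laplacian(ring), symmetric = TRUE)$values
  expect_equal(sort(ev), c(0, 1, 1, 2), tolerance = 1e-10)
  withr::with_seed(14, {
    for (i in 1:10) {
      L <- normalized_laplacian(random_adjacency(12))
      ev <- eigen(L, symmetric = TRUE, only.values = TRUE)$values
      expect_true(all(ev >= -1e-10 & ev <= 2 + 1e-10))
    }
  })
  expect_error(normalized_laplacian(matrix(1:9, 3, 3)), "symmetric")
})

test_that("rescaling maps the spectrum into [-1, 1]", {
  expect_equal(scale_laplacian(diag(3), lambda_max = 2), matrix(0, 3, 3))
  withr::with_seed(15, {
    for (i in 1:5) {
      L <- normalized_laplacian(random_adjacency(10))
      lt <- scale_laplacian(L)
      ev <- eigen(lt, symmetric = TRUE, only.values = TRUE)$values
      expect_true(all(ev >= -1 - 1e-10 & ev <= 1 + 1e-10))
    }
  })
})

test_that("Chebyshev convolution matches a dense polynomial oracle", {
  withr::with_seed(16, {
    n <- 8; fin <- 4; fout <- 3; K <- 4
    L <- normalized_laplacian(random_adjacency(n))
    lt <- scale_laplacian(L)
    X <- matrix(rnorm(n * fin), n, fin)
    Theta <- lapply(1:K, function(k) matrix(rnorm(fin * fout), fin, fout))
  })
  # closed-form polynomials, independent of the recurrence in the package
  T0 <- diag(n); T1 <- lt
  T2 <- 2 * lt %*% lt - diag(n)
  T3 <- 4 * lt %*% lt %*% lt - 3 * lt
  oracle <- T0 %*% X %*% Theta[[1]] + T1 %*% X %*% Theta[[2]] +
    T2 %*% X %*% Theta[[3]] + T3 %*% X %*% Theta[[4]]
  expect_equal(cheb_conv(X, lt, Theta), oracle, tolerance = 1e-10)
  # K = 1 degenerates to a graph-independent linear map
  expect_equal(cheb_conv(X, lt, Theta, K = 1), X %*% Theta[[1]],
               tolerance = 1e-12)
  # zero rescaled Laplacian: odd terms vanish, T2 contributes -X Theta_2
  z <- matrix(0, n, n)
  expect_equal(cheb_conv(X, z, Theta, K = 3),
               X %*% Theta[[1]] - X %*% Theta[[3]], tolerance = 1e-12)
  expect_error(cheb_conv(X, lt, Theta, K = 9), "K exceeds")
})

test_that("forward pass emits proper probabilities", {
  g <- toy_graph()
  hy <- gcn_hyperparams(n_hidden_layers = 2, hidden_width = 5, epochs = 3,
                        seed = 2)
  model <- train_gcn(g, hy)
  pred <- predict_gcn(model, g, nodes = "all")
  fw <- braingcn:::gcn_forward(model$params, g$features, model$Tk)
  expect_equal(unname(rowSums(fw$probs)), rep(1, 6), tolerance = 1e-12)
  expect_true(all(fw$probs > 0 & fw$probs < 1))
  expect_equal(pred$score, fw$probs[, 2])
})

test_that("analytic gradients agree with finite differences", {
  g <- toy_graph(seed = 23)
  hy <- gcn_hyperparams(n_hidden_layers = 2, cheb_order = 3,
                        hidden_width = 4, dropout = 0, epochs = 1, seed = 3)
  withr::with_seed(3, params <- braingcn:::gcn_init_params(3, hy))
  L <- normalized_laplacian(g$C)
  Tk <- braingcn:::cheb_basis(scale_laplacian(L), 3)
  y_onehot <- matrix(0, 6, 2)
  yid <- as.integer(g$labels)
  y_onehot[cbind(1:6, yid)] <- 1
  mask <- g$mask
  lg <- braingcn:::gcn_loss_grad(params, g$features, Tk, y_onehot, mask)
  h <- 1e-6
  for (l in seq_along(params)) {
    for (k in seq_along(params[[l]]$Theta)) {
      probe <- cbind(sample(nrow(params[[l]]$Theta[[k]]), 3, replace = TRUE),
                     sample(ncol(params[[l]]$Theta[[k]]), 3, replace = TRUE))
      for (r in seq_len(nrow(probe))) {
        pp <- params
        pp[[l]]$Theta[[k]][probe[r, 1], probe[r, 2]] <-
          pp[[l]]$Theta[[k]][probe[r, 1], probe[r, 2]] + h
        up <- braingcn:::gcn_loss_grad(pp, g$features, Tk, y_onehot, mask)$loss
        pp[[l]]$Theta[[k]][probe[r, 1], probe[r, 2]] <-
          pp[[l]]$Theta[[k]][probe[r, 1], probe[r, 2]] - 2 * h
        dn <- braingcn:::gcn_loss_grad(pp, g$features, Tk, y_onehot, mask)$loss
        fd <- (up - dn) / (2 * h)
        an <- lg$grads[[l]]$Theta[[k]][probe[r, 1], probe[r, 2]]
        expect_equal(an, fd, tolerance = 1e-5)
      }
    }
  }
})

test_that("the model is permutation equivariant", {
  g <- toy_graph(seed = 31, n = 8, f = 4)
  hy <- gcn_hyperparams(n_hidden_layers = 2, hidden_width = 6, epochs = 40,
                        dropout = 0, seed = 7)
  model <- train_gcn(g, hy)
  fw <- braingcn:::gcn_forward(model$params, g$features, model$Tk)
  perm <- withr::with_seed(8, sample(8))
  Cp <- g$C[perm, perm]
  Xp <- g$features[perm, ]
  Tkp <- braingcn:::cheb_basis(
    scale_laplacian(normalized_laplacian(Cp),
                    max(eigen(normalized_laplacian(g$C), symmetric = TRUE,
                              only.values = TRUE)$values)),
    hy$cheb_order)
  fwp <- braingcn:::gcn_forward(model$params, Xp, Tkp)
  expect_equal(fwp$probs, fw$probs[perm, ], tolerance = 1e-12)
})

test_that("an edgeless graph factorizes over nodes", {
  g <- toy_graph(seed = 33)
  g$C <- matrix(0, 6, 6)
  hy <- gcn_hyperparams(n_hidden_layers = 2, hidden_width = 4, epochs = 30,
                        dropout = 0, lambda_max = 2, seed = 9)
  model <- train_gcn(g, hy)
  base <- braingcn:::gcn_forward(model$params, g$features, model$Tk)$probs
  pert <- g$features
  pert[4, ] <- pert[4, ] + 10
  out <- braingcn:::gcn_forward(model$params, pert, model$Tk)$probs
  expect_equal(out[-4, ], base[-4, ], tolerance = 1e-12)
  expect_false(isTRUE(all.equal(out[4, ], base[4, ])))
})

test_that("training is seeded-deterministic, descends, and fits the labels", {
  coh <- tiny_cohort(seed = 41, n_per_class = 10, n_regions = 16,
                     n_timepoints = 30, d = 2)
  ds <- as_dataset(coh)
  sc_g <- fit_scaler(ds$gmv); sc_s <- fit_scaler(ds$spl)
  fc <- concatenate_selected(
    braingcn::subset_selected(apply_scaler(sc_g, ds$gmv), 1:8),
    braingcn::subset_selected(apply_scaler(sc_s, ds$spl), 1:8))
  mask <- rep(c(TRUE, TRUE, TRUE, FALSE), 5)
  g <- build_subject_graph(fc, ds$phenotypes, ds$labels,
                           labelled_mask = mask)
  hy <- gcn_hyperparams(epochs = 300, seed = 11)
  m1 <- train_gcn(g, hy)
  m2 <- train_gcn(g, hy)
  expect_identical(m1$params, m2$params)
  p1 <- predict_gcn(m1, g)
  expect_identical(p1, predict_gcn(m1, g))
  # softmax probabilities; may saturate to the closed bounds in double
  # precision once the cohort is fitted hard
  expect_true(all(p1$score >= 0 & p1$score <= 1))
  expect_lt(m1$loss_trace[10], m1$loss_trace[1])
  # labelled-node training accuracy on a separable cohort
  all_pred <- predict_gcn(m1, g, nodes = "all")
  acc_train <- mean(all_pred$predicted[mask] == ds$labels[mask])
  expect_gte(acc_train, 0.95)
})

test_that("single-class labels degenerate to constant prediction", {
  g <- toy_graph(seed = 55)
  g$labels <- factor(rep("NC", 6), levels = c("NC", "EMCI"))
  hy <- gcn_hyperparams(n_hidden_layers = 1, hidden_width = 4, epochs = 120,
                        seed = 5)
  expect_warning(model <- train_gcn(g, hy), "single class")
  pred <- predict_gcn(model, g, nodes = "all")
  expect_true(all(pred$predicted == "NC"))
})
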