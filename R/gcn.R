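#' GCN hyperparameters
#'
#' Defaults follow the configuration used for subject-level population
#' graphs in this problem: 5 hidden graph-convolution layers, Chebyshev
#' order K = 4 (terms T_0..T_3, a 3-hop receptive field per layer),
#' dropout 0.01, learning rate 0.02, 500 epochs.
#'
#' @param n_hidden_layers Number of hidden graph-convolution layers (L).
#' @param cheb_order Number of Chebyshev terms per convolution (K).
#' @param dropout Dropout rate on the input of each hidden layer during
#'   training, in [0, 1).
#' @param learning_rate Adam learning rate.
#' @param epochs Training epochs.
#' @param hidden_width Channels per hidden layer.
#' @param lambda_max Either `"eigen"` (compute the Laplacian's largest
#'   eigenvalue per graph) or a fixed number such as 2.
#' @param seed Seed for weight initialization and dropout.
#' @return An object of class `gcn_hyperparams`.
#' @export
gcn_hyperparams <- function(n_hidden_layers = 5L, cheb_order = 4L,
                            dropout = 0.01, learning_rate = 0.02,
                            epochs = 500L, hidden_width = 16L,
                            lambda_max = "eigen", seed = 1L) {
  stopifnot(n_hidden_layers >= 1, cheb_order >= 1,
            dropout >= 0, dropout < 1, epochs >= 1, hidden_width >= 1)
  structure(list(n_hidden_layers = as.integer(n_hidden_layers),
                 cheb_order = as.integer(cheb_order),
                 dropout = dropout, learning_rate = learning_rate,
                 epochs = as.integer(epochs),
                 hidden_width = as.integer(hidden_width),
                 lambda_max = lambda_max, seed = as.integer(seed)),
            class = "gcn_hyperparams")
}

#' Symmetric normalized graph Laplacian
#'
#' `L = I - D^(-1/2) C D^(-1/2)` with D the degree matrix. Isolated
#' nodes (degree 0) get a zero scaling entry, so their Laplacian row is
#' the identity row and they pass through convolutions untouched by
#' neighbours.
#'
#' @param C Symmetric nonnegative adjacency with zero diagonal, or a
#'   `subject_graph`.
#' @return N-by-N Laplacian matrix; eigenvalues lie in [0, 2].
#' @export
normalized_laplacian <- function(C) {
  if (inherits(C, "subject_graph")) C <- C$C
  C <- as.matrix(C)
  if (max(abs(C - t(C))) > 1e-10) {
    abort("Adjacency must be symmetric.", class = "braingcn_data_error")
  }
  if (any(C < 0)) {
    abort("Adjacency must be nonnegative.", class = "braingcn_data_error")
  }
  d <- rowSums(C)
  dinv <- ifelse(d > 0, 1 / sqrt(d), 0)
  diag(length(d)) - (dinv * C) * rep(dinv, each = length(d))
}

#' Rescale a Laplacian to the Chebyshev domain
#'
#' `L_tilde = 2 L / lambda_max - I`, mapping the spectrum into [-1, 1]
#' where Chebyshev polynomials are well behaved.
#'
#' @param L Normalized Laplacian.
#' @param lambda_max Largest eigenvalue; `NULL` computes it, a number
#'   (e.g. the upper bound 2) fixes it.
#' @return Rescaled Laplacian.
#' @export
scale_laplacian <- function(L, lambda_max = NULL) {
  if (is.null(lambda_max) || identical(lambda_max, "eigen")) {
    lambda_max <- max(eigen(L, symmetric = TRUE, only.values = TRUE)$values)
    if (lambda_max <= 0) lambda_max <- 2
  }
  if (lambda_max <= 0) {
    abort("`lambda_max` must be positive.", class = "braingcn_config_error")
  }
  2 * L / lambda_max - diag(nrow(L))
}

# T_0..T_{K-1} of the rescaled Laplacian via the Chebyshev recurrence.
cheb_basis <- function(L_tilde, K) {
  n <- nrow(L_tilde)
  Tk <- vector("list", K)
  Tk[[1]] <- diag(n)
  if (K >= 2) Tk[[2]] <- L_tilde
  if (K >= 3) {
    for (k in 3:K) {
      Tk[[k]] <- 2 * L_tilde %*% Tk[[k - 1]] - Tk[[k - 2]]
    }
  }
  Tk
}

#' Chebyshev graph convolution
#'
#' `sum_k T_k(L_tilde) X Theta_k` for k = 0..K-1, with the polynomials
#' evaluated by the recurrence `T_k = 2 L_tilde T_{k-1} - T_{k-2}`,
#' `T_0 = I`, `T_1 = L_tilde`. With K = 1 this degenerates to a
#' graph-independent linear map.
#'
#' @param X N-by-F node-feature matrix.
#' @param L_tilde Rescaled Laplacian (see [scale_laplacian()]).
#' @param Theta List of K F-by-F' coefficient matrices.
#' @param K Number of Chebyshev terms (must not exceed `length(Theta)`).
#' @return N-by-F' transformed features.
#' @export
cheb_conv <- function(X, L_tilde, Theta, K = length(Theta)) {
  if (K > length(Theta)) {
    abort("K exceeds the number of coefficient matrices supplied.",
          class = "braingcn_config_error")
  }
  Tk <- cheb_basis(L_tilde, K)
  out <- matrix(0, nrow(X), ncol(Theta[[1]]))
  for (k in seq_len(K)) {
    out <- out + (Tk[[k]] %*% X) %*% Theta[[k]]
  }
  out
}

# ---- internal model machinery -------------------------------------------

glorot_theta <- function(K, f_in, f_out) {
  s <- sqrt(6 / (K * f_in + f_out))
  lapply(seq_len(K), function(k) {
    matrix(runif(f_in * f_out, -s, s), f_in, f_out)
  })
}

gcn_init_params <- function(n_features, hyper) {
  dims <- c(n_features, rep(hyper$hidden_width, hyper$n_hidden_layers), 2L)
  lapply(seq_len(length(dims) - 1L), function(l) {
    list(Theta = glorot_theta(hyper$cheb_order, dims[l], dims[l + 1]),
         bias = rep(0, dims[l + 1]))
  })
}

row_softmax <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

# Forward pass. Tk: list of K N-by-N Chebyshev basis matrices.
# drop_masks: NULL (no dropout) or per-hidden-layer multiplier matrices.
# Caches per layer what backprop needs: TXd (Tk %*% dropped input) and Z.
gcn_forward <- function(params, X, Tk, drop_masks = NULL) {
  n_layers <- length(params)
  cache <- vector("list", n_layers)
  H <- X
  for (l in seq_len(n_layers)) {
    hidden <- l < n_layers
    Xd <- if (hidden && !is.null(drop_masks)) H * drop_masks[[l]] else H
    TXd <- lapply(Tk, function(Tm) Tm %*% Xd)
    Z <- matrix(rep(params[[l]]$bias, each = nrow(X)), nrow(X))
    for (k in seq_along(Tk)) {
      Z <- Z + TXd[[k]] %*% params[[l]]$Theta[[k]]
    }
    cache[[l]] <- list(TXd = TXd, Z = Z)
    H <- if (hidden) pmax(Z, 0) else Z
  }
  probs <- row_softmax(H)
  list(probs = probs, cache = cache)
}

# Masked cross-entropy loss and analytic gradients (backprop).
# y_onehot: N-by-2; mask: logical labelled nodes.
gcn_loss_grad <- function(params, X, Tk, y_onehot, mask,
                          drop_masks = NULL) {
  fw <- gcn_forward(params, X, Tk, drop_masks)
  m <- sum(mask)
  eps <- 1e-12
  loss <- -sum(log(pmax(fw$probs[mask, , drop = FALSE], eps)) *
                 y_onehot[mask, , drop = FALSE]) / m

  n_layers <- length(params)
  grads <- vector("list", n_layers)
  dZ <- (fw$probs - y_onehot)
  dZ[!mask, ] <- 0
  dZ <- dZ / m
  for (l in rev(seq_len(n_layers))) {
    cc <- fw$cache[[l]]
    gTheta <- lapply(seq_along(Tk), function(k) crossprod(cc$TXd[[k]], dZ))
    gBias <- colSums(dZ)
    grads[[l]] <- list(Theta = gTheta, bias = gBias)
    if (l > 1) {
      dXd <- matrix(0, nrow(X), nrow(params[[l]]$Theta[[1]]))
      for (k in seq_along(Tk)) {
        dXd <- dXd + Tk[[k]] %*% (dZ %*% t(params[[l]]$Theta[[k]]))
      }
      if (!is.null(drop_masks) && l <= length(drop_masks)) {
        dXd <- dXd * drop_masks[[l]]
      }
      dZ <- dXd * (fw$cache[[l - 1]]$Z > 0)
    }
  }
  list(loss = loss, grads = grads, probs = fw$probs)
}

adam_state <- function(params) {
  rapply(params, function(x) x * 0, how = "replace")
}

#' Train the spectral GCN on a subject graph
#'
#' Transductive semi-supervised training: the graph holds every subject
#' (labelled and unlabelled), convolutions propagate information across
#' phenotype-gated edges, and the masked cross-entropy is computed on
#' labelled nodes only. Hidden layers are ReLU-activated Chebyshev
#' convolutions; the output layer is a Chebyshev convolution to two
#' channels followed by row-wise softmax. Optimized with Adam; fully
#' deterministic given the seed in `hyper`.
#'
#' @param graph A [build_subject_graph()] result.
#' @param hyper A [gcn_hyperparams()].
#' @return An object of class `gcn_model`: fitted parameters, the
#'   Chebyshev basis of the training graph, the per-epoch loss trace and
#'   the hyperparameters.
#' @export
train_gcn <- function(graph, hyper = gcn_hyperparams()) {
  stopifnot(inherits(graph, "subject_graph"),
            inherits(hyper, "gcn_hyperparams"))
  mask <- graph$mask
  y <- graph$labels
  classes <- levels(y) %||% sort(unique(as.character(y)))
  if (length(classes) != 2) {
    abort("Exactly two classes are required.", class = "braingcn_data_error")
  }
  if (sum(mask) < 1) {
    abort("Need at least one labelled node.", class = "braingcn_data_error")
  }
  if (length(unique(as.character(y[mask]))) < 2) {
    warn("Labelled nodes contain a single class; the fitted model is degenerate.")
  }

  L <- normalized_laplacian(graph$C)
  lt <- scale_laplacian(L, if (identical(hyper$lambda_max, "eigen")) NULL
                           else hyper$lambda_max)
  Tk <- cheb_basis(lt, hyper$cheb_order)
  X <- graph$features
  yid <- as.integer(factor(as.character(y), levels = classes))
  y_onehot <- matrix(0, nrow(X), 2)
  y_onehot[cbind(which(mask), yid[mask])] <- 1

  n <- nrow(X)
  lr <- hyper$learning_rate
  b1 <- 0.9; b2 <- 0.999; aeps <- 1e-8

  withr::with_seed(hyper$seed, {
    params <- gcn_init_params(ncol(X), hyper)
    mom <- adam_state(params)
    vel <- adam_state(params)
    trace <- numeric(hyper$epochs)
    step <- 0
    for (epoch in seq_len(hyper$epochs)) {
      drop_masks <- NULL
      if (hyper$dropout > 0) {
        keep <- 1 - hyper$dropout
        dims <- c(ncol(X), rep(hyper$hidden_width,
                               hyper$n_hidden_layers - 1L))
        drop_masks <- lapply(dims, function(f) {
          matrix(rbinom(n * f, 1, keep) / keep, n, f)
        })
      }
      lg <- gcn_loss_grad(params, X, Tk, y_onehot, mask, drop_masks)
      trace[epoch] <- lg$loss
      step <- step + 1
      for (l in seq_along(params)) {
        for (k in seq_along(params[[l]]$Theta)) {
          g <- lg$grads[[l]]$Theta[[k]]
          mom[[l]]$Theta[[k]] <- b1 * mom[[l]]$Theta[[k]] + (1 - b1) * g
          vel[[l]]$Theta[[k]] <- b2 * vel[[l]]$Theta[[k]] + (1 - b2) * g^2
          mhat <- mom[[l]]$Theta[[k]] / (1 - b1^step)
          vhat <- vel[[l]]$Theta[[k]] / (1 - b2^step)
          params[[l]]$Theta[[k]] <- params[[l]]$Theta[[k]] -
            lr * mhat / (sqrt(vhat) + aeps)
        }
        g <- lg$grads[[l]]$bias
        mom[[l]]$bias <- b1 * mom[[l]]$bias + (1 - b1) * g
        vel[[l]]$bias <- b2 * vel[[l]]$bias + (1 - b2) * g^2
        params[[l]]$bias <- params[[l]]$bias -
          lr * (mom[[l]]$bias / (1 - b1^step)) /
            (sqrt(vel[[l]]$bias / (1 - b2^step)) + aeps)
      }
    }
    structure(list(params = params, Tk = Tk, classes = classes,
                   n_features = ncol(X), hyper = hyper,
                   loss_trace = trace),
              class = "gcn_model")
  })
}

#' Predict node labels on the training graph
#'
#' Transductive prediction: a forward pass with dropout off over the
#' same graph the model was trained on; the softmax assigns a label and
#' a positive-class (EMCI) probability to every node. By default only
#' unlabelled nodes are returned.
#'
#' @param model A [train_gcn()] result.
#' @param graph The same `subject_graph` used for training.
#' @param nodes `"unlabelled"` (default) or `"all"`.
#' @return Tibble with `subject_id`, `node`, `predicted`, `score`
#'   (positive-class probability) and `labelled`.
#' @export
predict_gcn <- function(model, graph, nodes = c("unlabelled", "all")) {
  nodes <- match.arg(nodes)
  stopifnot(inherits(model, "gcn_model"), inherits(graph, "subject_graph"))
  if (ncol(graph$features) != model$n_features) {
    abort("Graph feature count does not match the trained model.",
          class = "braingcn_data_error")
  }
  fw <- gcn_forward(model$params, graph$features, model$Tk)
  pred <- model$classes[max.col(fw$probs, ties.method = "first")]
  out <- tibble::tibble(
    subject_id = rownames(graph$features) %||%
      as.character(seq_len(nrow(graph$features))),
    node = seq_len(nrow(graph$features)),
    predicted = factor(pred, levels = model$classes),
    score = fw$probs[, 2],
    labelled = graph$mask
  )
  if (nodes == "unlabelled") out <- out[!out$labelled, ]
  out
}

#' @export
print.gcn_model <- function(x, ...) {
  cat("<gcn_model> ", length(x$params) - 1L, " hidden layers, K = ",
      x$hyper$cheb_order, ", ", x$n_features, " input features, final loss ",
      format(x$loss_trace[length(x$loss_trace)], digits = 4), "\n", sep = "")
  invisible(x)
}

#' @export
tidy.gcn_model <- function(x, ...) {
  tibble::tibble(epoch = seq_along(x$loss_trace), loss = x$loss_trace)
}

#' @export
glance.gcn_model <- function(x, ...) {
  tibble::tibble(
    n_layers = length(x$params) - 1L,
    cheb_order = x$hyper$cheb_order,
    n_features = x$n_features,
    epochs = x$hyper$epochs,
    initial_loss = x$loss_trace[1],
    final_loss = x$loss_trace[length(x$loss_trace)]
  )
}
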