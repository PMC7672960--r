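#' Fit per-feature scaling on training subjects
#'
#' Two-step scaling fitted strictly on training subjects: each feature is
#' first mapped to [-1, +1] by its training min/max, then z-scored by the
#' mean/sd of the range-scaled training values. Fitting on training
#' subjects only keeps cross-validation leak-free; the fitted-on ids are
#' recorded so this can be audited.
#'
#' @param train A [feature_matrix()] of training subjects (>= 2 rows).
#' @return An object of class `scaler_params` with per-feature `min`,
#'   `max`, `mean`, `sd`, and `fitted_on` subject ids. Constant features
#'   are flagged in `constant` and transformed to 0.
#' @export
fit_scaler <- function(train) {
  stopifnot(inherits(train, "feature_matrix"))
  x <- train$values
  if (nrow(x) < 2) {
    abort("Need at least 2 training subjects to fit a scaler.",
          class = "braingcn_data_error")
  }
  mn <- apply(x, 2, min)
  mx <- apply(x, 2, max)
  constant <- mx == mn
  ranged <- range_scale(x, mn, mx, constant)
  mu <- colMeans(ranged)
  s <- apply(ranged, 2, sd)
  zero_sd <- s == 0
  if (any(zero_sd)) s[zero_sd] <- 1
  structure(list(min = mn, max = mx, mean = mu, sd = s,
                 constant = constant,
                 feature_names = train$feature_names,
                 fitted_on = train$subjects),
            class = "scaler_params")
}

range_scale <- function(x, mn, mx, constant) {
  out <- sweep(sweep(x, 2, mn), 2, ifelse(constant, 1, mx - mn), "/")
  out <- 2 * out - 1
  out[, constant] <- 0
  out
}

#' Apply a fitted scaler
#'
#' Values pass through the range step `v -> 2(v - min)/(max - min) - 1`
#' and then the z step `(v - mean)/sd` with the training statistics.
#' Held-out values outside the training range extrapolate linearly — no
#' clipping, so the ordering of extreme values is preserved.
#'
#' @param params A [fit_scaler()] result.
#' @param x A [feature_matrix()] whose feature names match `params`.
#' @return A `feature_matrix` of the same modality with transformed
#'   values.
#' @export
apply_scaler <- function(params, x) {
  stopifnot(inherits(params, "scaler_params"), inherits(x, "feature_matrix"))
  if (!identical(params$feature_names, x$feature_names)) {
    abort("Feature names do not match the fitted scaler.",
          class = "braingcn_data_error")
  }
  ranged <- range_scale(x$values, params$min, params$max, params$constant)
  z <- sweep(sweep(ranged, 2, params$mean), 2, params$sd, "/")
  feature_matrix(z, x$modality,
                 provenance = c(x$provenance,
                                list(scaled = TRUE,
                                     fitted_on = params$fitted_on)))
}
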