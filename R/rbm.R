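#' Restricted Boltzmann machine for ambulatory glucose sequences
#'
#' The blood-glucose forecaster is a restricted Boltzmann machine (RBM)
#' over `m` visible and `n_h` hidden binary units with energy
#' `E(z, x) = -sum(b * z) - sum(c * x) - z' W x` (visible bias `b`,
#' hidden bias `c`, weights `W`). Joint probabilities follow the
#' Boltzmann distribution `exp(-E) / B(theta)` with partition function
#' `B(theta)`, tractable by enumeration only for tiny models (used here
#' as a test oracle). A glucose series is min-max encoded to `[0, 1]`,
#' cut into sliding windows of `lag` past values plus one target, and
#' the machine is trained by contrastive divergence; forecasting clamps
#' the lag units and reconstructs the target by deterministic mean-field
#' iteration.
#'
#' @name glucose_rbm
NULL

#' Construct RBM parameters
#'
#' @param b visible bias vector (length `m`).
#' @param c_ hidden bias vector (length `n_h`).
#' @param W `m x n_h` weight matrix.
#' @return object of class `rbm_params`.
#' @export
rbm_params <- function(b, c_, W) {
  W <- as.matrix(W)
  b <- as.numeric(b)
  c_ <- as.numeric(c_)
  if (nrow(W) != length(b) || ncol(W) != length(c_)) {
    stop(sprintf("shape mismatch: W is %dx%d but |b|=%d, |c|=%d",
                 nrow(W), ncol(W), length(b), length(c_)), call. = FALSE)
  }
  if (any(!is.finite(b)) || any(!is.finite(c_)) || any(!is.finite(W))) {
    stop("RBM parameters must be finite", call. = FALSE)
  }
  structure(list(b = b, c = c_, W = W, m = length(b), n_hidden = length(c_)),
            class = "rbm_params")
}

#' @export
print.rbm_params <- function(x, ...) {
  cat(sprintf("<rbm_params: %d visible, %d hidden>\n", x$m, x$n_hidden))
  invisible(x)
}

check_units <- function(v, len, what) {
  v <- as.numeric(v)
  if (length(v) != len) {
    stop(sprintf("%s has length %d, expected %d", what, length(v), len),
         call. = FALSE)
  }
  if (any(!is.finite(v)) || any(v < 0) || any(v > 1)) {
    stop(sprintf("%s must lie in [0, 1]", what), call. = FALSE)
  }
  v
}

#' RBM energy of a joint configuration
#'
#' `E(z, x) = -sum(b_i z_i) - sum(c_j x_j) - sum_ij z_i W_ij x_j`.
#'
#' @param params an [rbm_params].
#' @param z visible vector (length `m`, entries in \{0,1\}).
#' @param x hidden vector (length `n_h`, entries in \{0,1\}).
#' @return scalar energy.
#' @examples
#' p <- rbm_params(b = 1, c_ = 2, W = matrix(3))
#' energy(p, 1, 1)  # -6
#' @export
energy <- function(params, z, x) {
  stopifnot(inherits(params, "rbm_params"))
  z <- check_units(z, params$m, "visible vector z")
  x <- check_units(x, params$n_hidden, "hidden vector x")
  -sum(params$b * z) - sum(params$c * x) -
    as.numeric(t(z) %*% params$W %*% x)
}

all_binary_states <- function(n) {
  if (n == 0L) return(matrix(numeric(0), nrow = 1L, ncol = 0L))
  as.matrix(expand.grid(rep(list(c(0, 1)), n)))
}

#' Exact partition function by state enumeration
#'
#' `B(theta) = sum over all joint states of exp(-E(z, x))`. Only
#' feasible for tiny machines; guarded at `m + n_h <= 20`. Intended as a
#' test oracle and for exact log-likelihood tracking on small instances.
#'
#' @param params an [rbm_params] with `m + n_hidden <= 20`.
#' @return positive scalar.
#' @examples
#' p <- rbm_params(b = c(0, 0), c_ = 0, W = matrix(0, 2, 1))
#' partition_function(p)  # 8 states, each exp(0)
#' @export
partition_function <- function(params) {
  stopifnot(inherits(params, "rbm_params"))
  if (params$m + params$n_hidden > 20L) {
    stop("exact enumeration limited to m + n_hidden <= 20", call. = FALSE)
  }
  # sum over visible states of the analytically summed hidden layer
  Z <- all_binary_states(params$m)
  sum(exp(free_energy_terms(params, Z)))
}

# log sum_x exp(-E(z, x)) for each row z of Z (negative free energy)
free_energy_terms <- function(params, Z) {
  act <- sweep(Z %*% params$W, 2, params$c, `+`)
  as.numeric(Z %*% params$b) + rowSums(log1p(exp(-abs(act))) + pmax(act, 0))
}

#' Exact log-likelihood of visible configurations
#'
#' Mean log marginal probability `log T(z | theta)` over the rows of
#' `Z`, computed from the analytic hidden-layer sum and the enumerated
#' partition function (so the same size guard applies).
#'
#' @param params an [rbm_params] with `m + n_hidden <= 20`.
#' @param Z matrix of visible configurations, one row each.
#' @return mean log-likelihood (scalar).
#' @export
rbm_log_likelihood <- function(params, Z) {
  stopifnot(inherits(params, "rbm_params"))
  Z <- as.matrix(Z)
  mean(free_energy_terms(params, Z)) - log(partition_function(params))
}

#' Hidden-unit activation probabilities
#'
#' `P(x_j = 1 | z) = sigmoid(c_j + sum_i z_i W_ij)`.
#'
#' @param params an [rbm_params].
#' @param z visible vector in `[0, 1]^m` (binary states or mean
#'   activations).
#' @return probability vector of length `n_hidden`.
#' @export
hidden_activation <- function(params, z) {
  stopifnot(inherits(params, "rbm_params"))
  z <- check_units(z, params$m, "visible vector z")
  sigmoid(params$c + as.numeric(crossprod(params$W, z)))
}

#' Visible-unit activation probabilities
#'
#' `P(z_i = 1 | x) = sigmoid(b_i + sum_j W_ij x_j)`.
#'
#' @param params an [rbm_params].
#' @param x hidden vector in `[0, 1]^{n_hidden}`.
#' @return probability vector of length `m`.
#' @export
visible_activation <- function(params, x) {
  stopifnot(inherits(params, "rbm_params"))
  x <- check_units(x, params$n_hidden, "hidden vector x")
  sigmoid(params$b + as.numeric(params$W %*% x))
}

#' Train an RBM by contrastive divergence
#'
#' Mini-batch CD-k on visible vectors in `[0, 1]` (binary data or
#' Bernoulli mean activations from the window encoding). Hidden states
#' are sampled binary along the chain; visible reconstructions use mean
#' activations. Weights start at `N(0, 0.01^2)`, biases at 0, and the
#' learning rate is fixed.
#'
#' @param windows numeric matrix of visible vectors (rows), entries in
#'   `[0, 1]`.
#' @param n_hidden number of hidden units.
#' @param epochs full passes over the data.
#' @param learning_rate step size.
#' @param cd_steps Gibbs steps per update (k in CD-k).
#' @param seed integer seed; training is reproducible given the seed.
#' @param batch_size mini-batch size.
#' @return trained [rbm_params].
#' @export
train_cd <- function(windows, n_hidden, epochs = 150L, learning_rate = 0.1,
                     cd_steps = 1L, seed = 1L, batch_size = 16L) {
  windows <- as.matrix(windows)
  if (nrow(windows) == 0L) stop("no training windows supplied", call. = FALSE)
  if (any(!is.finite(windows)) || any(windows < 0) || any(windows > 1)) {
    stop("training windows must lie in [0, 1]", call. = FALSE)
  }
  n_hidden <- check_count(n_hidden, "n_hidden")
  epochs <- check_count(epochs, "epochs")
  cd_steps <- check_count(cd_steps, "cd_steps")
  batch_size <- check_count(batch_size, "batch_size")
  lr <- check_scalar(learning_rate, "learning_rate", min = 0)
  m <- ncol(windows)
  n <- nrow(windows)

  with_seed(seed, {
    W <- matrix(stats::rnorm(m * n_hidden, sd = 0.01), m, n_hidden)
    b <- numeric(m)
    cc <- numeric(n_hidden)
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      starts <- seq(1L, n, by = batch_size)
      for (s in starts) {
        idx <- ord[s:min(s + batch_size - 1L, n)]
        v0 <- windows[idx, , drop = FALSE]
        nb <- length(idx)
        ph0 <- sigmoid(sweep(v0 %*% W, 2, cc, `+`))
        h <- matrix(stats::runif(nb * n_hidden) < ph0, nb, n_hidden) * 1
        vk <- v0
        phk <- ph0
        for (k in seq_len(cd_steps)) {
          vk <- sigmoid(sweep(h %*% t(W), 2, b, `+`))
          phk <- sigmoid(sweep(vk %*% W, 2, cc, `+`))
          if (k < cd_steps) {
            h <- matrix(stats::runif(nb * n_hidden) < phk, nb, n_hidden) * 1
          }
        }
        W <- W + lr * (crossprod(v0, ph0) - crossprod(vk, phk)) / nb
        b <- b + lr * colMeans(v0 - vk)
        cc <- cc + lr * colMeans(ph0 - phk)
      }
    }
    rbm_params(b, cc, W)
  })
}

#' Deterministic reconstruction error
#'
#' Mean squared distance between each window and its one-step mean-field
#' reconstruction (hidden means from the data, visible means from the
#' hidden means). Used to verify that training improves the fit.
#'
#' @param params an [rbm_params].
#' @param windows matrix of visible vectors.
#' @return mean squared reconstruction error (scalar).
#' @export
reconstruction_error <- function(params, windows) {
  stopifnot(inherits(params, "rbm_params"))
  windows <- as.matrix(windows)
  ph <- sigmoid(sweep(windows %*% params$W, 2, params$c, `+`))
  vr <- sigmoid(sweep(ph %*% t(params$W), 2, params$b, `+`))
  mean(rowSums((windows - vr)^2))
}

#' Min-max window encoding for a glucose series
#'
#' Affine map from mmol/L onto `[0, 1]` used to drive the visible units.
#' The range is the series range padded by `margin` of its width (or by
#' 0.5 mmol/L for a constant series), so encode-then-decode is the
#' identity inside the range.
#'
#' @param series a [glucose_series] or numeric vector.
#' @param lag autoregressive order: number of past values per window.
#' @param margin fractional range padding.
#' @return object of class `window_encoding` with fields `min`, `max`,
#'   `lag`.
#' @export
window_encoding <- function(series, lag, margin = 0.05) {
  v <- series_values(series)
  lag <- check_count(lag, "lag")
  lo <- min(v)
  hi <- max(v)
  pad <- if (hi > lo) margin * (hi - lo) else 0.5
  structure(list(min = lo - pad, max = hi + pad, lag = lag),
            class = "window_encoding")
}

series_values <- function(series) {
  if (inherits(series, "glucose_series")) series$values else as.numeric(series)
}

#' Encode glucose values to `[0, 1]`
#' @param enc a [window_encoding].
#' @param v numeric glucose values (mmol/L).
#' @return values mapped into `[0, 1]` (clipped at the padded range).
#' @export
encode_values <- function(enc, v) {
  stopifnot(inherits(enc, "window_encoding"))
  pmin(1, pmax(0, (as.numeric(v) - enc$min) / (enc$max - enc$min)))
}

#' Decode unit-interval activations back to mmol/L
#' @param enc a [window_encoding].
#' @param u values in `[0, 1]`.
#' @return glucose values in mmol/L (non-negative).
#' @export
decode_values <- function(enc, u) {
  stopifnot(inherits(enc, "window_encoding"))
  pmax(0, enc$min + as.numeric(u) * (enc$max - enc$min))
}

#' Sliding training windows from a series
#'
#' Each row holds `lag` consecutive encoded values (oldest first)
#' followed by the next value as the target unit, so the visible layer
#' has `lag + 1` units.
#'
#' @param enc a [window_encoding].
#' @param series a [glucose_series] or numeric vector.
#' @return matrix with `length(series) - lag` rows and `lag + 1` columns.
#' @export
make_windows <- function(enc, series) {
  v <- encode_values(enc, series_values(series))
  n <- length(v)
  lag <- enc$lag
  if (n <= lag) stop("series shorter than lag + 1", call. = FALSE)
  idx <- seq_len(n - lag)
  out <- vapply(0:lag, function(o) v[idx + o], numeric(length(idx)))
  matrix(out, nrow = length(idx), ncol = lag + 1L)
}

#' Forecast a glucose series with a trained RBM
#'
#' The final `horizon` values of `series` are withheld as actuals.
#' Starting from the last `lag` observed values before them, each step
#' clamps the lag units to the encoded recent values and reconstructs
#' the single free target unit; its mean activation is decoded to
#' mmol/L. Multi-step horizons roll forward on the model's own
#' predictions. There is no sampling at forecast time, so repeated
#' calls give identical results.
#'
#' With `method = "exact"` (default) the hidden layer is summed out
#' analytically, giving the exact model conditional
#' `P(z_target = 1 | lags)`: its logit is `b_m + sum_j
#' (softplus(a_j + W_mj) - softplus(a_j))` with
#' `a_j = c_j + sum_lags z_i W_ij`, which is tractable because exactly
#' one visible unit is free. `method = "mean_field"` instead runs
#' `mf_iter` deterministic sweeps alternating hidden means and the
#' target's visible mean from a 0.5 start; it approximates the same
#' conditional.
#'
#' @param params trained [rbm_params] with `m = lag + 1` visible units.
#' @param enc the [window_encoding] used for training.
#' @param series a [glucose_series] or numeric vector containing at
#'   least `lag + horizon` values.
#' @param horizon number of steps to forecast (0 gives an empty result).
#' @param method `"exact"` or `"mean_field"`.
#' @param mf_iter mean-field sweeps per step (mean-field method only).
#' @return object of class `forecast_result`: list with `predicted`,
#'   `actual` (both length `horizon`) and `rmse` (`NA` when
#'   `horizon = 0`).
#' @export
forecast <- function(params, enc, series, horizon,
                     method = c("exact", "mean_field"), mf_iter = 20L) {
  stopifnot(inherits(params, "rbm_params"), inherits(enc, "window_encoding"))
  method <- match.arg(method)
  horizon <- check_count(horizon, "horizon", min = 0L)
  v <- series_values(series)
  lag <- enc$lag
  if (params$m != lag + 1L) {
    stop(sprintf("model has %d visible units but encoding implies %d",
                 params$m, lag + 1L), call. = FALSE)
  }
  if (horizon == 0L) {
    return(structure(list(predicted = numeric(0), actual = numeric(0),
                          rmse = NA_real_), class = "forecast_result"))
  }
  if (length(v) < lag + horizon) {
    stop("series shorter than lag + horizon", call. = FALSE)
  }
  n_ctx <- length(v) - horizon
  actual <- v[(n_ctx + 1L):length(v)]
  context <- v[seq_len(n_ctx)]
  predicted <- numeric(horizon)
  softplus <- function(a) log1p(exp(-abs(a))) + pmax(a, 0)
  for (s in seq_len(horizon)) {
    lags <- encode_values(enc, utils::tail(context, lag))
    u <- if (method == "exact") {
      a <- params$c +
        as.numeric(crossprod(params$W[seq_len(lag), , drop = FALSE], lags))
      logit <- params$b[lag + 1L] +
        sum(softplus(a + params$W[lag + 1L, ]) - softplus(a))
      sigmoid(logit)
    } else {
      vis <- c(lags, 0.5)
      for (it in seq_len(mf_iter)) {
        h <- hidden_activation(params, vis)
        vis[lag + 1L] <- visible_activation(params, h)[lag + 1L]
      }
      vis[lag + 1L]
    }
    predicted[s] <- decode_values(enc, u)
    context <- c(context, predicted[s])
  }
  structure(list(predicted = predicted, actual = actual,
                 rmse = rmse(predicted, actual)),
            class = "forecast_result")
}

#' @export
print.forecast_result <- function(x, ...) {
  cat(sprintf("<forecast_result: %d steps, rmse=%s>\n",
              length(x$predicted),
              if (is.na(x$rmse)) "NA" else sprintf("%.4f", x$rmse)))
  invisible(x)
}

#' Root mean square error
#'
#' `sqrt(mean((predicted - actual)^2))` over paired vectors.
#'
#' @param predicted,actual numeric vectors of equal non-zero length.
#' @return non-negative scalar.
#' @examples
#' rmse(3, 1)  # 2
#' @export
rmse <- function(predicted, actual) {
  p <- as.numeric(predicted)
  a <- as.numeric(actual)
  if (length(p) == 0L || length(p) != length(a)) {
    stop("predicted and actual must have equal non-zero length",
         call. = FALSE)
  }
  sqrt(mean((p - a)^2))
}

#' Train an RBM forecaster on a glucose series
#'
#' Convenience wrapper: builds the window encoding, the sliding windows
#' and the CD-trained parameters in one call.
#'
#' @param series a [glucose_series] or numeric vector.
#' @param lag autoregressive order.
#' @param n_hidden hidden units.
#' @param epochs,learning_rate training schedule, passed to [train_cd].
#' @param ... further [train_cd] arguments (`cd_steps`, `seed`,
#'   `batch_size`).
#' @return list with `params` ([rbm_params]) and `encoding`
#'   ([window_encoding]).
#' @export
fit_glucose_rbm <- function(series, lag = 24L, n_hidden = 64L,
                            epochs = 500L, learning_rate = 0.3, ...) {
  enc <- window_encoding(series, lag)
  win <- make_windows(enc, series)
  list(params = train_cd(win, n_hidden, epochs = epochs,
                         learning_rate = learning_rate, ...),
       encoding = enc)
}
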