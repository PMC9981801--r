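#' Soft-margin linear classifier and the Diabetes Index
#'
#' The risk classifier is a linear soft-margin machine: it minimizes
#' `0.5 * ||r||^2 + C * sum(zeta)` subject to
#' `y_a * (r . x_a + g) >= 1 - zeta_a`, `zeta_a >= 0`. Training solves
#' the dual quadratic program by sequential minimal optimization (SMO)
#' with maximal-violating-pair working-set selection. Decision values
#' `d(x) = r . x + g` are turned into a Diabetes Index
#' `DI(x) = 1 / (1 + exp(S * d(x) + F))` by fitting the conversion
#' parameters `(S, F)` with a penalized Bernoulli maximum-likelihood
#' sigmoid fit. The feature map is the identity (linear kernel).
#'
#' @name risk_classifier
NULL

#' Train the soft-margin linear classifier
#'
#' Solves the dual of the primal problem
#' `min 0.5 * r'r + C * sum(zeta)` s.t. `y_a (r . x_a + g) >= 1 - zeta_a`
#' by SMO. The bias `g` is recovered from the converged KKT bounds and
#' the slacks `zeta_a = max(0, 1 - y_a (r . x_a + g))` are returned as a
#' training artifact.
#'
#' @param x numeric matrix, one row per sample.
#' @param y labels in \{-1, +1\}, both classes present.
#' @param C positive penalty on slack.
#' @param tol KKT violation tolerance for convergence.
#' @param max_iter iteration cap.
#' @return object of class `margin_classifier` with fields `weights` (r),
#'   `bias` (g), `C`, `alpha` (dual variables), `slacks` (zeta) and
#'   `objective` (the achieved primal value).
#' @examples
#' x <- matrix(c(-1, 1), ncol = 1)
#' m <- train_classifier(x, c(-1, 1), C = 100)
#' sign(decision_value(m, 1))
#' @export
train_classifier <- function(x, y, C = 1, tol = 1e-8, max_iter = NULL) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- as.numeric(y)
  m <- nrow(x)
  if (m < 2L || length(y) != m) {
    stop("need >= 2 samples with one label per row", call. = FALSE)
  }
  if (!all(y %in% c(-1, 1))) stop("labels must be -1/+1", call. = FALSE)
  if (length(unique(y)) < 2L) {
    stop("training requires both classes present", call. = FALSE)
  }
  if (any(!is.finite(x))) stop("non-finite values in inputs", call. = FALSE)
  C <- check_scalar(C, "C")
  if (C <= 0) stop_param("C", "must be > 0")
  if (is.null(max_iter)) max_iter <- max(20000L, 200L * m)

  alpha <- numeric(m)
  w <- numeric(ncol(x))
  grad <- rep(-1, m)                 # grad_t = y_t * (x_t . w) - 1
  tau <- 1e-12
  krow <- function(i) as.numeric(x %*% x[i, ])

  for (iter in seq_len(max_iter)) {
    viol <- -y * grad                # = y_t - x_t . w at alpha-feasible pts
    up <- (y > 0 & alpha < C - 1e-12) | (y < 0 & alpha > 1e-12)
    low <- (y > 0 & alpha > 1e-12) | (y < 0 & alpha < C - 1e-12)
    i <- which(up)[which.max(viol[up])]
    j <- which(low)[which.min(viol[low])]
    if (length(i) == 0L || length(j) == 0L || viol[i] - viol[j] <= tol) break

    Ki <- krow(i)
    Kj <- krow(j)
    if (y[i] != y[j]) {
      quad <- Ki[i] + Kj[j] - 2 * Ki[j]
      if (quad <= 0) quad <- tau
      delta <- (-grad[i] - grad[j]) / quad
      diffv <- alpha[i] - alpha[j]
      ai <- alpha[i] + delta
      aj <- alpha[j] + delta
      if (diffv > 0) {
        if (aj < 0) { aj <- 0; ai <- diffv }
      } else {
        if (ai < 0) { ai <- 0; aj <- -diffv }
      }
      if (diffv > 0) {
        if (ai > C) { ai <- C; aj <- C - diffv }
      } else {
        if (aj > C) { aj <- C; ai <- C + diffv }
      }
    } else {
      quad <- Ki[i] + Kj[j] - 2 * Ki[j]
      if (quad <= 0) quad <- tau
      delta <- (grad[i] - grad[j]) / quad
      s <- alpha[i] + alpha[j]
      ai <- alpha[i] - delta
      aj <- alpha[j] + delta
      if (s > C) {
        if (ai > C) { ai <- C; aj <- s - C }
        if (aj > C) { aj <- C; ai <- s - C }
      } else {
        if (aj < 0) { aj <- 0; ai <- s }
        if (ai < 0) { ai <- 0; aj <- s }
      }
    }
    dai <- ai - alpha[i]
    daj <- aj - alpha[j]
    alpha[i] <- ai
    alpha[j] <- aj
    grad <- grad + y * (Ki * (y[i] * dai) + Kj * (y[j] * daj))
    w <- w + dai * y[i] * x[i, ] + daj * y[j] * x[j, ]
  }

  # bias from the converged violation interval (equals y_t - x_t . w at
  # free support vectors)
  viol <- -y * grad
  up <- (y > 0 & alpha < C - 1e-12) | (y < 0 & alpha > 1e-12)
  low <- (y > 0 & alpha > 1e-12) | (y < 0 & alpha < C - 1e-12)
  free <- alpha > 1e-8 & alpha < C - 1e-8
  g <- if (any(free)) {
    mean(viol[free])
  } else {
    (max(viol[up]) + min(viol[low])) / 2
  }

  margins <- y * (as.numeric(x %*% w) + g)
  zeta <- pmax(0, 1 - margins)
  structure(
    list(weights = as.numeric(w), bias = g, C = C, alpha = alpha,
         slacks = zeta,
         objective = 0.5 * sum(w^2) + C * sum(zeta),
         dim = ncol(x)),
    class = "margin_classifier"
  )
}

#' @export
print.margin_classifier <- function(x, ...) {
  cat(sprintf("<margin_classifier: d=%d, C=%g, |SV|=%d, primal=%.6g>\n",
              x$dim, x$C, sum(x$alpha > 1e-8), x$objective))
  invisible(x)
}

#' Classifier decision value
#'
#' `d(x) = r . x + g` for a trained model; rows of a matrix are scored
#' independently.
#'
#' @param model a `margin_classifier`.
#' @param x numeric vector of length `d`, or matrix with `d` columns.
#' @return numeric vector of decision values.
#' @export
decision_value <- function(model, x) {
  stopifnot(inherits(model, "margin_classifier"))
  if (is.vector(x)) x <- matrix(x, nrow = 1L)
  x <- as.matrix(x)
  if (ncol(x) != model$dim) {
    stop(sprintf("input has %d columns, model expects %d",
                 ncol(x), model$dim), call. = FALSE)
  }
  as.numeric(x %*% model$weights + model$bias)
}

#' Fit the sigmoid probability calibration
#'
#' Fits conversion parameters `(S, F)` of
#' `P(y = 1 | d) = 1 / (1 + exp(S * d + F))` by maximizing the Bernoulli
#' log-likelihood with Platt-style smoothed targets
#' `(N+ + 1) / (N+ + 2)` for positives and `1 / (N- + 2)` for negatives,
#' which keeps the parameters finite on perfectly separated data. When
#' larger decision values accompany the positive class the fitted `S` is
#' negative.
#'
#' @param decision_values numeric vector.
#' @param labels vector in \{-1, +1\}, both classes present.
#' @return object of class `calibration` with fields `S` and `F`.
#' @examples
#' d <- c(-2, -1, 1, 2)
#' y <- c(-1, -1, 1, 1)
#' cal <- fit_calibration(d, y)
#' cal$S < 0
#' @export
fit_calibration <- function(decision_values, labels) {
  d <- as.numeric(decision_values)
  y <- as.numeric(labels)
  if (length(d) != length(y) || length(d) < 2L) {
    stop("decision values and labels must have equal length >= 2",
         call. = FALSE)
  }
  if (!all(y %in% c(-1, 1)) || length(unique(y)) < 2L) {
    stop("calibration requires both labels -1 and +1 present",
         call. = FALSE)
  }
  npos <- sum(y > 0)
  nneg <- sum(y < 0)
  t <- ifelse(y > 0, (npos + 1) / (npos + 2), 1 / (nneg + 2))

  nll <- function(par) {
    eta <- par[1] * d + par[2]
    # p = 1/(1+exp(eta)) = plogis(-eta); log-lik in numerically safe form
    -sum(t * stats::plogis(-eta, log.p = TRUE) +
           (1 - t) * stats::plogis(eta, log.p = TRUE))
  }
  gr <- function(par) {
    eta <- par[1] * d + par[2]
    p <- stats::plogis(-eta)
    resid <- t - p            # d(nll)/d(eta) = t - p
    c(sum(resid * d), sum(resid))
  }
  fit <- stats::optim(c(0, 0), nll, gr, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-14))
  structure(list(S = fit$par[1], F = fit$par[2], value = fit$value),
            class = "calibration")
}

#' @export
print.calibration <- function(x, ...) {
  cat(sprintf("<calibration: S=%.4g, F=%.4g>\n", x$S, x$F))
  invisible(x)
}

#' Diabetes Index of an input
#'
#' Calibrated probability `DI(x) = 1 / (1 + exp(S * d(x) + F))` that the
#' input belongs to the diabetic class; always in `[0, 1]`, and a
#' strictly monotone function of the decision value whenever `S != 0`.
#'
#' @param model a trained `margin_classifier`.
#' @param cal a fitted `calibration`.
#' @param x input vector or matrix of inputs (rows).
#' @return numeric vector of probabilities in `[0, 1]`.
#' @export
diabetes_index <- function(model, cal, x) {
  stopifnot(inherits(cal, "calibration"))
  d <- decision_value(model, x)
  calibrated_probability(cal, d)
}

#' Apply a fitted calibration to decision values
#'
#' @param cal a `calibration`.
#' @param d numeric decision values.
#' @return probabilities `1 / (1 + exp(S * d + F))` in `[0, 1]`.
#' @export
calibrated_probability <- function(cal, d) {
  stopifnot(inherits(cal, "calibration"))
  stats::plogis(-(cal$S * as.numeric(d) + cal$F))
}

#' Train classifier and calibration together
#'
#' Trains the margin classifier on the full data and fits the sigmoid
#' calibration on out-of-fold decision values (default 3 folds) to avoid
#' the optimism of in-sample calibration.
#'
#' @param x input matrix.
#' @param y labels in \{-1, +1\}.
#' @param C penalty.
#' @param folds number of calibration folds (>= 2); folds are assigned
#'   round-robin in data order so the split is deterministic.
#' @return list with `model` (`margin_classifier`) and `calibration`.
#' @export
fit_risk_model <- function(x, y, C = 1, folds = 3L) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  folds <- check_count(folds, "folds", min = 2L)
  m <- nrow(x)
  fold_id <- rep_len(seq_len(folds), m)
  d_oof <- numeric(m)
  for (k in seq_len(folds)) {
    tr <- fold_id != k
    if (length(unique(y[tr])) < 2L) {
      stop("a calibration fold lost one class; use fewer folds",
           call. = FALSE)
    }
    mk <- train_classifier(x[tr, , drop = FALSE], y[tr], C = C)
    d_oof[!tr] <- decision_value(mk, x[!tr, , drop = FALSE])
  }
  list(model = train_classifier(x, y, C = C),
       calibration = fit_calibration(d_oof, y))
}
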