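#' Longitudinal patient record containers and decay-weighted aggregation
#'
#' A patient's clinical history is a time-ordered set of sub-records, each a
#' timestamp plus a fixed-dimension vector of numeric indicator values. To
#' feed a fixed-length classifier input, the history is collapsed into a
#' single vector by a decay-weighted average in which recent records carry
#' more weight.
#'
#' @name records
NULL

#' Construct a patient history
#'
#' @param patient_id identifier (coerced to character).
#' @param timestamps integer day offsets, one per sub-record; sorted
#'   ascending together with `features` (stable for ties).
#' @param features numeric matrix, one row per sub-record, `d` columns of
#'   indicator values. A vector is treated as a single-column matrix when
#'   one record is supplied, otherwise as a single record.
#' @return an object of class `patient_history` with fields `patient_id`,
#'   `timestamps`, `features` and record count `l`.
#' @examples
#' h <- patient_history("p1", c(0, 7, 9), matrix(rnorm(6), 3, 2))
#' h$l
#' @export
patient_history <- function(patient_id, timestamps, features) {
  if (is.vector(features)) features <- matrix(features, nrow = 1L)
  features <- as.matrix(features)
  storage.mode(features) <- "double"
  if (!is.numeric(timestamps) || length(timestamps) != nrow(features)) {
    stop("`timestamps` must be numeric with one entry per feature row",
         call. = FALSE)
  }
  if (nrow(features) < 1L) stop("history must contain >= 1 sub-record",
                                call. = FALSE)
  if (any(!is.finite(features))) {
    bad <- which(rowSums(!is.finite(features)) > 0L)[1L]
    stop(sprintf("non-finite feature value in sub-record %d of patient %s",
                 bad, patient_id), call. = FALSE)
  }
  ord <- order(timestamps)  # stable: ties keep input order
  structure(
    list(patient_id = as.character(patient_id),
         timestamps = as.numeric(timestamps)[ord],
         features = features[ord, , drop = FALSE],
         l = nrow(features)),
    class = "patient_history"
  )
}

#' @export
print.patient_history <- function(x, ...) {
  cat(sprintf("<patient_history %s: %d records x %d features, days %g..%g>\n",
              x$patient_id, x$l, ncol(x$features),
              min(x$timestamps), max(x$timestamps)))
  invisible(x)
}

#' Normalized exponential decay weights
#'
#' Computes the weight vector `Ph` with `Ph[b] = exp(-alpha * b) /
#' sum(exp(-alpha * k), k = 0..l-1)` for `b = 0..l-1` (0-indexed
#' internally; element `b + 1` of the returned vector is `Ph[b]`). With
#' `alpha = 0` the weights are uniform; with `alpha > 0` they decrease
#' strictly in `b` and always sum to 1.
#'
#' @param l positive integer, number of records spanned.
#' @param alpha non-negative decay rate per record rank.
#' @return numeric vector of length `l`, positive, summing to 1.
#' @examples
#' decay_weights(3, 0)        # uniform 1/3
#' decay_weights(2, log(2))   # 2/3, 1/3
#' @export
decay_weights <- function(l, alpha) {
  l <- check_count(l, "l", min = 1L)
  alpha <- check_scalar(alpha, "alpha", min = 0)
  b <- seq_len(l) - 1L
  # subtract nothing: exponents are <= 0, no overflow risk
  w <- exp(-alpha * b)
  w / sum(w)
}

#' Decay-weighted risk input vector
#'
#' Collapses a patient history into the fixed-length risk input
#' `x = sum_{b=1}^{l} Ph[l - b] * f_b`, where `f_b` is the feature vector
#' of the b-th record in time order and `Ph` are [decay_weights]. The
#' index shift means the most recent record (`b = l`) receives the largest
#' weight `Ph[0]`.
#'
#' @param history a [patient_history].
#' @param alpha non-negative decay rate.
#' @return numeric vector of length `d` (the feature dimension).
#' @examples
#' h <- patient_history("p", c(0, 3), rbind(c(1, 0), c(0, 1)))
#' risk_input(h, 0)       # plain mean
#' risk_input(h, 10)      # nearly the latest record
#' @export
risk_input <- function(history, alpha) {
  stopifnot(inherits(history, "patient_history"))
  w <- decay_weights(history$l, alpha)
  # record b (1-indexed, oldest first) gets Ph[l - b], i.e. rev(w)
  as.numeric(crossprod(history$features, rev(w)))
}

#' Risk input matrix for a whole cohort
#'
#' Applies [risk_input] to every history in a cohort and returns the
#' labeled design matrix used for classifier training.
#'
#' @param cohort a `glycorisk_cohort` from [generate_cohort] or
#'   [read_cohort].
#' @param alpha non-negative decay rate.
#' @return list with `inputs` (n x d matrix, rownames = patient ids) and
#'   `labels` (integer vector in -1/+1).
#' @export
cohort_risk_inputs <- function(cohort, alpha) {
  stopifnot(inherits(cohort, "glycorisk_cohort"))
  X <- t(vapply(cohort$histories, risk_input, alpha = alpha,
                FUN.VALUE = numeric(cohort$n_features)))
  if (cohort$n_features == 1L) X <- matrix(X, ncol = 1L)
  rownames(X) <- vapply(cohort$histories, `[[`, "", "patient_id")
  list(inputs = X, labels = cohort$labels)
}
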