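# Independent oracles used across the suite. Each re-derives the checked
# quantity by brute force (loops, enumeration, generic solvers), never by
# calling the implementation path it verifies.

# Eq.-style decay-weighted aggregation as an explicit double loop.
loop_risk_input_oracle <- function(features, alpha) {
  l <- nrow(features)
  denom <- 0
  for (k in 0:(l - 1)) denom <- denom + exp(-alpha * k)
  x <- numeric(ncol(features))
  for (b in 1:l) {
    w <- exp(-alpha * (l - b)) / denom
    for (j in seq_len(ncol(features))) x[j] <- x[j] + w * features[b, j]
  }
  x
}

# Soft-margin primal optimum via a generic QP solver on the dual
# (kernlab::ipop), with the bias recovered by 1-D convex minimization of
# the hinge objective.
qp_primal_oracle <- function(X, y, C) {
  K <- X %*% t(X)
  H <- (y %o% y) * K
  sol <- kernlab::ipop(c = rep(-1, nrow(X)), H = H,
                       A = matrix(y, 1), b = 0,
                       l = rep(0, nrow(X)), u = rep(C, nrow(X)), r = 0)
  a <- kernlab::primal(sol)
  w <- as.numeric(t(X) %*% (a * y))
  primal <- function(g) 0.5 * sum(w^2) + C * sum(pmax(0, 1 - y * (X %*% w + g)))
  opt <- stats::optimize(primal, c(-50, 50), tol = 1e-12)
  list(w = w, g = opt$minimum, objective = opt$objective)
}

# Full enumeration of the RBM joint distribution.
enum_rbm_joint <- function(params) {
  Zs <- as.matrix(expand.grid(rep(list(c(0, 1)), params$m)))
  Xs <- as.matrix(expand.grid(rep(list(c(0, 1)), params$n_hidden)))
  un <- matrix(0, nrow(Zs), nrow(Xs))
  for (i in seq_len(nrow(Zs))) {
    for (j in seq_len(nrow(Xs))) {
      e <- -sum(params$b * Zs[i, ]) - sum(params$c * Xs[j, ]) -
        as.numeric(t(Zs[i, ]) %*% params$W %*% Xs[j, ])
      un[i, j] <- exp(-e)
    }
  }
  list(Zs = Zs, Xs = Xs, unnorm = un, B = sum(un))
}

enum_hidden_conditional <- function(joint, z) {
  zi <- which(apply(joint$Zs, 1, function(r) all(r == z)))
  vapply(seq_len(ncol(joint$Xs)), function(j) {
    sum(joint$unnorm[zi, joint$Xs[, j] == 1]) / sum(joint$unnorm[zi, ])
  }, numeric(1))
}

enum_visible_conditional <- function(joint, x) {
  xj <- which(apply(joint$Xs, 1, function(r) all(r == x)))
  vapply(seq_len(ncol(joint$Zs)), function(i) {
    sum(joint$unnorm[joint$Zs[, i] == 1, xj]) / sum(joint$unnorm[, xj])
  }, numeric(1))
}

# Relatedness by exhaustive path counting: sum (1/2)^len over all
# up-then-down paths X -> peak -> Y whose up and down legs share only
# the peak. Valid for non-inbred pedigrees, where the up-path to each
# ancestor is unique.
path_sum_oracle <- function(ped, X, Y) {
  up_paths <- function(id) {
    # list of vectors id -> ... -> ancestor (all ancestors incl. self)
    out <- list(id)
    frontier <- list(id)
    while (length(frontier)) {
      nxt <- list()
      for (p in frontier) {
        last <- p[length(p)]
        f <- ped$father[[last]]
        m <- ped$mother[[last]]
        for (par in c(f, m)) {
          if (par != "0") {
            np <- c(p, par)
            out <- c(out, list(np))
            nxt <- c(nxt, list(np))
          }
        }
      }
      frontier <- nxt
    }
    out
  }
  px <- up_paths(X)
  py <- up_paths(Y)
  total <- 0
  for (a in px) {
    for (b in py) {
      peak_a <- a[length(a)]
      peak_b <- b[length(b)]
      if (peak_a == peak_b) {
        shared <- intersect(a, b)
        if (identical(shared, peak_a)) {
          total <- total + 0.5^(length(a) - 1 + length(b) - 1)
        }
      }
    }
  }
  total
}

sigmoidm <- function(x) 1 / (1 + exp(-x))

# Walk-forward one-step predictions over target positions `pos`: for each
# p the model sees series[1..p-1] and predicts value p (forecast() with
# horizon 1 withholds the final value as the actual).
one_step_predictions <- function(fit, values, pos) {
  vapply(pos, function(p) {
    forecast(fit$params, fit$encoding, values[seq_len(p)],
             horizon = 1)$predicted
  }, numeric(1))
}

# Small handcrafted three-generation pedigree with first cousins:
#   gp1 x gp2 -> sib1, sib2; sib1 x sp1 -> cous1; sib2 x sp2 -> cous2
cousin_pedigree <- function(affected = c(gp1 = 1)) {
  ids <- c("gp1", "gp2", "sp1", "sp2", "sib1", "sib2", "cous1", "cous2")
  df <- data.frame(
    id = ids,
    father = c("0", "0", "0", "0", "gp1", "gp1", "sp1", "sp2"),
    mother = c("0", "0", "0", "0", "gp2", "gp2", "sib1", "sib2"),
    affected = as.integer(ids %in% names(affected)[affected == 1]),
    stringsAsFactors = FALSE
  )
  pedigree(df)
}
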