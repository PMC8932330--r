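# One-vs-one RBF support vector machine built on the package's SMO dual
# solver. The kernel is phi(x, z) = exp(-||x - z||^2 / sigma^2) (note the
# sigma^2 parameterization, not the 1/(2 sigma^2) convention).

#' Train a binary soft-margin RBF SVM
#'
#' Solves the dual quadratic program with sequential minimal optimization.
#'
#' @param X numeric matrix (rows = samples).
#' @param y labels in `{-1, +1}`.
#' @param C soft-margin penalty (> 0).
#' @param sigma RBF kernel width (> 0).
#' @param tol KKT violation tolerance for the solver (default 1e-6).
#' @return List of class `binary_svm` with support vectors `sv`, dual
#'   coefficients `alpha` (for all training points), `coef` (`alpha * y`
#'   restricted to support vectors), bias `b`, and the hyperparameters.
#' @export
train_binary_svm <- function(X, y, C = 10, sigma = sqrt(11), tol = 1e-6) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (!all(y %in% c(-1, 1))) ff_stop_invalid("binary labels must be -1/+1")
  if (length(unique(y)) < 2L) ff_stop_invalid("both classes must be present")
  check_scalar(C, "C", positive = TRUE)
  check_scalar(sigma, "sigma", positive = TRUE)
  K <- cpp_rbf_kernel(X, X, sigma)
  sol <- cpp_smo_solve(K, y, C, tol = tol)
  alpha <- sol$alpha
  sv_idx <- which(alpha > 1e-8)
  structure(
    list(sv = X[sv_idx, , drop = FALSE], coef = alpha[sv_idx] * y[sv_idx],
         alpha = alpha, y = y, b = sol$b, C = C, sigma = sigma,
         iterations = sol$iterations, gap = sol$gap),
    class = "binary_svm"
  )
}

#' Decision values of a binary SVM
#'
#' `f(x) = sum_i alpha_i y_i phi(x, x_i) + b`.
#'
#' @param model a `binary_svm`.
#' @param X matrix of query points (rows).
#' @return Numeric vector of decision values; the predicted label is their
#'   sign.
#' @export
svm_decision <- function(model, X) {
  stopifnot(inherits(model, "binary_svm"))
  X <- as.matrix(X)
  if (nrow(model$sv) == 0L) return(rep(model$b, nrow(X)))
  K <- cpp_rbf_kernel(X, model$sv, model$sigma)
  as.numeric(K %*% model$coef + model$b)
}

ovo_pairs <- function() list(c(-1, 0), c(-1, 1), c(0, 1))

#' Train a one-vs-one multiclass SVM for the three fatigue states
#'
#' Trains three binary RBF sub-models, one per state pair ((-1,0), (-1,1),
#' (0,1)); within a pair the larger state label is coded +1.
#'
#' @param X numeric matrix of (fused) feature vectors.
#' @param y state labels in `{-1, 0, 1}`.
#' @inheritParams train_binary_svm
#' @return List of class `ovo_svm` with the three sub-models.
#' @export
train_ovo_svm <- function(X, y, C = 10, sigma = sqrt(11), tol = 1e-6) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  classes <- c(-1, 0, 1)
  missing <- setdiff(classes, unique(y))
  if (length(missing))
    ff_stop_invalid(sprintf("class(es) %s absent from the training data",
                            paste(missing, collapse = ", ")))
  subs <- lapply(ovo_pairs(), function(pr) {
    sel <- y %in% pr
    yy <- ifelse(y[sel] == max(pr), 1, -1)
    m <- train_binary_svm(X[sel, , drop = FALSE], yy, C = C, sigma = sigma,
                          tol = tol)
    m$pair <- pr
    m
  })
  structure(list(models = subs, classes = classes, C = C, sigma = sigma),
            class = "ovo_svm")
}

#' Predict fatigue states with a one-vs-one SVM
#'
#' Each sub-model votes for one state of its pair; the majority state wins.
#' A three-way tie is broken by the largest total absolute decision value
#' accumulated by each state, then by the lowest state label — both
#' deterministic.
#'
#' @param object an `ovo_svm` model.
#' @param newdata matrix of query feature vectors (rows).
#' @param ... unused.
#' @return Numeric vector of predicted states in `{-1, 0, 1}`.
#' @export
predict.ovo_svm <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  n <- nrow(X)
  classes <- object$classes
  votes <- matrix(0, n, length(classes),
                  dimnames = list(NULL, as.character(classes)))
  score <- votes
  for (m in object$models) {
    dec <- svm_decision(m, X)
    hi <- as.character(max(m$pair))
    lo <- as.character(min(m$pair))
    win <- ifelse(dec >= 0, hi, lo)
    for (k in seq_len(n)) {
      votes[k, win[k]] <- votes[k, win[k]] + 1
      score[k, win[k]] <- score[k, win[k]] + abs(dec[k])
    }
  }
  vapply(seq_len(n), function(k) {
    v <- votes[k, ]
    best <- which(v == max(v))
    if (length(best) > 1L) {
      s <- score[k, best]
      best <- best[s == max(s)]
    }
    classes[best[1L]]  # lowest label among remaining ties
  }, numeric(1))
}

# Per-feature z-scoring with training-set statistics; constant features get
# unit scale so they standardize to zero rather than NaN.
fit_scaler <- function(X) {
  mu <- colMeans(X)
  sdv <- apply(X, 2L, sd)
  sdv[sdv < 1e-12] <- 1
  list(mean = mu, sd = sdv)
}

apply_scaler <- function(X, scaler) {
  sweep(sweep(as.matrix(X), 2L, scaler$mean, "-"), 2L, scaler$sd, "/")
}
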