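# Particle-swarm-optimized feature fusion. Each feature vector is the
# concatenation of an ECG block (a = 3 features) and an sEMG block (b = 8),
# and a fusion coefficient vector d of length a + b = 11 weights the
# (standardized) features elementwise before classification. The weights act
# as trust degrees per feature; the swarm searches the simplex-like set
# {d >= 0, sum(d) = 11} for the coefficients maximizing the recognition rate
# of a one-vs-one RBF-SVM on an inner validation split.

N_FEATURES <- 11L

#' Fuse a feature matrix with fusion coefficients
#'
#' Elementwise product `x_i = [d_1 f_i1, ..., d_a f_ia, d_{a+1} e_i1, ...,
#' d_{a+b} e_ib]` applied row-wise.
#'
#' @param X numeric matrix (rows = samples, 11 columns).
#' @param d fusion coefficient vector of length 11.
#' @return The fused matrix.
#' @export
fuse <- function(X, d) {
  X <- as.matrix(X)
  if (length(d) != ncol(X))
    ff_stop_invalid(sprintf("fusion vector length %d does not match %d features",
                            length(d), ncol(X)))
  sweep(X, 2L, as.numeric(d), "*")
}

# Project a coefficient vector onto {d >= 0, sum(d) = n}: clip negatives,
# rescale; an all-zero vector resets to uniform weights.
project_coefficients <- function(d, total = N_FEATURES) {
  d <- pmax(d, 0)
  s <- sum(d)
  if (s < 1e-12) return(rep(total / length(d), length(d)))
  d * (total / s)
}

#' Swarm configuration
#'
#' @param q swarm size (>= 1). Desk-scale default 50; the study-scale profile
#'   uses 2000.
#' @param c1,c2 cognitive and social learning factors (default 0.5 each).
#' @param omega inertia weight (default 0.8).
#' @param h_e expected fitness in `[0, 1]`: the swarm stops once the global
#'   best recognition rate reaches it (default 0.95).
#' @param max_iter iteration cap (default 100).
#' @param v_max per-dimension velocity bound (default 2).
#' @param seed integer seed for the swarm's randomness.
#' @return List of class `swarm_config`.
#' @export
swarm_config <- function(q = 50L, c1 = 0.5, c2 = 0.5, omega = 0.8,
                         h_e = 0.95, max_iter = 100L, v_max = 2,
                         seed = NULL) {
  if (q < 1) ff_stop_invalid("`q` must be >= 1")
  if (c1 < 0 || c2 < 0 || omega < 0)
    ff_stop_invalid("`c1`, `c2`, `omega` must be >= 0")
  if (h_e < 0 || h_e > 1) ff_stop_invalid("`h_e` must be in [0, 1]")
  if (max_iter < 1) ff_stop_invalid("`max_iter` must be >= 1")
  structure(list(q = as.integer(q), c1 = c1, c2 = c2, omega = omega,
                 h_e = h_e, max_iter = as.integer(max_iter), v_max = v_max,
                 seed = seed),
            class = "swarm_config")
}

#' Recognition-rate fitness of a fusion coefficient vector
#'
#' Trains a one-vs-one RBF-SVM on the fused training split and returns the
#' recognition rate (fraction of correctly identified samples) on the fused
#' evaluation split.
#'
#' @param d fusion coefficient vector (length 11).
#' @param X_train,y_train training split (standardized features and labels).
#' @param X_eval,y_eval evaluation split.
#' @param C,sigma SVM hyperparameters.
#' @return Recognition rate in `[0, 1]`.
#' @export
fusion_fitness <- function(d, X_train, y_train, X_eval, y_eval,
                           C = 10, sigma = sqrt(11)) {
  if (length(y_train) == 0L || length(y_eval) == 0L)
    ff_stop_invalid("fitness splits must be non-empty")
  model <- train_ovo_svm(fuse(X_train, d), y_train, C = C, sigma = sigma,
                         tol = 1e-3)
  recognition_rate(predict(model, fuse(X_eval, d)), y_eval)
}

#' Particle swarm optimization of the fusion coefficients
#'
#' Standard inertia-weight PSO over the constrained coefficient space: after
#' every velocity/position update each particle is re-projected onto
#' `{d >= 0, sum(d) = 11}`. Per-particle and global bests are tracked and the
#' swarm stops as soon as the global best fitness reaches the expected
#' fitness `h_e`, or after `max_iter` iterations. Fully deterministic for a
#' fixed `cfg$seed`.
#'
#' @param fitness_fn function taking a coefficient vector and returning a
#'   fitness in `[0, 1]` (see [fusion_fitness()]).
#' @param cfg a [swarm_config()].
#' @param n_dim dimension of the coefficient vector (default 11).
#' @return List with `d` (best coefficients), `fitness` (its fitness),
#'   `history` (global-best trace per iteration, non-decreasing) and
#'   `iterations`.
#' @export
pso_optimize <- function(fitness_fn, cfg = swarm_config(), n_dim = N_FEATURES) {
  stopifnot(inherits(cfg, "swarm_config"))
  with_seed(cfg$seed, {
    q <- cfg$q
    pos <- t(vapply(seq_len(q), function(i)
      project_coefficients(runif(n_dim), total = n_dim), numeric(n_dim)))
    vel <- matrix(runif(q * n_dim, -1, 1), q, n_dim)
    fit <- apply(pos, 1L, fitness_fn)
    pbest <- pos
    pbest_fit <- fit
    g <- which.max(fit)
    gbest <- pos[g, ]
    gbest_fit <- fit[g]
    history <- gbest_fit
    iter <- 1L
    while (gbest_fit < cfg$h_e && iter < cfg$max_iter) {
      iter <- iter + 1L
      r1 <- matrix(runif(q * n_dim), q, n_dim)
      r2 <- matrix(runif(q * n_dim), q, n_dim)
      vel <- cfg$omega * vel +
        cfg$c1 * r1 * (pbest - pos) +
        cfg$c2 * r2 * (matrix(gbest, q, n_dim, byrow = TRUE) - pos)
      vel <- pmin(pmax(vel, -cfg$v_max), cfg$v_max)
      pos <- pos + vel
      pos <- t(apply(pos, 1L, project_coefficients, total = n_dim))
      fit <- apply(pos, 1L, fitness_fn)
      improved <- fit > pbest_fit
      pbest[improved, ] <- pos[improved, , drop = FALSE]
      pbest_fit[improved] <- fit[improved]
      g <- which.max(pbest_fit)
      if (pbest_fit[g] > gbest_fit) {
        gbest_fit <- pbest_fit[g]
        gbest <- pbest[g, ]
      }
      history <- c(history, gbest_fit)
    }
    list(d = gbest, fitness = gbest_fit, history = history, iterations = iter)
  })
}

# Stratified index split: returns indices of the first part at fraction p.
stratified_split <- function(y, p) {
  idx <- unlist(lapply(unique(y), function(cl) {
    pool <- which(y == cl)
    k <- max(1L, round(p * length(pool)))
    if (k >= length(pool)) k <- length(pool) - 1L
    if (k < 1L) ff_stop_invalid("class too small to split")
    sample(pool, k)
  }))
  sort(idx)
}

#' Fit the full IPSO-SVM fusion classifier
#'
#' End-to-end training: z-score standardization (training statistics), an
#' inner stratified 70/30 split for leakage-free fitness evaluation, particle
#' swarm optimization of the fusion coefficients, then a final one-vs-one
#' RBF-SVM trained on the whole (fused) training set with the optimal
#' coefficients.
#'
#' @param X numeric matrix of 11 raw (unstandardized) features.
#' @param y state labels in `{-1, 0, 1}`.
#' @param cfg a [swarm_config()]; its seed drives the inner split and swarm.
#' @param C,sigma SVM hyperparameters (defaults C = 10, sigma = sqrt(11), a
#'   feature-count heuristic).
#' @param inner_fraction fraction of the training data used to train during
#'   fitness evaluation (default 0.7).
#' @param columns optional column subset (e.g. a single modality block); the
#'   fusion vector then has that many entries and sums to its length.
#' @return List of class `ipso_svm` with the final `model`, optimal
#'   coefficients `d`, the `scaler`, `history`, `iterations` and `fitness`.
#' @export
fit_ipso_svm <- function(X, y, cfg = swarm_config(), C = 10, sigma = sqrt(11),
                         inner_fraction = 0.7, columns = NULL) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (!is.null(columns)) X <- X[, columns, drop = FALSE]
  if (length(setdiff(c(-1, 0, 1), unique(y))))
    ff_stop_invalid("all three states must be present in the training data")
  scaler <- fit_scaler(X)
  Xs <- apply_scaler(X, scaler)
  n_dim <- ncol(Xs)
  res <- with_seed(cfg$seed, {
    tr <- stratified_split(y, inner_fraction)
    ev <- setdiff(seq_along(y), tr)
    inner_cfg <- cfg
    inner_cfg$seed <- NULL  # already inside the seeded RNG stream
    pso_optimize(function(d)
      fusion_fitness(d, Xs[tr, , drop = FALSE], y[tr],
                     Xs[ev, , drop = FALSE], y[ev], C = C, sigma = sigma),
      cfg = inner_cfg, n_dim = n_dim)
  })
  model <- train_ovo_svm(fuse(Xs, res$d), y, C = C, sigma = sigma)
  structure(list(model = model, d = res$d, scaler = scaler,
                 history = res$history, iterations = res$iterations,
                 fitness = res$fitness, C = C, sigma = sigma,
                 columns = columns),
            class = "ipso_svm")
}

#' @export
predict.ipso_svm <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (!is.null(object$columns)) X <- X[, object$columns, drop = FALSE]
  Xs <- apply_scaler(X, object$scaler)
  predict(object$model, fuse(Xs, object$d))
}

#' @export
print.ipso_svm <- function(x, ...) {
  cat(sprintf("<ipso_svm> %d features, %d PSO iterations, inner fitness %.4f\n",
              length(x$d), x$iterations, x$fitness))
  cat("fusion coefficients:\n")
  print(round(x$d, 3))
  invisible(x)
}
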