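#' Recognition rate
#'
#' Fraction of test samples correctly identified.
#'
#' @param predictions,truths equal-length label vectors.
#' @return Rate in `[0, 1]`.
#' @export
recognition_rate <- function(predictions, truths) {
  if (length(predictions) == 0L) ff_stop_invalid("empty label sequences")
  if (length(predictions) != length(truths))
    ff_stop_invalid("prediction and truth lengths differ")
  mean(predictions == truths)
}

# Per-class recognition rates and 3x3 confusion matrix (rows = truth).
class_rates <- function(predictions, truths, classes = c(-1, 0, 1)) {
  cm <- table(factor(truths, levels = classes),
              factor(predictions, levels = classes))
  per <- diag(cm) / pmax(rowSums(cm), 1L)
  list(confusion = unclass(cm), per_class = as.numeric(per))
}

#' Classifier factories
#'
#' Each factory returns a list with `name`, `fit(X, y)` and
#' `predict(model, X)` so every classifier runs through the identical MCCV
#' path. Baselines standardize features internally with training-set
#' statistics and operate on the unfused feature matrix.
#'
#' @param cfg a [swarm_config()] for the IPSO-SVM (the per-split seed is
#'   supplied by [mccv()]).
#' @param C,sigma SVM hyperparameters.
#' @param columns optional feature-column subset (modality selection).
#' @return A classifier factory list.
#' @name classifier_factories
NULL

#' @rdname classifier_factories
#' @export
clf_ipso_svm <- function(cfg = swarm_config(), C = 10, sigma = sqrt(11),
                         columns = NULL) {
  list(name = "ipso_svm",
       fit = function(X, y, split_seed = NULL) {
         c2 <- cfg
         if (!is.null(split_seed)) c2$seed <- split_seed
         fit_ipso_svm(X, y, cfg = c2, C = C, sigma = sigma, columns = columns)
       },
       predict = function(model, X) predict(model, X))
}

#' @rdname classifier_factories
#' @export
clf_svm <- function(C = 10, sigma = sqrt(11), columns = NULL) {
  # identity-fusion SVM: plain OVO RBF-SVM on standardized features
  list(name = "svm",
       fit = function(X, y, split_seed = NULL) {
         X <- as.matrix(X)
         if (!is.null(columns)) X <- X[, columns, drop = FALSE]
         scaler <- fit_scaler(X)
         model <- train_ovo_svm(apply_scaler(X, scaler), y, C = C, sigma = sigma)
         list(model = model, scaler = scaler, columns = columns)
       },
       predict = function(m, X) {
         X <- as.matrix(X)
         if (!is.null(m$columns)) X <- X[, m$columns, drop = FALSE]
         predict(m$model, apply_scaler(X, m$scaler))
       })
}

#' @param size hidden layer width for the BP neural network (default 16).
#' @param decay weight decay for the BP neural network (default 5e-4).
#' @param maxit training iteration cap (default 300).
#' @rdname classifier_factories
#' @export
clf_bpnn <- function(size = 16L, decay = 5e-4, maxit = 300L, columns = NULL) {
  list(name = "bpnn",
       fit = function(X, y, split_seed = NULL) {
         X <- as.matrix(X)
         if (!is.null(columns)) X <- X[, columns, drop = FALSE]
         scaler <- fit_scaler(X)
         Xs <- apply_scaler(X, scaler)
         yf <- factor(y, levels = c(-1, 0, 1))
         net <- with_seed(split_seed %||% 0,
           nnet::nnet(Xs, nnet::class.ind(yf), size = size, decay = decay,
                      maxit = maxit, softmax = TRUE, trace = FALSE))
         list(net = net, scaler = scaler, columns = columns)
       },
       predict = function(m, X) {
         X <- as.matrix(X)
         if (!is.null(m$columns)) X <- X[, m$columns, drop = FALSE]
         pr <- predict(m$net, apply_scaler(X, m$scaler))
         c(-1, 0, 1)[max.col(pr, ties.method = "first")]
       })
}

#' @param k neighbour count for KNN (default 5).
#' @rdname classifier_factories
#' @export
clf_knn <- function(k = 5L, columns = NULL) {
  list(name = "knn",
       fit = function(X, y, split_seed = NULL) {
         X <- as.matrix(X)
         if (!is.null(columns)) X <- X[, columns, drop = FALSE]
         scaler <- fit_scaler(X)
         list(X = apply_scaler(X, scaler), y = factor(y, levels = c(-1, 0, 1)),
              scaler = scaler, k = k, columns = columns,
              seed = split_seed %||% 0)
       },
       predict = function(m, X) {
         X <- as.matrix(X)
         if (!is.null(m$columns)) X <- X[, m$columns, drop = FALSE]
         # class::knn breaks distance/vote ties at random; seed it so
         # evaluations are reproducible
         with_seed(m$seed, as.numeric(as.character(
           class::knn(m$X, apply_scaler(X, m$scaler), m$y, k = m$k))))
       })
}

#' @rdname classifier_factories
#' @export
clf_lda <- function(columns = NULL) {
  list(name = "lda",
       fit = function(X, y, split_seed = NULL) {
         X <- as.matrix(X)
         if (!is.null(columns)) X <- X[, columns, drop = FALSE]
         scaler <- fit_scaler(X)
         # IEMG/RMS (and MPF/MF) are strongly collinear by construction;
         # lda warns about that on small samples, harmlessly
         list(fit = suppressWarnings(
                MASS::lda(apply_scaler(X, scaler),
                          grouping = factor(y, levels = c(-1, 0, 1)))),
              scaler = scaler, columns = columns)
       },
       predict = function(m, X) {
         X <- as.matrix(X)
         if (!is.null(m$columns)) X <- X[, m$columns, drop = FALSE]
         as.numeric(as.character(
           predict(m$fit, apply_scaler(X, m$scaler))$class))
       })
}

#' Monte Carlo cross-validation
#'
#' Repeated stratified random train/test splitting: the classifier is
#' trained fresh on each split and evaluated on the held-out fraction.
#' Split indices are derived deterministically from `seed`, so two
#' classifiers evaluated with the same `seed` see identical splits (paired
#' comparison).
#'
#' @param X feature matrix (11 columns) or the data.frame from
#'   [extract_feature_table()] (feature columns are taken by name).
#' @param y labels in `{-1, 0, 1}` (taken from `X$label` when omitted and
#'   `X` is a data.frame).
#' @param classifier a factory from [classifier_factories].
#' @param n_rep number of repetitions (default 20).
#' @param test_fraction held-out fraction in (0, 1) (default 0.3).
#' @param seed integer seed controlling the splits and per-split classifier
#'   seeds.
#' @return List of class `evaluation_report`: `classifier`, `mean_rate`,
#'   `per_class_rate` (named by state), `confusion` (3x3 counts summed over
#'   repetitions, rows = truth), `rep_rates`, `n_rep`, `test_fraction`,
#'   `seed`.
#' @export
mccv <- function(X, y = NULL, classifier = clf_svm(), n_rep = 20L,
                 test_fraction = 0.3, seed = NULL) {
  if (is.data.frame(X)) {
    if (is.null(y)) y <- X$label
    X <- as.matrix(X[, feature_names()])
  }
  y <- as.numeric(y)
  if (is.null(y) || anyNA(y)) ff_stop_invalid("labels are required")
  if (n_rep < 1) ff_stop_invalid("`n_rep` must be >= 1")
  if (test_fraction <= 0 || test_fraction >= 1)
    ff_stop_invalid("`test_fraction` must be in (0, 1)")
  split_seeds <- derive_seeds(seed %||% 0, n_rep, salt = 7L)
  classes <- c(-1, 0, 1)
  conf <- matrix(0L, 3L, 3L, dimnames = list(classes, classes))
  rep_rates <- numeric(n_rep)
  per_class_acc <- matrix(0, n_rep, 3L)
  for (r in seq_len(n_rep)) {
    tr <- with_seed(split_seeds[r], stratified_split(y, 1 - test_fraction))
    te <- setdiff(seq_along(y), tr)
    if (length(unique(y[tr])) < length(unique(y)))
      ff_stop("a class vanished from a training split; lower `test_fraction`",
              "fatiguefuse_stratification_error")
    model <- classifier$fit(X[tr, , drop = FALSE], y[tr],
                            split_seed = split_seeds[r])
    pred <- classifier$predict(model, X[te, , drop = FALSE])
    rep_rates[r] <- recognition_rate(pred, y[te])
    cr <- class_rates(pred, y[te], classes)
    conf <- conf + cr$confusion
    per_class_acc[r, ] <- cr$per_class
  }
  structure(list(
    classifier = classifier$name,
    mean_rate = mean(rep_rates),
    per_class_rate = stats::setNames(colMeans(per_class_acc),
                                     as.character(classes)),
    confusion = conf, rep_rates = rep_rates, n_rep = n_rep,
    test_fraction = test_fraction, seed = seed
  ), class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> %s: mean recognition rate %.2f%% over %d MCCV splits\n",
              x$classifier, 100 * x$mean_rate, x$n_rep))
  cat(sprintf("per-class (relaxed/transition/tired): %s\n",
              paste(sprintf("%.2f%%", 100 * x$per_class_rate), collapse = " / ")))
  invisible(x)
}

#' Compare ECG-only, sEMG-only and fused classification
#'
#' Runs three MCCV evaluations over identical splits (shared split seeds, so
#' the comparison is paired): the ECG feature block alone, the sEMG block
#' alone, and the fused 11-feature vector. By default all three runs use the
#' IPSO-SVM, so the comparison isolates the value of the data rather than of
#' the classifier.
#'
#' @inheritParams mccv
#' @param fused_classifier factory for the fused run (default
#'   [clf_ipso_svm()]).
#' @param single_classifier_fn function taking a column-index vector and
#'   returning a factory for a single-modality run (default an IPSO-SVM
#'   restricted to those columns; pass e.g. `function(cols)
#'   clf_svm(columns = cols)` for identity-fusion baselines).
#' @return List with `table` (data.frame: one row per modality with the
#'   three per-class rates and the mean rate) and `reports` (the three
#'   `evaluation_report`s).
#' @export
compare_modalities <- function(X, y = NULL, fused_classifier = clf_ipso_svm(),
                               single_classifier_fn = function(cols)
                                 clf_ipso_svm(columns = cols),
                               n_rep = 20L, test_fraction = 0.3, seed = NULL) {
  if (is.data.frame(X)) {
    if (is.null(y)) y <- X$label
    X <- as.matrix(X[, feature_names()])
  }
  ecg_cols <- match(ecg_feature_names(), feature_names())
  semg_cols <- match(semg_feature_names(), feature_names())
  reports <- list(
    ecg  = mccv(X, y, single_classifier_fn(ecg_cols), n_rep, test_fraction, seed),
    semg = mccv(X, y, single_classifier_fn(semg_cols), n_rep, test_fraction, seed),
    fused = mccv(X, y, fused_classifier, n_rep, test_fraction, seed)
  )
  tab <- do.call(rbind, lapply(names(reports), function(nm) {
    r <- reports[[nm]]
    data.frame(modality = nm, relaxed = r$per_class_rate[["-1"]],
               transition = r$per_class_rate[["0"]],
               tired = r$per_class_rate[["1"]], mean = r$mean_rate)
  }))
  list(table = tab, reports = reports)
}
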