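# The four classification learners: quadratic-kernel SVM (one-vs-one),
# fine (k = 1) nearest neighbour, ridge-regularised linear discriminant,
# and the random-subspace discriminant ensemble (ESD).

#' Classifier specification
#'
#' Families and hyperparameters of the classifier battery:
#' * `QSVM` — support vector machine with inhomogeneous quadratic kernel
#'   `(x.z + 1)^2`, box constraint C = 1, one-vs-one multiclass, features
#'   standardised by training mean/SD;
#' * `FKNN` — "fine" nearest neighbour: k = 1, Euclidean, equal weights;
#' * `LDA` — linear discriminant with pooled within-class covariance,
#'   ridge-regularised by `eps * mean(diag) * I`;
#' * `ESD` — ensemble of `n_learners` LDA base learners, each on a random
#'   feature subspace of dimension `subspace_dim`, combined by majority
#'   vote (ties to the larger training prior, then lexicographic).
#'
#' @param family One of `"QSVM"`, `"FKNN"`, `"LDA"`, `"ESD"`.
#' @param cost SVM box constraint (QSVM).
#' @param k Neighbour count (FKNN).
#' @param ridge LDA covariance regularisation factor.
#' @param n_learners Ensemble size (ESD).
#' @param subspace_dim Random-subspace dimension (ESD).
#' @param seed Integer seed (drives ESD subspace sampling).
#' @return Object of class `classifier_spec`.
#' @export
classifier_spec <- function(family = c("QSVM", "FKNN", "LDA", "ESD"),
                            cost = 1, k = 1L, ridge = 1e-2,
                            n_learners = 30L, subspace_dim = 128L,
                            seed = 1L) {
  family <- match.arg(family)
  stopifnot(k >= 1, n_learners >= 1, subspace_dim >= 1, cost > 0, ridge >= 0)
  structure(list(family = family, cost = cost, k = as.integer(k),
                 ridge = ridge, n_learners = as.integer(n_learners),
                 subspace_dim = as.integer(subspace_dim),
                 seed = as.integer(seed)),
            class = "classifier_spec")
}

.check_classes <- function(y) {
  y <- as.character(y)
  tab <- table(y)
  if (any(tab < 2))
    stop("every class needs at least 2 training samples; offending: ",
         paste(names(tab)[tab < 2], collapse = ", "))
  y
}

# ---- regularised LDA ------------------------------------------------------

#' Fit a ridge-regularised linear discriminant
#'
#' Pooled within-class covariance plus a ridge of `ridge * mean(diag(Sw))`
#' on the diagonal, giving linear discriminant scores with log-prior
#' intercepts. The ridge keeps the pooled covariance invertible when the
#' sample count barely exceeds the band count.
#'
#' @param X Feature matrix (n x p).
#' @param y Class labels (>= 2 samples per class).
#' @param ridge Regularisation factor relative to the mean diagonal.
#' @return Object of class `lda_ridge` with `classes`, `W`, `intercept`,
#'   `priors`.
#' @export
fit_lda_ridge <- function(X, y, ridge = 1e-2) {
  X <- as.matrix(X); y <- .check_classes(y)
  classes <- sort(unique(y))
  n <- nrow(X); b <- ncol(X)
  M <- t(vapply(classes, function(c) colMeans(X[y == c, , drop = FALSE]),
                numeric(b)))
  Sw <- matrix(0, b, b)
  for (c in classes) {
    Xc <- sweep(X[y == c, , drop = FALSE], 2, M[match(c, classes), ])
    Sw <- Sw + crossprod(Xc)
  }
  Sw <- Sw / max(n - length(classes), 1)
  Sw <- Sw + diag(ridge * mean(diag(Sw)) + .Machine$double.eps, b)
  priors <- as.numeric(table(factor(y, classes))) / n
  W <- solve(Sw, t(M))                       # b x C
  intercept <- -0.5 * colSums(t(M) * W) + log(priors)
  structure(list(classes = classes, W = W, intercept = intercept,
                 priors = priors),
            class = "lda_ridge")
}

#' Linear discriminant scores
#'
#' Raw per-class discriminant scores of an [fit_lda_ridge()] model; the
#' predicted class is the column-wise argmax, the posterior the softmax.
#'
#' @param model An `lda_ridge` model.
#' @param X Feature matrix.
#' @return Score matrix (n x C) with class-named columns.
#' @export
predict_lda_scores <- function(model, X) {
  G <- as.matrix(X) %*% model$W
  G <- sweep(G, 2, model$intercept, "+")
  colnames(G) <- model$classes
  G
}

# ---- family fits ----------------------------------------------------------

.standardize_fit <- function(X) {
  mu <- colMeans(X)
  sd <- apply(X, 2, stats::sd)
  sd[sd < .Machine$double.eps] <- 1
  list(mu = mu, sd = sd)
}

.standardize_apply <- function(X, st) {
  sweep(sweep(X, 2, st$mu), 2, st$sd, "/")
}

#' Fit a classifier of a given family
#'
#' Dispatches on `spec$family`: `QSVM` (quadratic-kernel support vector
#' machine on standardised features), `FKNN` (nearest-neighbour with
#' inverse-distance class scores), `LDA` ([fit_lda_ridge()]) or `ESD`
#' ([esd_fit()], a random-subspace discriminant ensemble).
#'
#' @param spec A [classifier_spec()].
#' @param X Feature matrix (n x p).
#' @param y Class labels (>= 2 samples per class).
#' @param scores_enabled Whether the fitted model must support per-class
#'   scores at prediction time (needed for AUC).
#' @return Object of class `brulat_model`.
#' @export
fit_classifier <- function(spec, X, y, scores_enabled = TRUE) {
  X <- as.matrix(X); y <- .check_classes(y)
  classes <- sort(unique(y))
  fit <- switch(spec$family,
    QSVM = {
      st <- .standardize_fit(X)
      sv <- e1071::svm(.standardize_apply(X, st), factor(y, classes),
                       kernel = "polynomial", degree = 2, gamma = 1,
                       coef0 = 1, cost = spec$cost, scale = FALSE,
                       probability = scores_enabled)
      list(svm = sv, st = st)
    },
    FKNN = list(X = X, y = y),
    LDA = fit_lda_ridge(X, y, ridge = spec$ridge),
    ESD = esd_fit(X, y, n_learners = spec$n_learners,
                  subspace_dim = spec$subspace_dim, seed = spec$seed,
                  ridge = spec$ridge)
  )
  structure(list(spec = spec, fit = fit, classes = classes),
            class = "brulat_model")
}

#' Fit a random-subspace discriminant ensemble
#'
#' Each of `n_learners` base learners is a ridge-regularised linear
#' discriminant fitted on `subspace_dim` features sampled uniformly
#' without replacement (independently per learner). Prediction is by
#' majority vote; ties break toward the class with the larger training
#' prior, then lexicographically.
#'
#' @param X Feature matrix (n x p).
#' @param y Class labels.
#' @param n_learners Number of base learners.
#' @param subspace_dim Features per learner (<= p).
#' @param seed Integer seed for the subspace draws.
#' @param ridge LDA covariance regularisation factor.
#' @return Object of class `esd_model`.
#' @export
esd_fit <- function(X, y, n_learners = 30L, subspace_dim = 128L, seed = 1L,
                    ridge = 1e-2) {
  X <- as.matrix(X); y <- .check_classes(y)
  if (subspace_dim > ncol(X))
    stop("subspace_dim (", subspace_dim, ") exceeds feature count (", ncol(X), ")")
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  classes <- sort(unique(y))
  priors <- as.numeric(table(factor(y, classes))) / length(y)
  learners <- lapply(seq_len(n_learners), function(i) {
    feats <- sort(sample.int(ncol(X), subspace_dim))
    list(feats = feats,
         lda = fit_lda_ridge(X[, feats, drop = FALSE], y, ridge = ridge))
  })
  structure(list(learners = learners, classes = classes, priors = priors),
            class = "esd_model")
}

#' Ensemble vote fractions per class
#'
#' @param model An `esd_model` from [esd_fit()].
#' @param X Feature matrix.
#' @return Matrix (n x C) of vote fractions; rows sum to one.
#' @export
esd_votes <- function(model, X) {
  X <- as.matrix(X)
  V <- matrix(0, nrow(X), length(model$classes),
              dimnames = list(NULL, model$classes))
  for (ln in model$learners) {
    G <- predict_lda_scores(ln$lda, X[, ln$feats, drop = FALSE])
    pred <- max.col(G, ties.method = "first")
    V[cbind(seq_len(nrow(X)), pred)] <- V[cbind(seq_len(nrow(X)), pred)] + 1
  }
  V / length(model$learners)
}

#' Majority-vote prediction of the discriminant ensemble
#'
#' Ties break toward the class with the larger training prior, then
#' lexicographically.
#'
#' @inheritParams esd_votes
#' @return Character vector of predicted classes.
#' @export
esd_predict <- function(model, X) {
  V <- esd_votes(model, X)
  # majority vote; ties -> larger prior, then lexicographic (classes sorted)
  order_key <- rank(-model$priors, ties.method = "first")
  apply(V, 1, function(v) {
    top <- which(v == max(v))
    model$classes[top[order(order_key[top])][1]]
  })
}

# ---- prediction -----------------------------------------------------------

#' Predict classes (and optionally per-class scores) from a fitted model
#'
#' @param model A `brulat_model` from [fit_classifier()].
#' @param X Feature matrix.
#' @param scores Whether to also return the per-class score matrix
#'   (probabilities, vote fractions or proximity scores, by family).
#' @return List with `class` (character vector) and `scores` (matrix or
#'   `NULL`).
#' @export
predict_model <- function(model, X, scores = FALSE) {
  X <- as.matrix(X)
  spec <- model$spec
  switch(spec$family,
    QSVM = {
      Xs <- .standardize_apply(X, model$fit$st)
      pr <- stats::predict(model$fit$svm, Xs, probability = scores)
      sc <- NULL
      if (scores) {
        sc <- attr(pr, "probabilities")
        sc <- sc[, model$classes, drop = FALSE]
      }
      list(class = as.character(pr), scores = sc)
    },
    FKNN = {
      tr <- model$fit
      pred <- as.character(class::knn(tr$X, X, factor(tr$y, model$classes),
                                      k = model$spec$k))
      sc <- if (scores) .knn_class_scores(tr$X, tr$y, X, model$classes) else NULL
      list(class = pred, scores = sc)
    },
    LDA = {
      G <- predict_lda_scores(model$fit, X)
      pred <- model$classes[max.col(G, ties.method = "first")]
      sc <- NULL
      if (scores) {
        E <- exp(G - apply(G, 1, max))
        sc <- E / rowSums(E)
      }
      list(class = pred, scores = sc)
    },
    ESD = {
      V <- esd_votes(model$fit, X)
      pred <- esd_predict(model$fit, X)
      list(class = pred, scores = if (scores) V else NULL)
    }
  )
}

# per-class proximity scores for 1-NN: inverse distance to the nearest
# training point of each class, normalised per row; argmax equals 1-NN.
.knn_class_scores <- function(Xtr, ytr, Xte, classes) {
  d2 <- outer(rowSums(Xte^2), rowSums(Xtr^2), "+") - 2 * Xte %*% t(Xtr)
  d2[d2 < 0] <- 0
  sc <- vapply(classes, function(c) {
    cols <- which(ytr == c)
    apply(d2[, cols, drop = FALSE], 1, min)
  }, numeric(nrow(Xte)))
  sc <- matrix(sc, nrow = nrow(Xte), dimnames = list(NULL, classes))
  sc <- 1 / (sqrt(sc) + 1e-12)
  sc / rowSums(sc)
}

# ---- training with cross-validation --------------------------------------

#' Seeded stratified fold assignment
#'
#' Assigns each sample to one of `n_folds` folds so every class is spread
#' as evenly as possible (fold counts per class differ by at most one).
#'
#' @param y Class labels.
#' @param n_folds Number of folds.
#' @param seed Integer seed; the global RNG state is restored afterwards.
#' @return Integer fold index per sample.
#' @export
stratified_folds <- function(y, n_folds, seed) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  fold <- integer(length(y))
  for (c in unique(y)) {
    idx <- sample(which(y == c))
    fold[idx] <- rep_len(sample(n_folds), length(idx))
  }
  fold
}

#' Train a classifier with stratified k-fold cross-validation
#'
#' Assigns seeded stratified folds, computes the pooled out-of-fold
#' accuracy over all folds, then refits the final model on all training
#' rows.
#'
#' @param spec A [classifier_spec()].
#' @param X Feature matrix (n x p).
#' @param y Class labels (character or factor).
#' @param n_folds Number of cross-validation folds.
#' @param seed Integer seed for the fold assignment.
#' @return List with `model` (the refitted classifier) and `cv_accuracy`
#'   (percent correct out-of-fold predictions).
#' @export
train_classifier <- function(spec, X, y, n_folds = 10L, seed = spec$seed) {
  X <- as.matrix(X); y <- .check_classes(y)
  if (!all(is.finite(X))) stop("features must be finite")
  fold <- stratified_folds(y, n_folds, seed)
  pred <- character(length(y))
  for (f in sort(unique(fold))) {
    tr <- fold != f
    m <- fit_classifier(spec, X[tr, , drop = FALSE], y[tr],
                        scores_enabled = FALSE)
    pred[!tr] <- predict_model(m, X[!tr, , drop = FALSE])$class
  }
  cv_accuracy <- 100 * mean(pred == y)
  model <- fit_classifier(spec, X, y, scores_enabled = TRUE)
  list(model = model, cv_accuracy = cv_accuracy)
}
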