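# Synthetic three-class Gaussian problem with well-separated means.
.gauss_problem <- function(n_per = 30, p = 12, sep = 6, seed = 42) {
  set.seed(seed)
  mu <- rbind(rep(0, p), c(rep(sep, 3), rep(0, p - 3)),
              c(rep(0, p - 3), rep(sep, 3)))
  X <- do.call(rbind, lapply(1:3, function(c)
    matrix(rnorm(n_per * p, mu[c, ]), n_per, p, byrow = TRUE)))
  list(X = X, y = rep(c("a", "b", "c"), each = n_per))
}

test_that("all families learn a well-separated Gaussian problem", {
  prob <- .gauss_problem()
  for (fam in c("QSVM", "FKNN", "LDA", "ESD")) {
    spec <- classifier_spec(fam, subspace_dim = 6L, seed = 9)
    fit <- train_classifier(spec, prob$X, prob$y, n_folds = 10, seed = 3)
    expect_gte(fit$cv_accuracy, 99)
    rep <- evaluate_classifier(fit$model, prob$X, prob$y,
                               cv_accuracy = fit$cv_accuracy)
    expect_gte(rep$test_accuracy, 99)
    expect_gte(rep$auc, 0.99)
  }
})

test_that("shuffled labels pin every family near chance", {
  prob <- .gauss_problem(n_per = 40, seed = 5)
  set.seed(8)
  y_shuf <- sample(prob$y)
  for (fam in c("FKNN", "LDA")) {
    spec <- classifier_spec(fam, subspace_dim = 6L)
    fit <- train_classifier(spec, prob$X, y_shuf, n_folds = 10, seed = 2)
    expect_gte(fit$cv_accuracy, 15)
    expect_lte(fit$cv_accuracy, 55)   # chance is 33%
  }
})

test_that("FKNN with k = 1 reproduces its training labels exactly", {
  prob <- .gauss_problem(n_per = 15)
  m <- fit_classifier(classifier_spec("FKNN"), prob$X, prob$y)
  out <- predict_model(m, prob$X, scores = TRUE)
  expect_equal(out$class, prob$y)
  # score argmax agrees with the hard 1-NN prediction
  expect_equal(colnames(out$scores)[max.col(out$scores)], prob$y)
  expect_true(all(abs(rowSums(out$scores) - 1) < 1e-9))
})

test_that("ridge LDA agrees with MASS::lda on well-conditioned data", {
  prob <- .gauss_problem(n_per = 50, p = 6, sep = 3, seed = 17)
  ours <- fit_lda_ridge(prob$X, prob$y, ridge = 0)
  ref <- MASS::lda(prob$X, grouping = prob$y)
  pred_ours <- ours$classes[max.col(predict_lda_scores(ours, prob$X))]
  pred_ref <- as.character(stats::predict(ref, prob$X)$class)
  expect_gte(mean(pred_ours == pred_ref), 0.99)
})

test_that("the subspace ensemble degenerates to plain LDA when told to", {
  prob <- .gauss_problem(n_per = 20, p = 8)
  es <- esd_fit(prob$X, prob$y, n_learners = 1L, subspace_dim = 8L,
                seed = 1, ridge = 1e-2)
  single <- fit_lda_ridge(prob$X, prob$y, ridge = 1e-2)
  expect_equal(esd_predict(es, prob$X),
               single$classes[max.col(predict_lda_scores(single, prob$X))])
})

test_that("the subspace ensemble is seeded, bounded and validated", {
  prob <- .gauss_problem(n_per = 20, p = 10)
  e1 <- esd_fit(prob$X, prob$y, n_learners = 5, subspace_dim = 4, seed = 3)
  e2 <- esd_fit(prob$X, prob$y, n_learners = 5, subspace_dim = 4, seed = 3)
  e3 <- esd_fit(prob$X, prob$y, n_learners = 5, subspace_dim = 4, seed = 4)
  expect_identical(lapply(e1$learners, `[[`, "feats"),
                   lapply(e2$learners, `[[`, "feats"))
  expect_false(identical(lapply(e1$learners, `[[`, "feats"),
                         lapply(e3$learners, `[[`, "feats")))
  expect_true(all(vapply(e1$learners,
                         function(l) length(l$feats) == 4 &&
                           !any(duplicated(l$feats)), logical(1))))
  expect_equal(esd_predict(e1, prob$X), prob$y)
  # vote fractions form a distribution over classes
  V <- esd_votes(e1, prob$X)
  expect_true(all(abs(rowSums(V) - 1) < 1e-12))
  expect_error(esd_fit(prob$X, prob$y, subspace_dim = 11), "exceeds")
})

test_that("ensemble ties break toward the larger prior", {
  model <- structure(list(learners = list(), classes = c("a", "b"),
                          priors = c(0.3, 0.7)),
                     class = "esd_model")
  # with zero learners every class gets zero votes: pure tie
  v <- matrix(0, 1, 2, dimnames = list(NULL, c("a", "b")))
  order_key <- rank(-model$priors, ties.method = "first")
  top <- which(v[1, ] == max(v[1, ]))
  expect_equal(model$classes[top[order(order_key[top])][1]], "b")
})

test_that("stratified folds balance every class and honour the seed", {
  y <- rep(c("a", "b", "c"), c(40, 25, 10))
  f1 <- stratified_folds(y, 5, seed = 7)
  f2 <- stratified_folds(y, 5, seed = 7)
  f3 <- stratified_folds(y, 5, seed = 8)
  expect_identical(f1, f2)
  expect_false(identical(f1, f3))
  expect_setequal(unique(f1), 1:5)
  for (c in c("a", "b", "c")) {
    per_fold <- table(factor(f1[y == c], 1:5))
    expect_lte(diff(range(per_fold)), 1)
  }
})

test_that("classifier specs and training inputs are validated", {
  expect_error(classifier_spec("RF"))
  expect_error(classifier_spec("LDA", ridge = -1))
  prob <- .gauss_problem(n_per = 5, p = 4)
  y_singleton <- prob$y; y_singleton[prob$y == "c"] <- "a"
  y_singleton[1] <- "c"   # one lone sample of class c
  expect_error(fit_classifier(classifier_spec("LDA"), prob$X, y_singleton),
               "at least 2")
  Xb <- prob$X; Xb[1, 1] <- Inf
  expect_error(train_classifier(classifier_spec("LDA"), Xb, prob$y), "finite")
})

test_that("evaluation reports accuracy, AUC and confusion bookkeeping", {
  prob <- .gauss_problem(n_per = 25, p = 6)
  fit <- train_classifier(classifier_spec("LDA"), prob$X, prob$y, seed = 1)
  rep <- evaluate_classifier(fit$model, prob$X, prob$y,
                             cv_accuracy = fit$cv_accuracy)
  expect_equal(rep$n_test, 75)
  expect_equal(sum(rep$confusion), 75)
  expect_equal(as.numeric(rowSums(rep$confusion)), rep(25, 3))
  expect_equal(rep$tpr_per_class + rep$fnr_per_class, rep(1, 3),
               ignore_attr = TRUE)
  # perfect prediction -> diagonal confusion, accuracy 100
  expect_equal(rep$test_accuracy, 100)
  expect_equal(sum(diag(rep$confusion)), 75)
  expect_error(evaluate_classifier(fit$model, prob$X, rep("z", 75)),
               "unseen")
  expect_error(evaluate_classifier(fit$model, prob$X[0, , drop = FALSE],
                                   character(0)), "empty")
  expect_output(print(rep), "evaluation_report")
})

test_that("binary AUC matches hand-computed small cases", {
  # perfect ranking
  expect_equal(auc_binary(c(0.9, 0.8, 0.2, 0.1), c(TRUE, TRUE, FALSE, FALSE)), 1)
  # perfectly wrong ranking
  expect_equal(auc_binary(c(0.1, 0.2, 0.8, 0.9), c(TRUE, TRUE, FALSE, FALSE)), 0)
  # one concordant swap of four pairs: AUC = 3/4
  expect_equal(auc_binary(c(0.9, 0.3, 0.4, 0.1), c(TRUE, TRUE, FALSE, FALSE)), 0.75)
  # all ties -> 0.5
  expect_equal(auc_binary(rep(1, 4), c(TRUE, TRUE, FALSE, FALSE)), 0.5)
  # degenerate: single class
  expect_true(is.na(auc_binary(1:4, rep(TRUE, 4))))
})

test_that("prediction speed is positive and normalisation tops at one", {
  prob <- .gauss_problem(n_per = 10, p = 4)
  m <- fit_classifier(classifier_spec("LDA"), prob$X, prob$y,
                      scores_enabled = FALSE)
  sp <- prediction_speed(m, prob$X, repetitions = 3)
  expect_gt(sp, 0)
  ns <- normalize_speeds(c(a = 100, b = 400, c = 50))
  expect_equal(max(ns), 1)
  expect_equal(names(which.max(ns)), "b")
  expect_equal(ns[["a"]], 0.25)
  expect_error(normalize_speeds(numeric(0)), "no speeds")
  expect_error(prediction_speed(m, prob$X, repetitions = 2), "repetitions")
})

test_that("confusion adjacency counts near-diagonal errors only", {
  cls <- paste0("c", 1:5)
  m <- matrix(0, 5, 5, dimnames = list(cls, cls))
  diag(m) <- 10
  m[1, 2] <- 4   # adjacent error
  m[1, 5] <- 1   # distant error
  expect_equal(confusion_adjacency(m, window = 2), 4 / 5)
  expect_equal(confusion_adjacency(m, window = 1), 4 / 5)
  expect_equal(confusion_adjacency(m, window = 4), 1)
  # error-free matrix has no defined adjacency
  diag_only <- diag(3); dimnames(diag_only) <- list(cls[1:3], cls[1:3])
  expect_true(is.na(confusion_adjacency(diag_only)))
  # reordering classes changes what counts as adjacent
  expect_equal(confusion_adjacency(m, ordering = cls[c(1, 5, 4, 3, 2)],
                                   window = 1), 1 / 5)
})
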