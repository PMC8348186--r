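test_that("PCA matches the eigendecomposition of the covariance matrix", {
  set.seed(101)
  X <- matrix(rnorm(20 * 6), 20, 6) %*% diag(c(4, 3, 2, 1, 0.5, 0.25))
  model <- fit_pca(X, A = 4)
  # orthonormal loadings
  expect_equal(model$loadings %*% t(model$loadings), diag(4),
               tolerance = 1e-12, ignore_attr = TRUE)
  # eigenvalues agree with eigen() on the sample covariance
  ev <- eigen(stats::cov(X), symmetric = TRUE)$values[1:4]
  expect_equal(model$eigenvalues, ev, tolerance = 1e-10)
  expect_true(all(diff(model$eigenvalues) <= 0))
  # deterministic sign convention
  for (a in 1:4)
    expect_gt(model$loadings[a, which.max(abs(model$loadings[a, ]))], 0)
  expect_identical(model$loadings, fit_pca(X, A = 4)$loadings)
  # validation
  expect_error(fit_pca(X, A = 0), "between 1")
  expect_error(fit_pca(X, A = 7), "between 1")
  X[1, 1] <- NA
  expect_error(fit_pca(X, A = 2), "non-finite")
})

test_that("PCA recovers a noiseless rank-1 structure exactly", {
  v <- c(3, 0, -4) / 5
  t_true <- seq(-2, 2, length.out = 11)
  X <- outer(t_true, v) + 0.5
  model <- fit_pca(X, A = 1)
  expect_equal(abs(as.vector(model$loadings)), abs(v), tolerance = 1e-12)
  expect_equal(q_residual(model, X), rep(0, 11), tolerance = 1e-20)
  # scores reproduce the generating coordinate up to sign
  sc <- pca_scores(model, X)[, 1]
  expect_equal(abs(sc), abs(t_true), tolerance = 1e-12)
})

test_that("Q residual and Hotelling T2 match brute-force definitions", {
  set.seed(7)
  X <- matrix(rnorm(30 * 8), 30, 8)
  model <- fit_pca(X, A = 3)
  mu <- model$mean; P <- model$loadings
  q_bf <- t2_bf <- numeric(30)
  for (p in 1:30) {
    xc <- X[p, ] - mu
    t_p <- drop(P %*% xc)
    q_bf[p] <- sum((xc - drop(t_p %*% P))^2)
    t2_bf[p] <- sum(t_p^2 / model$eigenvalues)
  }
  expect_equal(q_residual(model, X), q_bf, tolerance = 1e-10)
  expect_equal(hotelling_t2(model, X), t2_bf, tolerance = 1e-10)
  # Q vanishes when all components are retained
  full <- fit_pca(X, A = 8)
  expect_equal(max(q_residual(full, X)), 0, tolerance = 1e-18)
  # T2 of the training mean is zero
  expect_equal(drop(hotelling_t2(model, matrix(mu, 1))), 0, tolerance = 1e-20)
  # degenerate eigenvalue is refused
  degen <- fit_pca(outer(1:10, c(1, 2)), A = 2)
  expect_error(hotelling_t2(degen, matrix(0, 1, 2)), "zero eigenvalue")
  # band mismatch is refused
  expect_error(pca_scores(model, matrix(0, 2, 5)), "does not match")
})

test_that("hyperspectrogram length and layout follow the construction", {
  set.seed(3)
  for (rep in 1:5) {
    n <- sample(10:40, 1); b <- sample(4:9, 1); A <- sample(1:3, 1)
    X <- matrix(rnorm(n * b), n, b)
    hg <- build_hyperspectrogram(fit_pca(X, A = A), X)
    expect_length(hg$signal, A * b + (A + 2) * n)
    expect_equal(hg$segments$loadings, c(start = 1, end = A * b))
    # distribution curves are sorted (non-decreasing)
    for (seg in setdiff(names(hg$segments), "loadings")) {
      piece <- hg$signal[hg$segments[[seg]][1]:hg$segments[[seg]][2]]
      expect_length(piece, n)
      expect_true(all(diff(piece) >= 0), label = seg)
    }
  }
  expect_equal(hyperspectrogram_length(404, 384, 288), 776544)
})

test_that("histogram-mode curves are counts that total the pixel count", {
  set.seed(4)
  X <- matrix(rnorm(50 * 6), 50, 6)
  model <- fit_pca(X, A = 3)
  hg <- build_hyperspectrogram(model, X, distribution = "histogram", bins = 20)
  expect_length(hg$signal, 3 * 6 + 5 * 20)
  for (seg in setdiff(names(hg$segments), "loadings")) {
    piece <- hg$signal[hg$segments[[seg]][1]:hg$segments[[seg]][2]]
    expect_equal(sum(piece), 50)
    expect_true(all(piece >= 0))
  }
})

test_that("compression ratio reproduces the reference frame values", {
  # 404 x 384 x 288 cube against its length-621544 hyperspectrogram
  expect_equal(compression_ratio(404, 384, 288), 57.5)
  # a single-pixel "cube" expands rather than compresses
  expect_equal(compression_ratio(1, 1, 288), 0.3)
  # band count barely matters once frames are large
  expect_equal(compression_ratio(404, 384, 287), 57.3)
  expect_error(compression_ratio(0, 10, 10))
})

test_that("score images expose simulated bruises at high contrast", {
  sim <- default_l2_cube()
  cube <- sim$cube; truth <- sim$truth
  pm_all <- unfold(cube)
  model <- fit_pca(pm_all, A = 3)
  imgs <- lapply(1:3, function(a)
    score_image(model, pm_all, a, dim(cube)[1:2]))
  contrasts <- vapply(imgs, function(im)
    region_contrast(im, truth$bruise_mask, within = truth$fruit_mask),
    numeric(1))
  # a higher component separates bruised from sound tissue at >= 2 pooled SDs
  expect_gte(max(contrasts[2:3]), 2)
  # and at least as clearly as the broadband mean image
  broad <- fold_image(rowMeans(pm_all$values), dim(cube)[1:2])
  expect_gte(max(contrasts),
             region_contrast(broad, truth$bruise_mask,
                             within = truth$fruit_mask))
  # negative control: the same regions on a sound fruit show no contrast
  snd <- generate_hypercube(simulation_config(), "sound", seed = 11)
  pm_s <- unfold(snd$cube)
  model_s <- fit_pca(pm_s, A = 3)
  ctrl <- vapply(2:3, function(a)
    region_contrast(score_image(model_s, pm_s, a, dim(snd$cube)[1:2]),
                    truth$bruise_mask, within = snd$truth$fruit_mask),
    numeric(1))
  expect_lt(max(ctrl), 2)
  # scaling contract
  expect_true(all(imgs[[2]] >= 0 & imgs[[2]] <= 1))
  expect_error(score_image(model, pm_all, 4, dim(cube)[1:2]), "component")
})
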