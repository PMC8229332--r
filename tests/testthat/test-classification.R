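test_that("LDA closed forms: identity covariance and degenerate equal means", {
  set.seed(1)
  # C = I, mu difference along x1: weights proportional to (2, 0), cut at x1 = 1
  pos <- cbind(rnorm(2000) + 2, rnorm(2000))
  neg <- cbind(rnorm(2000), rnorm(2000))
  m <- fit_lda(pos, neg)
  expect_gt(abs(m$weights[1]) / (abs(m$weights[2]) + 1e-12), 10)
  cut <- m$bias / m$weights[1]
  expect_equal(cut, 1, tolerance = 0.15)
  # equal means: zero weights, classification at chance
  same <- matrix(rnorm(200), 100)
  m0 <- fit_lda(same, same)
  expect_equal(unname(m0$weights), c(0, 0), tolerance = 1e-12)
  expect_equal(m0$bias, 0, tolerance = 1e-12)
})

test_that("LDA weights equal C^-1 (mu_pos - mu_neg) exactly on hand-computed data", {
  # two points per class, spread along different directions so the pooled
  # covariance is invertible
  pos <- rbind(c(3, 1), c(5, 2))
  neg <- rbind(c(-1, 1), c(1, 0))
  m <- fit_lda(pos, neg)
  mu_p <- c(4, 1.5); mu_n <- c(0, 0.5)
  C <- (cov(pos) + cov(neg)) / 2
  expect_equal(unname(m$weights), unname(solve(C, mu_p - mu_n)),
               tolerance = 1e-12)
  expect_equal(m$bias, sum(m$weights * (mu_p + mu_n)) / 2, tolerance = 1e-12)
})

test_that("the LDA boundary matches a brute-force training-error grid search", {
  set.seed(2)
  pos <- cbind(rnorm(300, 2, 1), rnorm(300))
  neg <- cbind(rnorm(300, -2, 1), rnorm(300))
  m <- fit_lda(pos, neg)
  # project onto the learned direction; grid-search the best 1-D threshold
  w <- m$weights / sqrt(sum(m$weights^2))
  sp <- pos %*% w; sn <- neg %*% w
  grid <- seq(min(sp, sn), max(sp, sn), length.out = 2000)
  err <- vapply(grid, function(th) sum(sp <= th) + sum(sn > th), numeric(1))
  best <- grid[which.min(err)]
  lda_cut <- m$bias / sqrt(sum(m$weights^2))
  step <- diff(grid[1:2])
  # LDA threshold within a few grid steps of the empirical-risk minimizer
  expect_lt(abs(lda_cut - best), 20 * step)
})

test_that("singular pooled covariance triggers recorded shrinkage instead of failure", {
  set.seed(3)
  x <- rnorm(50)
  pos <- cbind(x + 1, 2 * (x + 1))          # rank-1 features
  neg <- cbind(x - 1, 2 * (x - 1))
  expect_message(m <- fit_lda(pos, neg), "shrinkage")
  expect_gt(m$shrinkage, 0)
  expect_true(all(is.finite(m$weights)))
})

test_that("one-vs-rest assignment takes the highest score with fear-first tie-break", {
  sc <- rbind(c(2, -1, -1), c(-1, 3, 0), c(0.5, 0.2, 0.9))
  colnames(sc) <- c("fear", "joy", "neutral")
  expect_equal(as.character(ovr_classify(sc)),
               c("fear", "joy", "neutral"))
  ties <- matrix(0, 2, 3, dimnames = list(NULL, c("fear", "joy", "neutral")))
  expect_equal(as.character(ovr_classify(ties)), c("fear", "fear"))
})

test_that("high-SNR three-class data is classified almost perfectly by the OVR stack", {
  g <- quick_epochs("PI", trials_per_state = 4, snr = 10, seed = 21)
  ovr <- fit_ovr(g$epochs, m = 2)
  pred <- predict(ovr, g$epochs)
  expect_gte(mean(as.character(pred$labels) == as.character(g$epochs$labels)),
             0.95)
})

test_that("cross-validation folds partition trials, 27 train / 3 test for 30 trials", {
  g <- quick_epochs("PI", trials_per_state = 10, snr = 1, seed = 30)
  cv <- run_cv(list(broadband = g$epochs), n_folds = 10, n_reps = 2, m = 2,
               seed = 5)
  expect_true(all(cv$test_units == 3))
  expect_true(all(cv$train_units == 27))
  expect_equal(dim(cv$binary_acc), c(2, 10, 1, 3))
  expect_true(all(cv$binary_acc >= 0 & cv$binary_acc <= 100))
  expect_equal(mean(cv$mean_binary), mean(cv$binary_acc))
})

test_that("fewer trials than folds reduces the fold count with a message", {
  g <- quick_epochs("PI", trials_per_state = 4, snr = 1, seed = 31)
  expect_message(cv <- run_cv(g$epochs, n_folds = 10, n_reps = 1, m = 2,
                              seed = 1),
                 "using 4 folds")
  expect_equal(cv$n_folds, 4)
})

test_that("fold models never see test trials: deleting them leaves fitted parameters unchanged", {
  g <- quick_epochs("PI", trials_per_state = 5, snr = 5, seed = 32)
  ep <- g$epochs
  test_trials <- 1:3   # one held-out trial per state
  train <- !(ep$trial_ids %in% test_trials)
  labels <- as.character(ep$labels)
  # path used inside run_cv: sufficient statistics over the FULL epoch set,
  # restricted to training columns when fitting the fold model
  mom <- emocsp:::epoch_moments(ep)
  deleted <- subset_epochs(ep, train)   # test trials physically removed
  for (s in c("fear", "joy", "neutral")) {
    pos <- train & labels == s
    neg <- train & labels != s
    m_cv <- emocsp:::fit_csp_cov(
      matrix(rowMeans(mom$Cflat[, pos, drop = FALSE]), mom$N, mom$N),
      matrix(rowMeans(mom$Cflat[, neg, drop = FALSE]), mom$N, mom$N), m = 2)
    m_del <- fit_csp(subset_epochs(deleted, deleted$labels == s),
                     subset_epochs(deleted, deleted$labels != s), m = 2)
    expect_equal(m_cv$projection, m_del$projection, tolerance = 1e-10)
    expect_equal(m_cv$eigvals_class1, m_del$eigvals_class1,
                 tolerance = 1e-12)
    f_cv <- emocsp:::csp_features_from_moments(m_cv, mom)$features
    lda_cv <- fit_lda(f_cv[pos, , drop = FALSE], f_cv[neg, , drop = FALSE])
    f_del <- apply_csp(m_del, deleted)$features
    lda_del <- fit_lda(f_del[deleted$labels == s, , drop = FALSE],
                       f_del[deleted$labels != s, , drop = FALSE])
    expect_equal(lda_cv$weights, lda_del$weights, tolerance = 1e-10)
    expect_equal(lda_cv$bias, lda_del$bias, tolerance = 1e-10)
  }
})

test_that("accuracy is invariant to channel-wise rescaling of the raw data", {
  g <- quick_epochs("PI", trials_per_state = 5, snr = 3, seed = 33)
  ep <- g$epochs
  cv1 <- run_cv(ep, n_folds = 5, n_reps = 2, m = 2, seed = 9)
  scaled <- ep
  scaled$data <- ep$data * 3.25
  cv2 <- run_cv(scaled, n_folds = 5, n_reps = 2, m = 2, seed = 9)
  expect_equal(cv1$binary_acc, cv2$binary_acc, tolerance = 1e-12)
  expect_equal(cv1$multi_acc, cv2$multi_acc, tolerance = 1e-12)
})

test_that("mean accuracy is non-decreasing in SNR", {
  accs <- vapply(c(0, 1, 10), function(s) {
    g <- quick_epochs("PI", trials_per_state = 6, snr = s, seed = 77)
    mean(run_cv(g$epochs, n_folds = 6, n_reps = 2, m = 2,
                seed = 3)$mean_multiclass)
  }, numeric(1))
  # allow small-sample wiggle at the bottom, require clear growth to the top
  expect_gt(accs[2], accs[1] - 8)
  expect_gt(accs[3], accs[1] + 20)
  expect_gt(accs[3], 90)
})
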