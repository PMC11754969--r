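test_that("train z-scaling standardises train and transfers to test untouched", {
  ft <- toy_feature_table(seed = 11)
  ds <- task_dataset(ft)
  train <- ds[1:80, ]
  test <- ds[81:nrow(ds), ]
  sc <- fit_train_scaler(train, provenance = "fold-A")
  tr2 <- apply_scaler(train, sc)
  for (f in hrv_feature_names()[1:5]) {
    expect_lt(abs(mean(tr2[[f]])), 1e-9)
    expect_lt(abs(sd(tr2[[f]]) - 1), 1e-9)
  }
  # test rows transformed with train statistics only
  te2 <- apply_scaler(test, sc)
  f <- "mean_rri"
  expect_equal(te2[[f]], (test[[f]] - mean(train[[f]])) / sd(train[[f]]))
  expect_identical(sc$provenance, "fold-A")

  # worked arithmetic: train {2, 4}, test value 5
  toy <- data.frame(v = c(2, 4))
  sc2 <- fit_train_scaler(toy, features = "v")
  expect_equal(apply_scaler(data.frame(v = 5), sc2)$v, (5 - 3) / sqrt(2),
               tolerance = 1e-12)

  # constant columns pass through as zero with a warning
  toy$v <- c(7, 7)
  expect_warning(sc3 <- fit_train_scaler(toy, features = "v"), "constant")
  expect_identical(apply_scaler(data.frame(v = c(1, 9)), sc3)$v, c(0, 0))
  expect_error(fit_train_scaler(toy[0, , drop = FALSE], features = "v"),
               "at least 2")
})

test_that("longitudinal scaling standardises within participant and is idempotent", {
  ft <- toy_feature_table(seed = 12, drift_sd = 0.5)
  sc <- longitudinal_scale(ft)
  for (p in unique(sc$participant)[1:4]) {
    for (f in c("mean_rri", "sampen", "lf_hf")) {
      v <- sc[[f]][sc$participant == p]
      expect_lt(abs(mean(v)), 1e-9)
      expect_lt(abs(sd(v) - 1), 1e-9)
    }
  }
  sc2 <- longitudinal_scale(sc)
  for (f in hrv_feature_names()) {
    expect_lt(max(abs(sc2[[f]] - sc[[f]])), 1e-9)
  }
})

test_that("longitudinal scaling maps {5,6,7} to {-1,0,1} and removes baselines", {
  base <- toy_feature_table(n_per_group = c(HC = 1), visits = 3, noise_sd = 0,
                            subject_sd = 0, task_effect = c(mean_rri = 0),
                            seed = 1)
  three <- base[base$phase == "rest1", ]
  three$log_lf <- c(5, 6, 7)
  sc <- suppressWarnings(longitudinal_scale(three, features = "log_lf"))
  expect_equal(sc$log_lf, c(-1, 0, 1))

  # two participants with different baselines but the same stress-relax offset
  # become indistinguishable after scaling
  two <- toy_feature_table(n_per_group = c(HC = 2), visits = 2, noise_sd = 0,
                           subject_sd = 0, task_effect = c(mean_rri = -1),
                           seed = 2)
  two$mean_rri <- two$mean_rri + ifelse(two$participant == two$participant[1], 0, 5)
  sc2 <- longitudinal_scale(two, features = "mean_rri")
  p1 <- sc2[sc2$participant == sc2$participant[1], ]
  p2 <- sc2[sc2$participant != sc2$participant[1], ]
  expect_equal(p1$mean_rri, p2$mean_rri, tolerance = 1e-9)
})

test_that("participants with a single record are excluded with a warning", {
  ft <- toy_feature_table(n_per_group = c(HC = 2), visits = 1, seed = 3)
  ft <- ft[-(1:4), ] # leave participant 1 with one row
  expect_warning(sc <- longitudinal_scale(ft), "excluding 1 participant")
  expect_false(ft$participant[1] %in% sc$participant)
})

test_that("t-SNE embedding is 2-D, seeded and scores class separation", {
  set.seed(6)
  X <- rbind(matrix(rnorm(150 * 4), 150), matrix(rnorm(150 * 4, 5), 150))
  lab <- rep(c("stress", "relaxation"), each = 150)
  Y <- embed_2d(X, labels = lab, perplexity = 30, max_iter = 150, seed = 9)
  expect_identical(dim(Y), c(300L, 2L))
  Y2 <- embed_2d(X, labels = lab, perplexity = 30, max_iter = 150, seed = 9)
  expect_identical(unclass(Y), unclass(Y2))
  expect_gt(attr(Y, "silhouette"), 0.3)
  expect_error(embed_2d(X[1:50, ], perplexity = 30), "perplexity")
})

test_that("longitudinal scaling improves task separation when drift dominates", {
  effect <- c(mean_rri = -1, sdnn = -1, rmssd = -1, pnn50 = -1, log_hf = -1,
              log_tot = -1, log_lf = 1, lf_nu = 1, sd1 = -1, apen = -1)
  ft <- toy_feature_table(n_per_group = c(MDD = 8, PD = 8, HC = 8), visits = 3,
                          task_effect = effect, subject_sd = 3, drift_sd = 0.3,
                          noise_sd = 0.25, seed = 14)
  ds <- task_dataset(ft)
  lab <- ds$task
  wins <- vapply(1:3, function(seed) {
    before <- embed_2d(as.matrix(scale(ds[, hrv_feature_names()])),
                       labels = lab, perplexity = 30, max_iter = 600,
                       seed = seed)
    after <- embed_2d(as.matrix(task_dataset(longitudinal_scale(ft))[, hrv_feature_names()]),
                      labels = lab, perplexity = 30, max_iter = 600,
                      seed = seed)
    attr(after, "silhouette") > attr(before, "silhouette")
  }, TRUE)
  expect_gte(sum(wins), 2)
})
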