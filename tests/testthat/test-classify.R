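test_that("subject-wise folds partition participants with balanced groups", {
  ds <- toy_labeled(n_participants = 147)
  plan <- assign_subject_folds(ds, k = 10, seed = 3)
  expect_identical(sort(unique(plan$fold)), 1:10)
  expect_identical(anyDuplicated(plan$participant), 0L)
  sizes <- table(plan$fold)
  expect_true(all(sizes %in% c(14L, 15L)))
  # per-fold group counts stay within 2 of the proportional share
  for (g in unique(plan$group)) {
    cnt <- table(factor(plan$fold, levels = 1:10)[plan$group == g])
    share <- sum(plan$group == g) / 10
    expect_true(all(abs(cnt - share) <= 2))
  }
  # a session's two task rows always share a fold (subject-wise by construction)
  merged <- merge(ds, plan[, c("participant", "fold")], by = "participant")
  per_session <- tapply(merged$fold, paste(merged$participant, merged$visit),
                        function(f) length(unique(f)))
  expect_true(all(per_session == 1L))
  expect_error(assign_subject_folds(ds[1:8, ], k = 10), "at least 10")
  expect_identical(plan, assign_subject_folds(ds, k = 10, seed = 3))
})

test_that("undersampling matches the smallest group at session level", {
  # groups with 181/191/278 sessions give 362/382/556 task rows
  ds <- toy_labeled(n_participants = 6, visits = 1)
  mk <- function(g, sessions) {
    d <- do.call(rbind, lapply(seq_len(sessions), function(i) {
      data.frame(participant = sprintf("%s%04d", g, (i - 1) %/% 5 + 1),
                 group = g, visit = (i - 1) %% 5 + 1,
                 task = c("stress", "relaxation"), x1 = rnorm(2), x2 = rnorm(2),
                 stringsAsFactors = FALSE)
    }))
    d
  }
  big <- rbind(mk("MDD", 181), mk("PD", 191), mk("HC", 278))
  expect_identical(as.integer(table(big$group)[c("MDD", "PD", "HC")]),
                   c(556L, 362L, 382L)[c(2, 3, 1)])
  us <- undersample(big, seed = 4)
  expect_true(all(table(us$group) == 362L))
  # sessions survive whole: every kept participant-visit still has both tasks
  expect_true(all(table(paste(us$participant, us$visit)) == 2L))
  # output rows are a subset of input rows
  expect_true(all(paste(us$participant, us$visit, us$task) %in%
                    paste(big$participant, big$visit, big$task)))
  # an already-balanced set is unchanged up to ordering
  bal <- rbind(mk("MDD", 40), mk("PD", 40), mk("HC", 40))
  us2 <- undersample(bal, seed = 5)
  expect_identical(nrow(us2), nrow(bal))
})

test_that("random-forest tuning picks from the grid and learns separable data", {
  ds <- toy_labeled(n_participants = 40, sep = 2, seed = 21)
  tr <- ds[ds$participant <= "Q030", ]
  te <- ds[ds$participant > "Q030", ]
  spec <- model_spec("random_forest", seed = 5)
  m <- tune_random_forest(tr, spec, features = c("x1", "x2"))
  expect_true(m$num_trees %in% c(50L, 100L, 200L))
  acc <- mean((predict_prob(m, te) >= 0.5) == (te$task == "stress"))
  expect_gt(acc, 0.95)
  # determinism of selection and prediction
  m2 <- tune_random_forest(tr, spec, features = c("x1", "x2"))
  expect_identical(m$num_trees, m2$num_trees)
  expect_identical(predict_prob(m, te), predict_prob(m2, te))
  # single-class training data is refused
  expect_error(tune_random_forest(tr[tr$task == "stress", ], spec,
                                  features = c("x1", "x2")), "single class")
})

test_that("MLP grid is the six prescribed combinations and learns separable data", {
  g <- mlp_default_grid()
  expect_identical(nrow(g), 6L)
  expect_identical(sort(unique(g$learning_rate)), c(1e-4, 1e-3, 1e-2))
  archs <- unique(lapply(g$hidden, as.integer))
  expect_identical(archs, list(c(4L, 8L, 16L), c(4L, 8L, 16L, 32L)))
  expect_identical(vapply(split(seq_len(6), g$learning_rate), length, 0L),
                   setNames(rep(2L, 3), c("1e-04", "0.001", "0.01")))

  ds <- toy_labeled(n_participants = 50, sep = 3, seed = 22)
  tr <- ds[ds$participant <= "Q040", ]
  te <- ds[ds$participant > "Q040", ]
  fit <- suppressWarnings(mlp_fit(tr[, c("x1", "x2")],
                                  as.numeric(tr$task == "stress"),
                                  participants = tr$participant,
                                  hidden = c(4, 8, 16), learning_rate = 1e-2,
                                  seed = 2))
  p <- predict_prob(fit, te)
  expect_true(all(p >= 0 & p <= 1))
  expect_gt(mean((p >= 0.5) == (te$task == "stress")), 0.9)
})

test_that("evaluation metrics match hand-computed confusion arithmetic", {
  perfect <- evaluate(c(0.9, 0.9, 0.1, 0.1),
                      c("stress", "stress", "relaxation", "relaxation"),
                      c("stress", "stress", "relaxation", "relaxation"))
  expect_equal(unlist(perfect[1, c("accuracy", "f1", "recall", "precision", "auc")]),
               setNames(rep(1, 5), c("accuracy", "f1", "recall", "precision", "auc")))

  # TP=3, FP=1, FN=1, TN=5
  labels <- c(rep("stress", 4), rep("relaxation", 6))
  preds <- c(rep("stress", 3), "relaxation", "stress", rep("relaxation", 5))
  probs <- ifelse(preds == "stress", 0.8, 0.2)
  ev <- evaluate(probs, preds, labels)
  expect_equal(ev$precision, 0.75)
  expect_equal(ev$recall, 0.75)
  expect_equal(ev$f1, 0.75)
  expect_equal(ev$accuracy, 0.8)
  # F1 is self-consistent with precision and recall
  expect_equal(ev$f1, 2 * ev$precision * ev$recall / (ev$precision + ev$recall),
               tolerance = 1e-9)

  # label-independent constant probability carries no ranking information
  ev2 <- evaluate(rep(0.5, 10), rep("stress", 10), labels)
  expect_equal(ev2$auc, 0.5)

  # single-class scope: AUC flagged undefined
  ev3 <- evaluate(c(0.6, 0.7), c("stress", "stress"), c("stress", "stress"))
  expect_true(is.na(ev3$auc))
})

test_that("repeated CV is reproducible, leak-free and reports per-group metrics", {
  ft <- toy_feature_table(n_per_group = c(MDD = 5, PD = 5, HC = 6), visits = 2,
                          task_effect = c(mean_rri = -2), subject_sd = 0.3,
                          seed = 31)
  spec <- model_spec("random_forest", grid = 50L, seed = 1)
  cv1 <- quiet_cv(ft, spec, k = 4, repeats = 2, scaling_mode = "train-zscore",
                  base_seed = 7)
  cv2 <- quiet_cv(ft, spec, k = 4, repeats = 2, scaling_mode = "train-zscore",
                  base_seed = 7)
  expect_identical(cv1$metrics, cv2$metrics)
  expect_setequal(unique(cv1$metrics$scope), c("overall", "MDD", "PD", "HC"))
  expect_true(all(cv1$metrics$mean >= 0 & cv1$metrics$mean <= 1))
  expect_true(all(cv1$metrics$sd >= 0))
  # strong planted signal is learnable
  expect_gt(cv_metric(cv1), 0.9)
})

test_that("per-group models never mix groups and return one result each", {
  ft <- toy_feature_table(n_per_group = c(MDD = 4, PD = 4, HC = 4), visits = 2,
                          task_effect = c(mean_rri = -2), seed = 32)
  spec <- model_spec("random_forest", grid = 50L, seed = 1)
  res <- suppressWarnings(suppressMessages(
    per_group_models(ft, spec, k = 3, repeats = 1, scaling_mode = "none",
                     base_seed = 2)))
  expect_named(res, c("MDD", "PD", "HC"))
  for (g in names(res)) {
    expect_s3_class(res[[g]], "cv_result")
    expect_setequal(unique(res[[g]]$metrics$scope), c("overall", g))
  }
})
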