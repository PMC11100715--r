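# shared small screen fixture: ground truth + knockout screen
gt_screen <- local({
  gt <- generate_ground_truth_model(16, 4, seed = 13)
  list(gt = gt, screen = knockout_screen(gt$model, gt$profiles))
})

test_that("training sets mirror the knockout screen exactly", {
  scr <- gt_screen$screen
  ts <- build_training_set(scr)
  expect_equal(nrow(ts$X), nrow(scr$table))
  expect_equal(length(ts$y), nrow(scr$table))
  expect_equal(colnames(ts$X), gt_screen$gt$model$nodes)
  # the clamped node is 0 in its own feature column
  expect_true(all(ts$X[cbind(seq_len(nrow(ts$X)),
                             match(scr$table$ko_node, colnames(ts$X)))] == 0))
  # baselines can be appended, labeled with their own state
  ts2 <- build_training_set(scr, include_baselines = TRUE)
  expect_equal(nrow(ts2$X), nrow(ts$X) + 4)

  # single-class screens are rejected
  fake <- scr
  fake$table$assigned <- "MES"
  expect_error(build_training_set(fake), "single-class")
})

test_that("every classifier kind separates a perfectly informative feature", {
  withr::with_seed(2, {
    X <- cbind(sep = rep(c(1, 0), each = 30),
               matrix(rbinom(60 * 5, 1, 0.5), 60, 5,
                      dimnames = list(NULL, paste0("n", 1:5))))
  })
  y <- factor(rep(c("MES", "NPC"), each = 30))
  holdout <- X[c(1:5, 31:35), ]
  truth <- as.character(y[c(1:5, 31:35)])
  for (kind in c("multinomial_elasticnet", "knn", "random_forest",
                 "boosted_trees")) {
    spec <- switch(kind,
      boosted_trees = model_spec(kind, seed = 1, subsample = 1),
      # recursive elimination must keep the separating feature
      knn = model_spec(kind, seed = 1, n_features = 2),
      model_spec(kind, seed = 1))
    clf <- train_classifier(list(X = X, y = y), spec)
    pred <- predict_state(clf, holdout)
    expect_equal(pred$state, truth, label = kind)
  }
})

test_that("identical seeds give identical fitted predictions", {
  ts <- build_training_set(gt_screen$screen)
  for (kind in c("random_forest", "boosted_trees")) {
    p1 <- predict_state(train_classifier(ts, model_spec(kind, seed = 7)),
                        ts$X)
    p2 <- predict_state(train_classifier(ts, model_spec(kind, seed = 7)),
                        ts$X)
    expect_identical(p1, p2, label = kind)
  }
})

test_that("a 1-nearest-neighbour model memorizes its training rows", {
  ts <- build_training_set(gt_screen$screen)
  clf <- train_classifier(ts, model_spec("knn", neighbors = 1,
                                         feature_selection = FALSE))
  pred <- predict_state(clf, ts$X)
  expect_equal(pred$state, as.character(ts$y))
})

test_that("prediction handles missing features and rejects empty profiles", {
  ts <- build_training_set(gt_screen$screen)
  clf <- train_classifier(ts, model_spec("boosted_trees", seed = 1,
                                         subsample = 1))
  x <- ts$X[1, ]
  expect_warning(pred <- predict_state(clf, x[-1]), "imputed")
  expect_equal(nrow(pred), 1)
  expect_error(predict_state(clf, matrix(0, 0, 0)), "empty")
})

test_that("balanced accuracy follows its one-vs-rest definition", {
  # TP = 9, FN = 1, TN = 85, FP = 5
  y_true <- c(rep("A", 10), rep("B", 90))
  y_pred <- c(rep("A", 9), "B", rep("A", 5), rep("B", 85))
  expect_equal(balanced_accuracy(y_true, y_pred, "A"),
               (0.9 + 85 / 90) / 2)
  # all-majority predictions score 0.5 for each class
  y_pred2 <- rep("B", 100)
  expect_equal(balanced_accuracy(y_true, y_pred2, "A"), 0.5)
  expect_equal(balanced_accuracy(y_true, y_pred2, "B"), 0.5)
  expect_equal(balanced_accuracy(y_true, y_true, "A"), 1.0)
  # invariant to relabeling of the negative classes
  y3 <- c(rep("A", 10), rep(c("B", "C"), 45))
  p3 <- c(rep("A", 9), "C", rep("A", 5), rep("B", 85))
  p3_relab <- replace(p3, p3 == "B", "Z")
  expect_equal(balanced_accuracy(y3, p3, "A"),
               balanced_accuracy(replace(y3, y3 == "B", "Z"), p3_relab, "A"))
  expect_warning(ba <- balanced_accuracy(c("A", "A"), c("B", "B"), "B"),
                 "undefined")
  expect_true(is.na(ba))
  expect_error(balanced_accuracy(c("A"), c("A"), "Q"), "absent")
})

test_that("attributions are additive and live only on split features", {
  ts <- build_training_set(gt_screen$screen)
  clf <- train_classifier(ts, model_spec("boosted_trees", seed = 1,
                                         subsample = 1))
  att <- attribute(clf, ts$X[1:5, ])
  # base value + sum of contributions = margin, per sample and class
  for (s in unique(att$sample)) {
    for (cl in unique(att$class)) {
      a <- att[att$sample == s & att$class == cl, ]
      expect_lt(abs(a$base_value[1] + sum(a$value) - a$margin[1]), 1e-6)
    }
  }
  # depth-1 stumps: only split features can carry attribution
  used <- unique(as.data.frame(xgboost::xgb.model.dt.tree(model = clf$fit))$Feature)
  unused <- setdiff(clf$selected, used)
  if (length(unused)) {
    expect_true(all(abs(att$value[att$feature %in% unused]) < 1e-12))
  }
  # cross-check against the library's own TreeSHAP (float32 precision)
  d <- xgboost::xgb.DMatrix(ts$X[1:5, clf$selected, drop = FALSE])
  ref_contrib <- predict(clf$fit, d, predcontrib = TRUE)
  ref_margin <- predict(clf$fit, d, outputmargin = TRUE)
  for (i in 1:5) {
    for (ci in seq_along(clf$classes)) {
      a <- att[att$sample == rownames(ts$X)[i] & att$class == clf$classes[ci], ]
      expect_equal(stats::setNames(a$value, a$feature),
                   ref_contrib[i, ci, a$feature], tolerance = 1e-4)
      expect_equal(a$margin[1], ref_margin[i, ci], tolerance = 1e-4)
    }
  }
  expect_error(attribute(train_classifier(ts, model_spec("random_forest")),
                         ts$X[1, ]), "tree")
})

test_that("tree attributions match the brute-force Shapley oracle", {
  skip_if_not_installed("data.table")
  withr::with_seed(4, {
    X <- matrix(rbinom(80 * 4, 1, 0.5), 80, 4,
                dimnames = list(NULL, paste0("f", 1:4)))
    y <- factor(ifelse(X[, 1] + X[, 2] >= 1, "MES",
                       ifelse(X[, 3] == 1, "NPC", "AC")))
  })
  clf <- train_classifier(list(X = X, y = y),
                          model_spec("boosted_trees", seed = 2, nrounds = 10,
                                     max_depth = 2, subsample = 1))
  x <- stats::setNames(c(1, 0, 1, 0), paste0("f", 1:4))
  att <- attribute(clf, x)
  oracle <- oracle_shap(clf$fit, x, n_class = nlevels(y))
  for (ci in seq_along(clf$classes)) {
    a <- att[att$class == clf$classes[ci], ]
    expect_equal(stats::setNames(a$value, a$feature),
                 oracle[ci, a$feature], tolerance = 1e-5)
  }
})

test_that("the planted knockout is recovered as a transition hypothesis", {
  ci <- constructed_instance()
  scr <- knockout_screen(ci$model, ci$profiles)
  ts <- build_training_set(scr)
  clf <- train_classifier(ts, model_spec("boosted_trees", seed = 3,
                                         subsample = 1),
                          augment_rate = 0.05, augment_copies = 10)
  pair <- generate_patient_pair(ci$profiles, "NPC", "MES", flip_rate = 0,
                                seed = 1)
  prof <- rbind(primary = pair$primary, recurrent = pair$recurrent)
  pred <- predict_state(clf, prof)
  expect_equal(pred$state, c("NPC", "MES"))
  att <- attribute(clf, prof)
  hyp <- transition_hypotheses(pair, pred$state, att, scr, ci$network)
  expect_gt(nrow(hyp$candidates), 0)
  # planted knockout T with its direct inhibiting edge to the flipped F
  hit <- hyp$candidates[hyp$candidates$ko_node == "T" &
                          hyp$candidates$feature == "F", ]
  expect_gte(nrow(hit), 1)
  expect_equal(hit$path[1], "T -> F")
  expect_equal(hit$path_sign[1], -1L)

  # identical predictions produce no hypotheses
  hyp0 <- transition_hypotheses(pair, c("NPC", "NPC"), att, scr, ci$network)
  expect_equal(nrow(hyp0$candidates), 0)
})

test_that("paths longer than max_path_len are excluded", {
  ci <- constructed_instance()
  scr <- knockout_screen(ci$model, ci$profiles)
  ts <- build_training_set(scr)
  clf <- train_classifier(ts, model_spec("boosted_trees", seed = 3,
                                         subsample = 1),
                          augment_rate = 0.05, augment_copies = 10)
  pair <- generate_patient_pair(ci$profiles, "NPC", "MES", flip_rate = 0,
                                seed = 1)
  prof <- rbind(primary = pair$primary, recurrent = pair$recurrent)
  pred <- predict_state(clf, prof)
  att <- attribute(clf, prof)
  # N -> T -> F needs 2 edges; with max_path_len = 1 only T -> F survives
  hyp <- transition_hypotheses(pair, pred$state, att, scr, ci$network,
                               max_path_len = 1)
  expect_false("N" %in% hyp$candidates$ko_node[hyp$candidates$feature == "F"])
  expect_true(all(hyp$candidates$path_len <= 1))
})
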