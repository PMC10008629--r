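test_that("every family separates a separable toy set and is deterministic", {
  tr <- separable_train(n = 200)
  models <- fit_single_models(tr, c("v1", "v2"), seed = 1)
  y <- as.numeric(tr$label == "presence")
  for (a in names(models)) {
    p <- predict(models[[a]], tr)
    expect_equal(auc_score(p, y), 1, tolerance = 1e-9,
                 label = paste("AUC of", a))
  }
  models2 <- fit_single_models(tr, c("v1", "v2"), seed = 1)
  for (a in names(models))
    expect_identical(predict(models[[a]], tr), predict(models2[[a]], tr))
  expect_error(fit_single_models(tr[tr$label == "presence", ],
                                 c("v1", "v2")), "single class")
  expect_error(fit_single_models(tr, "v1"), "2 covariates")
})

test_that("label-permuted data give chance-level held-out AUC", {
  set.seed(5)
  rep_seeds <- sample.int(1e6, 20)   # drawn up front: model fitting reseeds
  aucs <- vapply(rep_seeds, function(s) {
    tr <- separable_train(n = 300, seed = s)
    set.seed(s + 1)
    tr$label <- sample(tr$label)          # break the signal
    idx <- sample(nrow(tr), 200)
    m <- fit_single_models(tr[idx, ], c("v1", "v2"),
                           algorithms = "glm_ridge", seed = 1)
    te <- tr[-idx, ]
    auc_score(predict(m$glm_ridge, te),
              as.numeric(te$label == "presence"))
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 3 * sd(aucs) / sqrt(20) + 0.02)
})

test_that("permutation importance isolates the informative variable", {
  set.seed(2)
  n <- 300
  tr <- data.frame(label = rep(c("presence", "pseudo_absence"), each = n / 2),
                   v1 = c(rnorm(n / 2, 2), rnorm(n / 2, -2)),
                   v2 = 1)                       # constant: unusable
  m <- fit_single_models(tr, c("v1", "v2"), algorithms = "boosted_trees",
                         seed = 1)$boosted_trees
  imp <- permutation_importance(m, tr, n_perm = 10, seed = 1)
  expect_equal(imp$importance[imp$variable == "v2"], 0)
  expect_gt(imp$importance[imp$variable == "v1"], 0.5)
  # a collinear duplicate dilutes importance for ridge regression
  tr2 <- tr; tr2$v2 <- tr2$v1
  solo <- permutation_importance(
    fit_single_models(tr, c("v1", "v2"), algorithms = "glm_ridge",
                      seed = 1)$glm_ridge, tr, n_perm = 10, seed = 1)
  dup <- permutation_importance(
    fit_single_models(tr2, c("v1", "v2"), algorithms = "glm_ridge",
                      seed = 1)$glm_ridge, tr2, n_perm = 10, seed = 1)
  expect_lt(dup$importance[dup$variable == "v1"],
            solo$importance[solo$variable == "v1"])
})

test_that("variable selection applies the above-average rule", {
  tab <- data.frame(algorithm = "a",
                    variable = c("v1", "v2", "v3", "v4"),
                    importance = c(0.6, 0.3, 0.1, 0.0))
  expect_equal(select_variables(tab), c("v1", "v2"))   # mean 0.25
  tied <- data.frame(algorithm = "a", variable = c("x", "y"),
                     importance = c(0.4, 0.4))
  expect_equal(select_variables(tied), "x")
  one <- data.frame(algorithm = "a", variable = "only", importance = 0.2)
  expect_equal(select_variables(one), "only")
  expect_error(select_variables(one[0, ]), "empty")
})

test_that("evaluation arithmetic matches the confusion-matrix definitions", {
  # TP=45 FN=5 TN=40 FP=10 at threshold 0.5
  pred <- c(rep(0.8, 45), rep(0.05, 5), rep(0.1, 40), rep(0.9, 10))
  y <- c(rep(1, 50), rep(0, 50))
  sc <- confusion_scores(pred, y, 0.5)
  expect_equal(sc$sensitivity, 0.9)
  expect_equal(sc$specificity, 0.8)
  expect_equal(sc$TSS, 0.7)
})

test_that("model evaluation handles perfect and uninformative classifiers", {
  tr <- separable_train(n = 200, gap = 8, sd = 0.3)
  m <- fit_single_models(tr, c("v1", "v2"), algorithms = "boosted_trees",
                         seed = 1)$boosted_trees
  ev <- evaluate_model(m, tr)
  expect_equal(ev$TSS, 1)
  expect_equal(ev$kappa, 1)
  expect_equal(ev$AUC, 1)
  # constant features -> constant score -> TSS 0, AUC 0.5
  trc <- tr; trc$v1 <- 1; trc$v2 <- 2
  mc <- fit_single_models(trc, c("v1", "v2"), algorithms = "knn",
                          seed = 1)$knn
  evc <- evaluate_model(mc, trc)
  expect_equal(evc$TSS, 0)
  expect_equal(evc$AUC, 0.5)
  expect_error(evaluate_model(m, tr[tr$label == "presence", ]),
               "single class")
})

test_that("the reported threshold maximizes TSS over the sweep grid", {
  set.seed(8)
  for (rep in 1:5) {
    tr <- separable_train(n = 120, gap = 2, sd = 1.2,
                          seed = sample.int(1e6, 1))
    m <- fit_single_models(tr, c("v1", "v2"), algorithms = "random_forest",
                           seed = 3)$random_forest
    ev <- evaluate_model(m, tr)
    pred <- predict(m, tr)
    y <- as.numeric(tr$label == "presence")
    sweep_tss <- vapply(seq(0, 1, length.out = 101), function(th)
      confusion_scores(pred, y, th)$TSS, numeric(1))
    expect_equal(confusion_scores(pred, y, ev$threshold)$TSS, max(sweep_tss))
  }
})

test_that("committee averaging follows the lattice and the 0.5 rule", {
  evals <- list(a = list(TSS = 0.9), b = list(TSS = 0.8),
                c = list(TSS = 0.75))
  maps <- list(a = matrix(1, 1, 1), b = matrix(1, 1, 1), c = matrix(0, 1, 1))
  ens <- committee_ensemble(evals, maps, tss_gate = 0.7)
  expect_equal(ens$committee_score[1, 1], 2 / 3)
  expect_true(ens$binary_map[1, 1])
  # two members split 1/0: score 0.5 -> present by the >= rule
  maps2 <- list(a = matrix(1, 1, 1), b = matrix(0, 1, 1))
  ens2 <- committee_ensemble(evals[1:2], maps2, tss_gate = 0.7)
  expect_equal(ens2$committee_score[1, 1], 0.5)
  expect_true(ens2$binary_map[1, 1])
  # unanimity absent
  zero <- list(a = matrix(0, 1, 1), b = matrix(0, 1, 1))
  ens3 <- committee_ensemble(evals[1:2], zero, tss_gate = 0.7)
  expect_false(ens3$binary_map[1, 1])
  # gate failure reports each member's TSS
  expect_error(committee_ensemble(list(a = list(TSS = 0.2)), maps["a"], 0.7),
               "no admissible members.*a=0.200")
  # committee scores live on the k/m lattice
  set.seed(1)
  maps5 <- lapply(1:5, function(i) matrix(runif(20) > 0.5, 4, 5))
  names(maps5) <- letters[1:5]
  evals5 <- lapply(maps5, function(m) list(TSS = 0.9))
  s <- committee_ensemble(evals5, maps5, 0.7)$committee_score
  expect_true(all(abs(s * 5 - round(s * 5)) < 1e-12))
})

test_that("the region constraint masks and is idempotent", {
  g <- tiny_grid(n_regions = 2)
  score <- matrix(1, g$n_rows, g$n_cols)
  pred <- structure(list(committee_score = score,
                         binary_map = score > 0,
                         members = "a"),
                    class = "arc_ensemble_prediction")
  all_regions <- constrain_to_regions(pred, 1:2, g)
  expect_true(all(all_regions$binary_map[g$region_id > 0]))
  only1 <- constrain_to_regions(pred, 1, g)
  expect_true(all(!only1$binary_map[g$region_id == 2]))
  expect_true(all(only1$binary_map[g$region_id == 1]))
  twice <- constrain_to_regions(only1, 1, g)
  expect_identical(twice, only1)
  expect_error(constrain_to_regions(pred, integer(0), g), "non-empty")
  expect_error(constrain_to_regions(pred, 99, g), "unknown region")
})
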