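test_that("both classifiers separate well-separated populations almost perfectly", {
  samp <- test_samples(test_pair(delta = 4, n_events = 900), seed = 61)
  comm <- build_even_community(samp, n_per_pop = 800, seed = 1)
  sp <- split_train_test(comm, seed = 2)
  for (mth in c("LDA", "RF")) {
    fit <- fit_cell_classifier(sp, method = mth, seed = 3)
    expect_gte(evaluate_classifier(fit, sp)$accuracy, 0.99)
  }
})

test_that("identical distributions give chance-level held-out AUC", {
  samp <- test_samples(test_pair(delta = 0, n_events = 5300,
                                 ids = c("same1", "same2")), seed = 62)
  comm <- build_even_community(samp, n_per_pop = 5000, seed = 4)
  sp <- split_train_test(comm, seed = 5)  # 3,000 held-out cells
  fit <- fit_cell_classifier(sp, method = "LDA")
  rep <- evaluate_classifier(fit, sp)
  expect_equal(rep$n_test, 3000)
  expect_lt(abs(rep$auc - 0.5), 0.03)
})

test_that("fitting is deterministic given method, seed and data", {
  samp <- test_samples(test_pair(delta = 1, n_events = 500), seed = 63)
  comm <- build_even_community(samp, n_per_pop = 400, seed = 6)
  sp <- split_train_test(comm, seed = 7)
  f1 <- fit_cell_classifier(sp, method = "RF", seed = 11)
  f2 <- fit_cell_classifier(sp, method = "RF", seed = 11)
  expect_identical(predict(f1, sp$test$events),
                   predict(f2, sp$test$events))
  expect_identical(predict(f1, sp$test$events, type = "prob"),
                   predict(f2, sp$test$events, type = "prob"))
})

test_that("degenerate training sets are refused", {
  em <- random_event_matrix(50)
  expect_error(fit_cell_classifier(em, rep("A", 50)), "2 distinct")
  expect_error(fit_cell_classifier(em, rep("A", 10)), "one per training event")
})

test_that("prediction validates channels and handles empty input", {
  samp <- test_samples(test_pair(delta = 2, n_events = 300), seed = 64)
  comm <- build_even_community(samp, n_per_pop = 200, seed = 8)
  fit <- fit_cell_classifier(comm, method = "LDA")
  empty <- event_matrix(matrix(numeric(0), 0, 12), canonical_panel())
  expect_length(predict(fit, empty), 0)
  expect_equal(dim(predict(fit, empty, type = "prob")), c(0, 2))
  wrong <- random_event_matrix(5, channels = c("FL1-H", "FL3-H"))
  expect_error(predict(fit, wrong), "FSC-A")
})

test_that("scores are normalised and argmax-consistent with hard labels", {
  samp <- test_samples(test_pair(delta = 1, n_events = 600), seed = 65)
  comm <- build_even_community(samp, n_per_pop = 500, seed = 9)
  sp <- split_train_test(comm, seed = 10)
  for (mth in c("LDA", "RF")) {
    fit <- fit_cell_classifier(sp, method = mth, seed = 12)
    pr <- predict(fit, sp$test$events, type = "prob")
    cl <- predict(fit, sp$test$events, type = "class")
    expect_equal(unname(rowSums(pr)), rep(1, nrow(pr)), tolerance = 1e-9)
    expect_identical(as.character(cl),
                     fit$classes[max.col(pr, ties.method = "first")])
  }
})

test_that("RF scores equal per-tree vote fractions; one tree gives 0/1 scores", {
  samp <- test_samples(test_pair(delta = 1, n_events = 300), seed = 66)
  comm <- build_even_community(samp, n_per_pop = 200, seed = 13)
  sp <- split_train_test(comm, seed = 14)
  fit <- fit_cell_classifier(sp, method = "RF", ntree = 25, seed = 15)
  pr <- predict(fit, sp$test$events, type = "prob")
  # oracle: count the individual tree votes directly
  feat <- cytopop:::classifier_features(fit, sp$test$events)
  votes <- predict(fit$fit, feat, predict.all = TRUE)$individual
  frac_b <- rowMeans(votes == fit$classes[2])
  expect_equal(unname(pr[, 2]), unname(frac_b), tolerance = 1e-12)
  one <- fit_cell_classifier(sp, method = "RF", ntree = 1, seed = 16)
  p1 <- predict(one, sp$test$events, type = "prob")
  expect_true(all(p1 %in% c(0, 1)))
})

test_that("consistent relabelling of taxa permutes predictions identically", {
  samp <- test_samples(test_pair(delta = 2, n_events = 300), seed = 67)
  comm <- build_even_community(samp, n_per_pop = 250, seed = 17)
  test_ev <- simulate_population(test_pair(delta = 2)[[1]], seed = 99,
                                 n_events = 100)
  f_ab <- fit_cell_classifier(comm$events, comm$labels, method = "LDA")
  relab <- factor(ifelse(comm$labels == "A", "zz", "aa"))
  f_rel <- fit_cell_classifier(comm$events, relab, method = "LDA")
  map <- c(A = "zz", B = "aa")
  expect_identical(unname(map[as.character(predict(f_ab, test_ev))]),
                   as.character(predict(f_rel, test_ev)))
})

test_that("training accuracy dominates held-out accuracy on average", {
  deltas <- c(0.5, 1)
  gap <- vapply(1:4, function(s) {
    samp <- test_samples(test_pair(delta = deltas[1 + s %% 2],
                                   n_events = 400), seed = 70 + s)
    comm <- build_even_community(samp, n_per_pop = 300, seed = s)
    sp <- split_train_test(comm, seed = s + 100)
    fit <- fit_cell_classifier(sp, method = "RF", ntree = 50, seed = s)
    acc_tr <- accuracy(sp$train$labels, predict(fit, sp$train$events))
    acc_te <- accuracy(sp$test$labels, predict(fit, sp$test$events))
    acc_tr - acc_te
  }, 0)
  expect_gt(mean(gap), 0)
})

test_that("plug-in composition estimation counts predicted labels", {
  samp <- test_samples(test_pair(delta = 4, n_events = 1200), seed = 68)
  comm <- build_even_community(samp, n_per_pop = 1000, seed = 18)
  fit <- fit_cell_classifier(comm, method = "RF", seed = 19)
  # a gradient community at p1 = 0.30 is recovered closely
  gr <- build_gradient(samp[[1]], samp[[2]], levels = 0.30, n_total = 1000,
                       seed = 20)
  est <- estimate_composition(fit, gr$communities[[1]])
  expect_equal(sum(est$p_hat), 1, tolerance = 1e-9)
  expect_equal(sum(est$counts), 1000)
  expect_lt(abs(est$p_hat[["A"]] - 0.30), 0.02)
  expect_error(estimate_composition(
    fit, event_matrix(matrix(numeric(0), 0, 12), canonical_panel())),
    "zero events")
})

test_that("composition estimates equal the confusion rows applied to the truth", {
  samp <- test_samples(test_pair(delta = 1, n_events = 500), seed = 69)
  comm <- build_even_community(samp, n_per_pop = 400, seed = 21)
  sp <- split_train_test(comm, seed = 22)
  fit <- fit_cell_classifier(sp, method = "LDA")
  y_pred <- predict(fit, sp$test$events)
  cm <- confusion_matrix(sp$test$labels, y_pred, fit$classes)
  est <- estimate_composition(fit, sp$test$events)
  n_true <- as.numeric(table(sp$test$labels)[fit$classes])
  expect_equal(as.numeric(est$counts),
               as.numeric(n_true %*% cm$fractions))
})
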