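small_config <- function(seed = 1) {
  experiment_config(n_per_pop = 250, max_combinations = 3, n_total = 400,
                    levels = c(0.1, 0.5, 0.9), ntree = 60, seed = seed)
}

test_that("the pairwise scan covers every pair once per classifier", {
  models <- default_panel_models(n_taxa = 3, seed = 81, n_events = 400)
  samp <- test_samples(models, seed = 82)
  scan <- run_pairwise_scan(samp, small_config())
  expect_equal(nrow(scan$results), 3 * 2)  # C(3,2) pairs x 2 methods
  expect_setequal(unique(scan$results$method), c("LDA", "RF"))
  expect_true(all(scan$results$n_test ==
                    2 * (250 - round(0.7 * 250))))
  expect_true(all(is.finite(scan$results$auc)))
})

test_that("pairwise summary statistics recompute from the emitted table", {
  models <- default_panel_models(n_taxa = 3, seed = 83, n_events = 400)
  samp <- test_samples(models, seed = 84)
  scan <- run_pairwise_scan(samp, small_config())
  for (m in c("LDA", "RF")) {
    d <- scan$results[scan$results$method == m, ]
    s <- scan$summary[scan$summary$method == m, ]
    expect_equal(s$mu_acc, mean(d$accuracy))
    expect_equal(s$sd_auc, sd(d$auc))
    expect_equal(s$frac_acc_gt_090, mean(d$accuracy > 0.90))
  }
  # two populations: a single row whose summary equals it
  scan2 <- run_pairwise_scan(samp[1:2], small_config())
  expect_equal(nrow(scan2$results), 2)
  expect_equal(scan2$summary$mu_acc,
               scan2$results$accuracy[match(scan2$summary$method,
                                            scan2$results$method)])
})

test_that("experiments are byte-identical under a fixed root seed", {
  models <- default_panel_models(n_taxa = 3, seed = 85, n_events = 400)
  samp <- test_samples(models, seed = 86)
  s1 <- run_pairwise_scan(samp, small_config(seed = 9))
  s2 <- run_pairwise_scan(samp, small_config(seed = 9))
  expect_identical(s1$results, s2$results)
  expect_identical(s1$summary, s2$summary)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  f1 <- write_experiment(s1, d1); f2 <- write_experiment(s2, d2)
  expect_identical(readLines(f1[1]), readLines(f2[1]))
  s3 <- run_pairwise_scan(samp, small_config(seed = 10))
  expect_false(identical(s1$results$accuracy, s3$results$accuracy))
})

test_that("the richness scan enumerates all combinations when few exist", {
  models <- default_panel_models(n_taxa = 4, seed = 87, n_events = 400)
  samp <- test_samples(models, seed = 88)
  scan <- run_richness_scan(samp, S_values = c(2, 4),
                            config = small_config())
  # S = 2: C(4,2) = 6 capped at 3; S = 4: single community
  expect_equal(sum(scan$results$S == 2 & scan$results$method == "RF"), 3)
  expect_equal(sum(scan$results$S == 4 & scan$results$method == "RF"), 1)
  expect_equal(scan$summary$baseline[scan$summary$S == 4][1], 0.25)
  # band is mean +/- 1 sd
  s2 <- scan$summary[scan$summary$S == 2 & scan$summary$method == "RF", ]
  expect_equal(s2$band_hi - s2$band_lo, 2 * s2$sd_accuracy)
})

test_that("indistinguishable populations stay at chance across richness", {
  base <- gaussian_population("x", n_events = 400)
  models <- lapply(c("p1", "p2", "p3"), function(id) {
    population_model(id, base$components, n_events = 400)
  })
  samp <- test_samples(models, seed = 89)
  scan <- run_richness_scan(samp, S_values = c(2, 3),
                            config = small_config())
  for (S in c(2, 3)) {
    acc <- scan$summary$mean_accuracy[scan$summary$S == S]
    expect_true(all(abs(acc - 1 / S) < 0.06))
  }
})

test_that("gradient recovery reports per-level predictions, RMSE and D1 bands", {
  samp <- test_samples(test_pair(delta = 3, n_events = 1200), seed = 90)
  cfg <- small_config()
  gr <- run_gradient_recovery(samp[[1]], samp[[2]], cfg)
  expect_equal(nrow(gr$results), length(cfg$levels) * 2)
  expect_equal(gr$n_train, 2 * cfg$n_per_pop)
  rf <- gr$results[gr$results$method == "RF", ]
  expect_lt(rmse_gradient(rf$level, rf$p_hat), 0.06)
  expect_equal(gr$rmse$rmse[gr$rmse$method == "RF"],
               rmse_gradient(rf$level, rf$p_hat))
  # D1 columns agree with the diversity module at every level
  for (i in seq_len(nrow(rf))) {
    tgt <- d1_with_ci(c(rf$level[i], 1 - rf$level[i]), cfg$epsilon_i)
    expect_equal(rf$d1_target[i], tgt$d1)
    expect_equal(rf$d1_ci95_lo[i], tgt$ci95[["lo"]])
    expect_equal(rf$d1_pred[i], hill_d1(c(rf$p_hat[i], 1 - rf$p_hat[i])))
  }
})

test_that("gradient training draws are disjoint from gradient draws", {
  samp <- test_samples(test_pair(delta = 1, n_events = 1500), seed = 91)
  cfg <- experiment_config(n_per_pop = 300, n_total = 600,
                           levels = c(0.3, 0.5), ntree = 30, seed = 3)
  # tag each pooled event with a unique id on a scratch channel to track
  # event identity through the draws
  tag <- function(s, offset) {
    v <- s$pooled$values
    v[, "FL4-A"] <- offset + seq_len(nrow(v))
    s$pooled <- event_matrix(v, channels(s$pooled))
    s
  }
  res <- run_gradient_recovery(tag(samp[[1]], 0), tag(samp[[2]], 1e6), cfg)
  train_ids <- res$train_community$events$values[, "FL4-A"]
  for (comm in res$gradient$communities) {
    grad_ids <- comm$events$values[, "FL4-A"]
    expect_length(intersect(train_ids, grad_ids), 0)
    expect_false(anyDuplicated(grad_ids) > 0)  # without replacement
  }
})

test_that("experiment configs read from YAML and reject unknown keys", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("n_per_pop: 100", "ntree: 10", "seed: 4"), path)
  cfg <- read_experiment_config(path)
  expect_equal(cfg$n_per_pop, 100L)
  expect_equal(cfg$ntree, 10L)
  expect_equal(cfg$fraction_train, 0.70)
  expect_equal(cfg$levels, gradient_levels())
  bad <- withr::local_tempfile(fileext = ".yaml")
  writeLines("n_per_population: 5", bad)
  expect_error(read_experiment_config(bad), "unknown config key")
})
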