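test_that("simulated populations match their model in the large-sample limit", {
  m <- gaussian_population("t1", n_events = 50000)
  em <- simulate_population(m, seed = 41)
  expect_equal(n_events(em), 50000)
  expect_identical(channels(em), canonical_panel())
  expect_true(all(em$values >= 0))
  y <- asinh(em$values)
  mu <- m$components[[1]]$mean
  sdv <- sqrt(diag(m$components[[1]]$cov))
  se <- sdv / sqrt(50000)
  expect_true(all(abs(colMeans(y) - mu) < 4 * se))
  # area channels sit above and correlate with their height channels
  expect_gt(stats::cor(y[, "FL1-A"], y[, "FL1-H"]), 0.8)
  expect_gt(mean(y[, "FL1-A"] - y[, "FL1-H"]), 0)
})

test_that("zero-drift replicates differ only by sampling noise", {
  m <- gaussian_population("t1", n_events = 20000)
  r1 <- simulate_population(m, drift_model(0, 0), replicate_index = 1,
                            seed = 42)
  r2 <- simulate_population(m, drift_model(0, 0), replicate_index = 2,
                            seed = 42)
  expect_false(identical(r1$values, r2$values))
  se <- sqrt(2) * sqrt(diag(m$components[[1]]$cov)) / sqrt(20000)
  diff <- abs(colMeans(asinh(r1$values)) - colMeans(asinh(r2$values)))
  expect_true(all(diff < 4 * se))
})

test_that("replicate drift shifts channel means beyond sampling noise", {
  m <- gaussian_population("t1", n_events = 20000)
  r1 <- simulate_population(m, drift_model(shift_sd = 0.3),
                            replicate_index = 1, seed = 43)
  r2 <- simulate_population(m, drift_model(shift_sd = 0.3),
                            replicate_index = 2, seed = 43)
  diff <- abs(colMeans(asinh(r1$values)) - colMeans(asinh(r2$values)))
  expect_gt(max(diff), 0.05)
})

test_that("an empty simulation yields an empty event matrix", {
  m <- gaussian_population("t1", n_events = 0)
  em <- simulate_population(m, seed = 44)
  expect_equal(n_events(em), 0)
  expect_identical(channels(em), canonical_panel())
})

test_that("simulation is bit-reproducible under a fixed seed", {
  m <- gaussian_population("t1", n_events = 500)
  expect_identical(simulate_population(m, seed = 45)$values,
                   simulate_population(m, seed = 45)$values)
  panel <- simulate_panel(test_pair(n_events = 300), seed = 46)
  panel2 <- simulate_panel(test_pair(n_events = 300), seed = 46)
  expect_identical(panel$manifest, panel2$manifest)
  expect_identical(panel$events[["A"]][[1]]$values,
                   panel2$events[["A"]][[1]]$values)
})

test_that("invalid population models are rejected", {
  mu <- rep(1, 12)
  good <- diag(12)
  bad_cov <- good; bad_cov[1, 1] <- -1
  expect_error(population_model("t", list(list(weight = 1, mean = mu,
                                               cov = bad_cov))),
               "semi-definite")
  expect_error(population_model("t", list(list(weight = 0.5, mean = mu,
                                               cov = good))),
               "sum to 1")
  expect_error(population_model("t", list(list(weight = 1, mean = 1:5,
                                               cov = good))),
               "length 12")
})

test_that("panels write files plus a manifest that reconciles exactly", {
  dir <- withr::local_tempdir()
  panel <- simulate_panel(test_pair(n_events = 200), replicates = 2,
                          noise = noise_model(0.1), seed = 47, dir = dir,
                          format = "csv")
  expect_equal(nrow(panel$manifest), 4)  # 2 taxa x 2 replicates
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  for (i in seq_len(nrow(panel$manifest))) {
    row <- panel$manifest[i, ]
    em <- read_events(row$path)
    expect_equal(n_events(em), row$n_events)
    flags <- panel$debris[[row$taxon_id]][[row$replicate]]
    expect_equal(sum(flags), row$n_noise)
    expect_length(flags, row$n_events)
  }
  reloaded <- load_panel(dir)
  expect_identical(reloaded$taxa, panel$taxa)
  expect_equal(reloaded$events[["A"]][[2]]$values,
               panel$events[["A"]][[2]]$values, tolerance = 1e-6)
  expect_error(simulate_panel(test_pair(ids = c("x", "x"))), "duplicate")
})

test_that("a 20-taxon duplicate panel yields 40 manifest rows", {
  models <- default_panel_models(n_taxa = 20, seed = 48, n_events = 20)
  panel <- simulate_panel(models, replicates = 2, seed = 49)
  expect_equal(nrow(panel$manifest), 40)
  expect_length(unique(panel$manifest$taxon_id), 20)
})

test_that("injected debris follows the noise fraction binomially", {
  models <- test_pair(n_events = 10000)
  panel <- simulate_panel(models, replicates = 1,
                          noise = noise_model(0.1), seed = 50)
  n_noise <- panel$manifest$n_noise
  expect_true(all(abs(n_noise - 1000) < 4 * sqrt(10000 * 0.1 * 0.9)))
  # the default gate removes (essentially all of) the debris
  samp <- panel_samples(panel)
  expect_lt(abs(cell_count(samp$A) - (10000 - n_noise[1])), 3)
})

test_that("preset separability orders downstream accuracy monotonically", {
  pp <- preset_pairs(n_events = 1500)
  acc <- vapply(c("none", "low", "medium", "high"), function(nm) {
    mean(vapply(1:2, function(s) {
      samp <- test_samples(pp[[nm]], seed = 500 + s,
                           noise = noise_model(0.02))
      comm <- build_even_community(samp, n_per_pop = 1000,
                                   seed = 600 + s)
      sp <- split_train_test(comm, seed = 700 + s)
      fit <- fit_cell_classifier(sp, method = "RF", ntree = 100,
                                 seed = 800 + s)
      evaluate_classifier(fit, sp)$accuracy
    }, 0))
  }, 0)
  expect_true(all(diff(acc) > 0))
  expect_lt(abs(acc[["none"]] - 0.5), 0.05)
  expect_gte(acc[["high"]], 0.98)
})
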