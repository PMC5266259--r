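#' Experiment configuration
#'
#' Bundles the tunable constants of the three community experiments. The
#' defaults are the standard study conditions: 5,000 cells subsampled per
#' axenic culture, a 70/30 stratified train/test split, at most 150 random
#' taxon combinations per richness level, 13 gradient levels from 1% to 99%
#' with 10,000 cells per gradient community, and a 5% instrumental counting
#' error for the diversity intervals.
#'
#' @param n_per_pop Cells drawn per population for even communities.
#' @param fraction_train Training fraction of the stratified split.
#' @param max_combinations Cap on combinations per richness level.
#' @param levels Gradient levels (target abundance of the first taxon).
#' @param n_total Cells per gradient community.
#' @param epsilon_i Relative instrumental counting error.
#' @param methods Classifier methods to run (always evaluated on identical
#'   community draws, so comparisons are paired).
#' @param ntree,mtry Random-forest settings (see [fit_cell_classifier()]).
#' @param seed Root seed; every stochastic step derives its own seed from it.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(n_per_pop = 5000L, fraction_train = 0.70,
                              max_combinations = 150L,
                              levels = gradient_levels(), n_total = 10000L,
                              epsilon_i = 0.05, methods = c("LDA", "RF"),
                              ntree = 200L, mtry = NULL, seed = 1L) {
  stopifnot(all(methods %in% c("LDA", "RF")))
  structure(list(n_per_pop = as.integer(n_per_pop),
                 fraction_train = fraction_train,
                 max_combinations = as.integer(max_combinations),
                 levels = levels, n_total = as.integer(n_total),
                 epsilon_i = epsilon_i, methods = methods,
                 ntree = as.integer(ntree), mtry = mtry,
                 seed = as.integer(seed)),
            class = "experiment_config")
}

#' Read an experiment configuration from a YAML file
#'
#' Flat key/value YAML; keys are the arguments of [experiment_config()].
#' Missing keys take their defaults.
#'
#' @param path Path to the YAML file.
#' @return An `experiment_config`.
#' @export
read_experiment_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- names(formals(experiment_config))
  unknown <- setdiff(names(cfg), known)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  do.call(experiment_config, cfg)
}

fit_pair_on_split <- function(split, config) {
  lapply(stats::setNames(config$methods, config$methods), function(mth) {
    fit_cell_classifier(split, method = mth, ntree = config$ntree,
                        mtry = config$mtry,
                        seed = derive_seed(config$seed, paste0("fit-", mth)))
  })
}

#' Pairwise (S = 2) performance scan
#'
#' Builds one even two-population community per pair of populations,
#' splits it, trains every configured classifier on the identical split and
#' evaluates accuracy and AUC on the held-out cells. With 20 populations
#' this enumerates all 190 pairs.
#'
#' @param samples Named list of `population_sample` objects.
#' @param config An [experiment_config()].
#' @return An object of class `pairwise_scan`: `results` (one row per pair
#'   per classifier: taxon_a, taxon_b, method, accuracy, auc, n_test) and
#'   `summary` (per classifier: mu_auc, sd_auc, frac_auc_gt_090, mu_acc,
#'   sd_acc, frac_acc_gt_090), pairs ranked by accuracy within method.
#' @export
run_pairwise_scan <- function(samples, config = experiment_config()) {
  stopifnot(length(samples) >= 2L)
  taxa <- vapply(samples, function(s) s$taxon_id, "")
  pairs <- utils::combn(sort(taxa), 2L, simplify = FALSE)
  rows <- list()
  for (k in seq_along(pairs)) {
    pr <- pairs[[k]]
    comm_seed <- derive_seed(config$seed, "pairwise", k)
    comm <- build_even_community(samples[match(pr, taxa)],
                                 n_per_pop = config$n_per_pop,
                                 seed = comm_seed)
    split <- split_train_test(comm, config$fraction_train,
                              seed = derive_seed(comm_seed, "split"))
    fits <- fit_pair_on_split(split, config)
    for (mth in names(fits)) {
      rep <- evaluate_classifier(fits[[mth]], split)
      rows[[length(rows) + 1L]] <- data.frame(
        taxon_a = pr[1L], taxon_b = pr[2L], method = mth,
        accuracy = rep$accuracy, auc = rep$auc, n_test = rep$n_test,
        seed = comm_seed, stringsAsFactors = FALSE)
    }
  }
  results <- do.call(rbind, rows)
  results <- results[order(results$method, -results$accuracy), ]
  rownames(results) <- NULL
  summary <- do.call(rbind, lapply(split(results, results$method),
    function(d) data.frame(
      method = d$method[1L], n_pairs = nrow(d),
      mu_auc = mean(d$auc), sd_auc = stats::sd(d$auc),
      frac_auc_gt_090 = mean(d$auc > 0.90),
      mu_acc = mean(d$accuracy), sd_acc = stats::sd(d$accuracy),
      frac_acc_gt_090 = mean(d$accuracy > 0.90),
      stringsAsFactors = FALSE)))
  rownames(summary) <- NULL
  structure(list(results = results, summary = summary, config = config),
            class = "pairwise_scan")
}

#' @export
print.pairwise_scan <- function(x, ...) {
  cat("pairwise_scan: ", length(unique(paste(x$results$taxon_a,
                                             x$results$taxon_b))),
      " communities x ", length(unique(x$results$method)),
      " classifier(s)\n", sep = "")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Classifier performance against community richness
#'
#' For each richness S, enumerates up to `max_combinations` taxon
#' combinations (all of them when fewer exist), builds the even community,
#' splits 70/30 and records held-out accuracy for every configured
#' classifier; per S the mean accuracy and a 68% band (mean +/- 1 SD across
#' communities) are reported next to the 1/S random-guess baseline.
#'
#' @param samples Named list of `population_sample` objects.
#' @param S_values Richness levels to scan (default `2:length(samples)`).
#' @param config An [experiment_config()].
#' @return An object of class `richness_scan`: `results` (one row per
#'   community per classifier) and `summary` (per S per classifier:
#'   n_communities, mean_accuracy, sd_accuracy, band_lo, band_hi, baseline).
#' @export
run_richness_scan <- function(samples, S_values = NULL,
                              config = experiment_config()) {
  taxa <- vapply(samples, function(s) s$taxon_id, "")
  if (is.null(S_values)) S_values <- 2:length(samples)
  stopifnot(all(S_values >= 2L), all(S_values <= length(samples)))
  rows <- list()
  for (S in S_values) {
    combos <- enumerate_communities(taxa, S, config$max_combinations,
                                    seed = derive_seed(config$seed,
                                                       "richness-combos", S))
    for (k in seq_along(combos)) {
      comm_seed <- derive_seed(config$seed, paste0("richness-S", S), k)
      comm <- build_even_community(samples[match(combos[[k]], taxa)],
                                   n_per_pop = config$n_per_pop,
                                   seed = comm_seed)
      split <- split_train_test(comm, config$fraction_train,
                                seed = derive_seed(comm_seed, "split"))
      fits <- fit_pair_on_split(split, config)
      for (mth in names(fits)) {
        rep <- evaluate_classifier(fits[[mth]], split)
        rows[[length(rows) + 1L]] <- data.frame(
          S = S, community = k, method = mth,
          taxa = paste(combos[[k]], collapse = "+"),
          accuracy = rep$accuracy, n_test = rep$n_test, seed = comm_seed,
          stringsAsFactors = FALSE)
      }
    }
  }
  results <- do.call(rbind, rows)
  rownames(results) <- NULL
  summary <- do.call(rbind, lapply(
    split(results, list(results$S, results$method), drop = TRUE),
    function(d) {
      s <- stats::sd(d$accuracy)
      if (is.na(s)) s <- 0
      data.frame(S = d$S[1L], method = d$method[1L],
                 n_communities = nrow(d), mean_accuracy = mean(d$accuracy),
                 sd_accuracy = s, band_lo = mean(d$accuracy) - s,
                 band_hi = mean(d$accuracy) + s, baseline = 1 / d$S[1L],
                 stringsAsFactors = FALSE)
    }))
  summary <- summary[order(summary$method, summary$S), ]
  rownames(summary) <- NULL
  structure(list(results = results, summary = summary, config = config),
            class = "richness_scan")
}

#' @export
print.richness_scan <- function(x, ...) {
  cat("richness_scan over S = ",
      paste(range(x$summary$S), collapse = ".."), "\n", sep = "")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Abundance-gradient recovery with diversity intervals
#'
#' Trains each configured classifier on a full even two-population community
#' (no held-out split: the gradient itself is the test set), predicts the
#' composition of every gradient community by plug-in cell counting, and
#' reports the RMSE between predicted and target abundances together with
#' the Hill diversity D1 of target and prediction at every level, the
#' target's confidence intervals reflecting the instrumental counting
#' error.
#'
#' Training draws and gradient draws are disjoint whenever the pools are
#' large enough: training cells are drawn first and each gradient community
#' is drawn from the remainder, emulating the separately measured mixtures
#' an in vitro gradient would provide.
#'
#' @param sample_a,sample_b `population_sample` objects for the two taxa.
#' @param config An [experiment_config()].
#' @return An object of class `gradient_recovery`: `results` (one row per
#'   level per classifier: level, method, p_hat, d1_target, d1_pred,
#'   d1_ci68_lo/hi, d1_ci95_lo/hi), `rmse` (per classifier), plus the
#'   `train_community` and `gradient` objects used.
#' @export
run_gradient_recovery <- function(sample_a, sample_b,
                                  config = experiment_config()) {
  stopifnot(inherits(sample_a, "population_sample"),
            inherits(sample_b, "population_sample"))
  n_a <- cell_count(sample_a); n_b <- cell_count(sample_b)
  need_grad <- max(round(config$levels * config$n_total),
                   round((1 - config$levels) * config$n_total))
  # training first; gradient from the remainder when capacity permits
  reserve <- function(s, avail) {
    idx <- with_seed(derive_seed(config$seed, paste0("train-", s$taxon_id)),
                     sample.int(avail, min(config$n_per_pop, avail)))
    idx
  }
  idx_a <- reserve(sample_a, n_a); idx_b <- reserve(sample_b, n_b)
  rest <- function(s, idx, need) {
    avail <- cell_count(s)
    if (avail - length(idx) >= need) {
      pooled_rest <- subset_events(s$pooled, setdiff(seq_len(avail), idx))
      structure(list(taxon_id = s$taxon_id, replicates = s$replicates,
                     gate = s$gate, pooled = pooled_rest,
                     counts = n_events(pooled_rest)),
                class = "population_sample")
    } else s  # pool too small for disjoint draws; fall back to full pool
  }
  grad_a <- rest(sample_a, idx_a, need_grad)
  grad_b <- rest(sample_b, idx_b, need_grad)
  train_comm <- {
    ev <- bind_events(subset_events(sample_a$pooled, idx_a),
                      subset_events(sample_b$pooled, idx_b))
    taxa <- c(sample_a$taxon_id, sample_b$taxon_id)
    n_i <- c(length(idx_a), length(idx_b))
    new_community(taxa, ev, factor(rep(taxa, n_i), levels = taxa),
                  n_i / sum(n_i), n_i)
  }
  gradient <- build_gradient(grad_a, grad_b, levels = config$levels,
                             n_total = config$n_total,
                             seed = derive_seed(config$seed, "gradient"))
  fits <- lapply(stats::setNames(config$methods, config$methods),
    function(mth) fit_cell_classifier(
      train_comm, method = mth, ntree = config$ntree, mtry = config$mtry,
      seed = derive_seed(config$seed, paste0("fit-", mth))))
  rows <- list()
  for (mth in names(fits)) {
    for (k in seq_along(config$levels)) {
      p1 <- config$levels[k]
      est <- estimate_composition(fits[[mth]], gradient$communities[[k]])
      p_hat1 <- unname(est$p_hat[sample_a$taxon_id])
      d_tgt <- d1_with_ci(c(p1, 1 - p1), config$epsilon_i)
      rows[[length(rows) + 1L]] <- data.frame(
        level = p1, method = mth, p_hat = p_hat1,
        d1_target = d_tgt$d1, d1_pred = hill_d1(c(p_hat1, 1 - p_hat1)),
        d1_ci68_lo = d_tgt$ci68[["lo"]], d1_ci68_hi = d_tgt$ci68[["hi"]],
        d1_ci95_lo = d_tgt$ci95[["lo"]], d1_ci95_hi = d_tgt$ci95[["hi"]],
        stringsAsFactors = FALSE)
    }
  }
  results <- do.call(rbind, rows)
  rownames(results) <- NULL
  rmse <- do.call(rbind, lapply(split(results, results$method), function(d) {
    data.frame(method = d$method[1L],
               rmse = rmse_gradient(d$level, d$p_hat),
               stringsAsFactors = FALSE)
  }))
  rownames(rmse) <- NULL
  structure(list(results = results, rmse = rmse,
                 n_train = n_events(train_comm$events),
                 train_community = train_comm, gradient = gradient,
                 config = config),
            class = "gradient_recovery")
}

#' @export
print.gradient_recovery <- function(x, ...) {
  cat("gradient_recovery: ", length(unique(x$results$level)),
      " levels, trained on ", x$n_train, " cells\n", sep = "")
  print(x$rmse, row.names = FALSE)
  invisible(x)
}

#' Write experiment outputs as tidy CSV plus a JSON summary
#'
#' @param x A `pairwise_scan`, `richness_scan` or `gradient_recovery`.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix; defaults to the object's class.
#' @return Character vector of the files written, invisibly.
#' @export
write_experiment <- function(x, dir, prefix = class(x)[1L]) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  written <- character(0)
  tables <- Filter(is.data.frame, unclass(x))
  for (nm in names(tables)) {
    p <- file.path(dir, paste0(prefix, "_", nm, ".csv"))
    utils::write.csv(tables[[nm]], p, row.names = FALSE)
    written <- c(written, p)
  }
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    summ <- tables[[intersect(c("summary", "rmse"), names(tables))[1L]]]
    p <- file.path(dir, paste0(prefix, "_summary.json"))
    jsonlite::write_json(summ, p, dataframe = "rows", digits = NA)
    written <- c(written, p)
  }
  invisible(written)
}
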