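#' Build an evenly composed in silico community
#'
#' Draws the same number of cells from each pooled axenic-culture sample,
#' uniformly without replacement, and labels every event with its population
#' of origin. Aggregating separately measured populations this way yields a
#' labelled single-cell training set whose composition is known exactly:
#' with S populations and `n_per_pop` cells each, the community holds
#' `S * n_per_pop` cells at target composition (1/S, ..., 1/S).
#'
#' @param samples List of `population_sample` objects (length >= 2).
#' @param n_per_pop Cells drawn per population (default 5000).
#' @param seed Integer seed; the draw is deterministic given the seed.
#' @param allow_short If `TRUE`, a pool smaller than `n_per_pop` contributes
#'   all of its cells and the achieved composition is recorded; otherwise a
#'   short pool is an error naming the taxon and shortfall.
#' @return An object of class `insilico_community` with fields `populations`,
#'   `events`, `labels` (factor), `target_composition`, `n_per_population`.
#' @export
build_even_community <- function(samples, n_per_pop = 5000L, seed = 1L,
                                 allow_short = FALSE) {
  stopifnot(is.list(samples), length(samples) >= 2L,
            all(vapply(samples, inherits, TRUE, "population_sample")))
  taxa <- vapply(samples, function(s) s$taxon_id, "")
  if (anyDuplicated(taxa)) stop("duplicate taxon ids in samples")
  n_avail <- vapply(samples, cell_count, 0L)
  take <- rep(as.integer(n_per_pop), length(samples))
  short <- which(n_avail < take)
  if (length(short) && !allow_short) {
    i <- short[1L]
    stop("pool for '", taxa[i], "' holds ", n_avail[i], " cells, ",
         take[i] - n_avail[i], " short of n_per_pop = ", take[i],
         " (use allow_short = TRUE to take all available)")
  }
  take[short] <- n_avail[short]
  draws <- with_seed(seed, lapply(seq_along(samples), function(i) {
    sample.int(n_avail[i], take[i], replace = FALSE)
  }))
  parts <- Map(function(s, idx) subset_events(s$pooled, idx), samples, draws)
  events <- bind_events(parts)
  labels <- factor(rep(taxa, take), levels = taxa)
  # achieved composition (= 1/S unless a short pool was allowed)
  target <- take / sum(take)
  new_community(taxa, events, labels, target, take, draw_indices = draws)
}

new_community <- function(taxa, events, labels, target, n_per_pop,
                          draw_indices = NULL) {
  stopifnot(abs(sum(target) - 1) < 1e-9, all(target >= 0), all(target <= 1))
  stopifnot(identical(as.integer(table(labels)[taxa]), as.integer(n_per_pop)))
  structure(list(populations = taxa, events = events, labels = labels,
                 target_composition = stats::setNames(target, taxa),
                 n_per_population = stats::setNames(as.integer(n_per_pop), taxa),
                 draw_indices = draw_indices),
            class = "insilico_community")
}

#' @export
print.insilico_community <- function(x, ...) {
  cat("insilico_community: S = ", length(x$populations), " populations, ",
      n_events(x$events), " labelled cells\n", sep = "")
  comp <- data.frame(taxon = x$populations,
                     n = as.integer(x$n_per_population),
                     target_p = round(unname(x$target_composition), 4))
  print(comp, row.names = FALSE)
  invisible(x)
}

#' Stratified train/test split of a labelled community
#'
#' Splits a community into disjoint training and held-out test sets,
#' stratified by population label: per taxon, `round(fraction_train * n_i)`
#' cells go to training and the rest to test, so the split composition
#' matches the community's within one cell per taxon.
#'
#' @param community An `insilico_community`.
#' @param fraction_train Training fraction, strictly inside (0, 1);
#'   default 0.70.
#' @param seed Integer seed.
#' @return An object of class `split_community` with `train` and `test`
#'   (each a list of `events` and `labels`) and `fraction_train`.
#' @export
split_train_test <- function(community, fraction_train = 0.70, seed = 1L) {
  stopifnot(inherits(community, "insilico_community"))
  if (!is.numeric(fraction_train) || length(fraction_train) != 1L ||
      fraction_train <= 0 || fraction_train >= 1) {
    stop("fraction_train must lie strictly between 0 and 1")
  }
  n <- n_events(community$events)
  if (n < 1L) stop("community is empty")
  labs <- community$labels
  train_idx <- with_seed(seed, {
    unlist(lapply(levels(labs), function(tx) {
      idx <- which(labs == tx)
      n_tr <- as.integer(round(fraction_train * length(idx)))
      n_tr <- max(1L, min(length(idx) - 1L, n_tr))
      sample(idx, n_tr)
    }), use.names = FALSE)
  })
  train_idx <- sort(train_idx)
  is_train <- rep(FALSE, n)
  is_train[train_idx] <- TRUE
  structure(list(
    train = list(events = subset_events(community$events, is_train),
                 labels = labs[is_train]),
    test = list(events = subset_events(community$events, !is_train),
                labels = labs[!is_train]),
    fraction_train = fraction_train
  ), class = "split_community")
}

#' @export
print.split_community <- function(x, ...) {
  cat("split_community: ", n_events(x$train$events), " train / ",
      n_events(x$test$events), " test (fraction_train = ",
      x$fraction_train, ")\n", sep = "")
  invisible(x)
}

#' Default abundance-gradient levels
#'
#' Target relative abundances of the first population along the standard
#' two-population gradient, from 1% to 99%.
#'
#' @return Numeric vector of 13 proportions.
#' @export
gradient_levels <- function() {
  c(0.01, 0.05, 0.10, 0.20, 0.30, 0.40, 0.50, 0.60, 0.70, 0.80, 0.90,
    0.95, 0.99)
}

#' Build a two-population abundance gradient
#'
#' For each target level p1, draws `round(p1 * n_total)` cells of the first
#' population and the remaining `n_total - round(p1 * n_total)` of the
#' second, without replacement and independently across levels, producing one
#' labelled community per level. Rounding is round-half-even on the first
#' taxon with the remainder assigned to the second, so every community
#' contains exactly `n_total` cells.
#'
#' @param sample_a,sample_b `population_sample` objects for the two taxa.
#' @param levels Target p1 values in (0, 1); default [gradient_levels()].
#' @param n_total Cells per community (default 10000).
#' @param seed Integer seed.
#' @param allow_short As in [build_even_community()].
#' @return An object of class `abundance_gradient`: list with `levels`,
#'   `communities` (one `insilico_community` per level) and
#'   `n_total_per_community`.
#' @export
build_gradient <- function(sample_a, sample_b, levels = gradient_levels(),
                           n_total = 10000L, seed = 1L, allow_short = FALSE) {
  stopifnot(inherits(sample_a, "population_sample"),
            inherits(sample_b, "population_sample"))
  if (any(levels < 0 | levels > 1)) {
    stop("gradient levels must lie in [0, 1]")
  }
  communities <- lapply(seq_along(levels), function(k) {
    p1 <- levels[k]
    n1 <- as.integer(round(p1 * n_total))
    n2 <- as.integer(n_total) - n1
    lvl_seed <- derive_seed(seed, "gradient-level", k)
    draw <- function(s, m) {
      avail <- cell_count(s)
      if (avail < m) {
        if (!allow_short) {
          stop("pool for '", s$taxon_id, "' holds ", avail, " cells, ",
               m - avail, " short of the ", m, " required at level ", p1)
        }
        m <- avail
      }
      with_seed(derive_seed(lvl_seed, s$taxon_id),
                subset_events(s$pooled, sample.int(avail, m)))
    }
    ev_a <- draw(sample_a, n1)
    ev_b <- draw(sample_b, n2)
    taxa <- c(sample_a$taxon_id, sample_b$taxon_id)
    n_drawn <- c(n_events(ev_a), n_events(ev_b))
    new_community(taxa, bind_events(ev_a, ev_b),
                  factor(rep(taxa, n_drawn), levels = taxa),
                  c(p1, 1 - p1), n_drawn)
  })
  structure(list(levels = levels, communities = communities,
                 n_total_per_community = as.integer(n_total)),
            class = "abundance_gradient")
}

#' @export
print.abundance_gradient <- function(x, ...) {
  cat("abundance_gradient: ", length(x$levels), " levels (p1 = ",
      paste(x$levels, collapse = ", "), "), ",
      x$n_total_per_community, " cells per community\n", sep = "")
  invisible(x)
}

#' Enumerate or sample communities of a given richness
#'
#' Lists taxon combinations of size S. When the number of combinations
#' C(n, S) does not exceed `max_combinations`, all of them are returned;
#' otherwise a uniform random sample of `max_combinations` distinct
#' combinations is drawn. Each combination is sorted and unique.
#'
#' @param taxa Character vector of taxon ids.
#' @param S Community richness, `2 <= S <= length(taxa)`.
#' @param max_combinations Cap on the number returned (default 150).
#' @param seed Integer seed for the sampled case.
#' @return List of sorted character vectors of length S.
#' @export
enumerate_communities <- function(taxa, S, max_combinations = 150L,
                                  seed = 1L) {
  n <- length(taxa)
  if (S < 2L || S > n) stop("S must satisfy 2 <= S <= length(taxa)")
  taxa <- sort(taxa)
  total <- choose(n, S)
  if (total <= max_combinations) {
    cmb <- utils::combn(taxa, S, simplify = FALSE)
    return(cmb)
  }
  # uniform distinct sample of combinations without materialising them all:
  # draw ranks in the combinatorial number system
  ranks <- with_seed(seed, {
    if (total < .Machine$integer.max) {
      sort(sample.int(as.integer(total), max_combinations))
    } else {
      # rejection sampling of distinct real-valued ranks for huge C(n, S)
      got <- numeric(0)
      while (length(got) < max_combinations) {
        got <- unique(c(got, floor(stats::runif(max_combinations, 0, total)) + 1))
      }
      sort(got[seq_len(max_combinations)])
    }
  })
  lapply(ranks, function(r) taxa[unrank_combination(n, S, r)])
}

# r-th (1-based) S-combination of 1..n in lexicographic order
unrank_combination <- function(n, S, r) {
  out <- integer(S)
  x <- 1L
  r <- r - 1
  for (i in seq_len(S)) {
    repeat {
      c_rest <- choose(n - x, S - i)
      if (r < c_rest) break
      r <- r - c_rest
      x <- x + 1L
    }
    out[i] <- x
    x <- x + 1L
  }
  out
}
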