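#' Hill number of order one (exponential Shannon diversity)
#'
#' `D1 = exp(-sum(p_i * log(p_i)))`, the effective number of equally
#' abundant populations implied by a composition vector: 1 for a single
#' population, S for a perfectly even community of S populations. Zero
#' abundances contribute nothing (`0 * log(0) := 0`).
#'
#' @param p Composition vector: `p_i` in `[0, 1]`, summing to 1 within 1e-9.
#' @return D1, a real in `[1, S]`.
#' @export
hill_d1 <- function(p) {
  check_composition(p)
  pos <- p[p > 0]
  exp(-sum(pos * log(pos)))
}

check_composition <- function(p) {
  if (!is.numeric(p) || length(p) < 1L) stop("p must be a numeric vector")
  if (any(p < 0 | p > 1)) stop("abundances must lie in [0, 1]")
  if (abs(sum(p) - 1) > 1e-9) {
    stop("composition must sum to 1 (got ", format(sum(p)), ")")
  }
  invisible(p)
}

#' Variance of a relative abundance under instrument counting error
#'
#' A relative abundance is a ratio of two flow-cytometric cell counts, each
#' carrying a relative counting error `epsilon_i`; propagating both gives
#' `sigma2_p = 2 * epsilon_i^2 * p^2`.
#'
#' @param p Relative abundance in `[0, 1]`.
#' @param epsilon_i Relative instrumental error of a cell count
#'   (default 0.05, the conventional upper bound for flow cytometry).
#' @return Non-negative variance (vectorised over `p`).
#' @export
var_p <- function(p, epsilon_i = 0.05) {
  stopifnot(all(p >= 0 & p <= 1), epsilon_i >= 0)
  2 * epsilon_i^2 * p^2
}

#' Variance of the Hill diversity D1 under instrument counting error
#'
#' First-order (delta-method) propagation of the per-abundance variances
#' into D1: `sigma2_D1 = D1^2 * sum((log(p_i) + 1)^2 * sigma2_p_i)`, with
#' the i-th term taken as 0 when `p_i = 0` (its limit). Abundances are
#' treated as independently measured, which is what makes the variances
#' combine additively. For S = 2 this reduces to the closed form computed by
#' [var_d1_binary()].
#'
#' @inheritParams hill_d1
#' @param epsilon_i Relative instrumental counting error (default 0.05).
#' @return Non-negative variance of D1.
#' @export
var_d1 <- function(p, epsilon_i = 0.05) {
  check_composition(p)
  stopifnot(epsilon_i >= 0)
  d1 <- hill_d1(p)
  pos <- p[p > 0]
  d1^2 * sum((log(pos) + 1)^2 * var_p(pos, epsilon_i))
}

#' Binary closed form of the D1 variance
#'
#' For a two-population community with first abundance `p1` (and
#' `p2 = 1 - p1`):
#' `sigma2_D1 = 2 * eps^2 * D1^2 * (p1^2 (log(p1)+1)^2 +
#'  (1-p1)^2 (log(1-p1)+1)^2)`.
#' Agrees with the general formula of [var_d1()] to machine precision.
#'
#' @param p1 Abundance of the first population, in `[0, 1]` (vectorised).
#' @param epsilon_i Relative instrumental counting error (default 0.05).
#' @return Non-negative variance of D1.
#' @export
var_d1_binary <- function(p1, epsilon_i = 0.05) {
  stopifnot(all(p1 >= 0 & p1 <= 1), epsilon_i >= 0)
  p2 <- 1 - p1
  d1 <- vapply(seq_along(p1),
               function(i) hill_d1(c(p1[i], p2[i])), 0)
  t1 <- ifelse(p1 > 0, p1^2 * (log(p1) + 1)^2, 0)
  t2 <- ifelse(p2 > 0, p2^2 * (log(p2) + 1)^2, 0)
  2 * epsilon_i^2 * d1^2 * (t1 + t2)
}

#' Hill diversity with propagated confidence intervals
#'
#' Computes D1 and, assuming approximate normality of the propagated error,
#' central confidence intervals: 68% as `D1 +/- 1.0 * sigma_D1` and 95% as
#' `D1 +/- 1.96 * sigma_D1`. With `epsilon_i = 0` both intervals collapse to
#' the point estimate.
#'
#' @inheritParams var_d1
#' @return An object of class `diversity_estimate` with fields `d1`,
#'   `var_d1`, `ci68`, `ci95` and `epsilon_i`.
#' @export
d1_with_ci <- function(p, epsilon_i = 0.05) {
  d1 <- hill_d1(p)
  v <- var_d1(p, epsilon_i)
  s <- sqrt(v)
  structure(list(d1 = d1, var_d1 = v,
                 ci68 = c(lo = d1 - s, hi = d1 + s),
                 ci95 = c(lo = d1 - 1.96 * s, hi = d1 + 1.96 * s),
                 epsilon_i = epsilon_i),
            class = "diversity_estimate")
}

#' @export
print.diversity_estimate <- function(x, ...) {
  cat("diversity_estimate: D1 = ", round(x$d1, 4),
      " (sigma = ", signif(sqrt(x$var_d1), 4), ", epsilon_i = ",
      x$epsilon_i, ")\n", sep = "")
  cat("  68% CI: [", round(x$ci68[1L], 4), ", ", round(x$ci68[2L], 4),
      "]\n  95% CI: [", round(x$ci95[1L], 4), ", ", round(x$ci95[2L], 4),
      "]\n", sep = "")
  invisible(x)
}

#' Monte-Carlo check of the propagated D1 interval
#'
#' Simulates the instrument-noise model under which the variance propagation
#' is derived: every abundance is a ratio of two cell counts, and the two
#' counts behind each abundance are perturbed by independent multiplicative
#' Gaussian noise with relative SD `epsilon_i` (independently across
#' populations, which is what lets the variances add). D1 is recomputed
#' from the perturbed abundances and the fraction of draws falling inside
#' the propagated interval is returned.
#'
#' @inheritParams var_d1
#' @param n_draws Number of Monte-Carlo draws (default 10000).
#' @param level `0.95` or `0.68`, selecting which interval to check.
#' @param seed Integer seed.
#' @return Empirical coverage, a proportion.
#' @export
d1_coverage_mc <- function(p, epsilon_i = 0.05, n_draws = 10000L,
                           level = 0.95, seed = 1L) {
  check_composition(p)
  stopifnot(level %in% c(0.68, 0.95))
  est <- d1_with_ci(p, epsilon_i)
  ci <- if (level == 0.95) est$ci95 else est$ci68
  # p_i_hat = p_i (1 + eps z_num) / (1 + eps z_den): numerator and
  # denominator counts of each abundance ratio erred independently
  draws <- with_seed(seed, {
    z_num <- matrix(stats::rnorm(n_draws * length(p)), n_draws)
    z_den <- matrix(stats::rnorm(n_draws * length(p)), n_draws)
    ratio <- (1 + epsilon_i * z_num) / (1 + epsilon_i * z_den)
    ph <- sweep(ratio, 2L, p, `*`)
    ph[ph <= 0] <- .Machine$double.eps
    apply(ph, 1L, function(q) exp(-sum(q * log(q))))
  })
  mean(draws >= ci[["lo"]] & draws <= ci[["hi"]])
}
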