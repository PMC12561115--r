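#' One-sided permutation test for a difference in group means
#'
#' Tests whether group `b` has a larger (alternative `"greater"`) or smaller
#' (`"less"`) mean than group `a`, using the difference of group means
#' `mean(b) - mean(a)` as the statistic. When the number of distinct label
#' assignments `choose(n_a + n_b, n_a)` is at most `exhaustive_limit`, all
#' assignments are enumerated and the p-value is exact (the proportion of
#' assignments whose statistic is at least as extreme as observed, the
#' observed split included). Otherwise a seeded Monte-Carlo test with `B`
#' random permutations is used with the add-one estimator
#' `p = (1 + #extreme) / (1 + B)`, which never returns exactly zero.
#'
#' @param group_a,group_b Numeric vectors with at least 2 observations each.
#' @param alternative `"greater"` (mean of `b` exceeds mean of `a`) or
#'   `"less"`.
#' @param B Monte-Carlo iterations (>= 1).
#' @param seed Integer seed for the Monte-Carlo path.
#' @param exhaustive_limit Enumerate exactly when the number of assignments
#'   does not exceed this.
#' @return List (class `permutation_test`) with `p_value`, `statistic`,
#'   `alternative`, `exact` (logical) and `B`.
#' @examples
#' permutation_test(c(1, 2), c(3, 4))$p_value # exact: 1/6
#' @export
permutation_test <- function(group_a, group_b,
                             alternative = c("greater", "less"),
                             B = 1000, seed = 0,
                             exhaustive_limit = 10000) {
  alternative <- match.arg(alternative)
  if (length(group_a) < 2 || length(group_b) < 2)
    stopf("each group needs at least 2 observations",
          class = "anomrecon_insufficient_data")
  if (B < 1) stopf("`B` must be >= 1", class = "anomrecon_config_error")
  na <- length(group_a); nb <- length(group_b)
  pooled <- c(group_a, group_b)
  obs <- mean(group_b) - mean(group_a)
  total <- choose(na + nb, na)
  # tolerance for ties in the permuted statistic (floating-point equality)
  eps <- 1e-9 * (max(abs(pooled)) + 1)
  extreme <- function(stat) {
    if (alternative == "greater") stat >= obs - eps else stat <= obs + eps
  }
  if (total <= exhaustive_limit) {
    S <- sum(pooled)
    idx <- utils::combn(na + nb, na)
    sums_a <- colSums(matrix(pooled[idx], nrow = na))
    stats_perm <- (S - sums_a) / nb - sums_a / na
    p <- mean(extreme(stats_perm))
    exact <- TRUE
  } else {
    stats_perm <- with_seed(seed, vapply(seq_len(B), function(i) {
      ia <- sample.int(na + nb, na)
      sa <- sum(pooled[ia])
      (sum(pooled) - sa) / nb - sa / na
    }, numeric(1)))
    p <- (1 + sum(extreme(stats_perm))) / (1 + B)
    exact <- FALSE
  }
  structure(list(p_value = p, statistic = obs, alternative = alternative,
                 exact = exact, B = if (exact) NA_integer_ else B),
            class = "permutation_test")
}

#' @export
print.permutation_test <- function(x, ...) {
  cat(sprintf("<permutation_test> statistic %.4g, one-sided (%s) p = %.4g (%s)\n",
              x$statistic, x$alternative, x$p_value,
              if (x$exact) "exact enumeration"
              else sprintf("Monte-Carlo, B = %d", x$B)))
  invisible(x)
}

#' Simulation-based power of the one-sided permutation test
#'
#' Estimates statistical power for comparing two groups by simulation:
#' repeatedly draw `n` observations per group from normal distributions with
#' the specified means and SDs, run the one-sided permutation test
#' (alternative: `mean_b > mean_a` when `mean_b >= mean_a`, else the
#' mirrored side), and report the fraction of simulations with `p < alpha`.
#'
#' @param mean_a,sd_a,mean_b,sd_b Group means and SDs of the generating
#'   normal distributions.
#' @param n Per-group sample size.
#' @param sims Number of simulated datasets.
#' @param alpha Significance level in (0, 1).
#' @param B Permutation iterations per simulated dataset.
#' @param seed Integer seed; identical seeds give identical results.
#' @return List (class `power_result`) with `power`, `sims`, `n`, `alpha`
#'   and the generating parameters.
#' @examples
#' power_simulation(0.35, 0.03, 0.70, 0.03, n = 5, sims = 50, seed = 1)$power
#' @export
power_simulation <- function(mean_a, sd_a, mean_b, sd_b, n, sims = 1000,
                             alpha = 0.05, B = 1000, seed = 0) {
  stopifnot(sd_a >= 0, sd_b >= 0, n >= 2, sims >= 1, alpha > 0, alpha < 1)
  alternative <- if (mean_b >= mean_a) "greater" else "less"
  sim_seeds <- with_seed(seed, sample.int(2147483646L, sims))
  rejections <- vapply(seq_len(sims), function(i) {
    dat <- with_seed(sim_seeds[i], list(
      a = stats::rnorm(n, mean_a, sd_a),
      b = stats::rnorm(n, mean_b, sd_b)))
    pt <- permutation_test(dat$a, dat$b, alternative = alternative, B = B,
                           seed = sim_seeds[i])
    pt$p_value < alpha
  }, logical(1))
  structure(list(power = mean(rejections), sims = sims, n = n, alpha = alpha,
                 B = B,
                 groups = list(a = c(mean = mean_a, sd = sd_a),
                               b = c(mean = mean_b, sd = sd_b))),
            class = "power_result")
}

#' @export
print.power_result <- function(x, ...) {
  cat(sprintf("<power_result> power %.3f (n = %d per group, %d sims, alpha = %g)\n",
              x$power, x$n, x$sims, x$alpha))
  invisible(x)
}
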