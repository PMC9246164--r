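# Bootstrap hypothesis-testing machinery.
#
# Significance throughout the package follows a mean-shift bootstrap: the
# observed sample is shifted so that its mean equals the null mean, the
# shifted sample is resampled with replacement n_boot times, and the
# p-value is the (add-one corrected) fraction of bootstrap means at least
# as extreme as the observed mean. Multiple comparisons use Bonferroni
# correction only.

#' Mean-shift bootstrap hypothesis test
#'
#' Shifts the sample so its mean equals `h0_mean` (creating a synthetic
#' null distribution), draws `n_boot` resamples of the original size with
#' replacement, and reports
#' `p = (1 + #(bootstrap means as-or-more extreme than observed)) / (n_boot + 1)`.
#' The add-one correction keeps p strictly above zero, with a floor of
#' `1 / (n_boot + 1)`.
#'
#' @param sample Numeric vector, length >= 2.
#' @param h0_mean Null-hypothesis mean (0 for Shapley contributions; the
#'   intact mean for lesion-score distributions).
#' @param n_boot Number of bootstrap resamples (study default 10000).
#' @param side `"two_sided"` (default), `"greater"` or `"less"`.
#' @param seed Integer seed.
#' @return A `bootstrap_result` list: `p_value`, `observed_mean`,
#'   `h0_mean`, `n_boot`, `side`, and `degenerate` (TRUE when the sample
#'   has zero variance and equals the null, in which case p = 1).
#' @export
bootstrap_p <- function(sample, h0_mean, n_boot = 10000L,
                        side = c("two_sided", "greater", "less"), seed = 1L) {
  side <- match.arg(side)
  stopifnot(is.numeric(sample), length(sample) >= 2, is.finite(h0_mean))
  obs <- mean(sample)
  degenerate <- stats::sd(sample) == 0 && obs == h0_mean
  if (degenerate) {
    return(structure(list(p_value = 1, observed_mean = obs, h0_mean = h0_mean,
                          n_boot = as.integer(n_boot), side = side,
                          degenerate = TRUE),
                     class = "bootstrap_result"))
  }
  null_sample <- sample - obs + h0_mean
  n <- length(sample)
  boot_means <- with_seed(seed, {
    colMeans(matrix(base::sample(null_sample, n * n_boot, replace = TRUE),
                    nrow = n, ncol = n_boot))
  })
  extreme <- switch(side,
    two_sided = abs(boot_means - h0_mean) >= abs(obs - h0_mean),
    greater   = boot_means >= obs,
    less      = boot_means <= obs
  )
  structure(
    list(p_value = (1 + sum(extreme)) / (n_boot + 1), observed_mean = obs,
         h0_mean = h0_mean, n_boot = as.integer(n_boot), side = side,
         degenerate = FALSE),
    class = "bootstrap_result"
  )
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("<bootstrap test (%s): observed mean %.4g vs H0 mean %.4g, p = %.4g (%d resamples)>\n",
              x$side, x$observed_mean, x$h0_mean, x$p_value, x$n_boot))
  invisible(x)
}

#' Bonferroni-corrected significance level
#'
#' @param alpha Family-wise significance level (default 0.05).
#' @param n_tests Number of tests in the family; at least 1.
#' @return `alpha / n_tests`.
#' @examples
#' bonferroni_alpha(0.05, 51) # 51 connection-wise tests
#' @export
bonferroni_alpha <- function(alpha = 0.05, n_tests) {
  if (n_tests < 1) stop("n_tests must be at least 1")
  alpha / n_tests
}

#' Percentile bootstrap confidence interval of the mean
#'
#' @param sample Numeric vector, length >= 2 (constant samples return a
#'   zero-width interval).
#' @param level Coverage (default 0.95).
#' @param n_boot Bootstrap resamples (default 10000).
#' @param seed Integer seed.
#' @return Numeric `(low, high)`.
#' @export
percentile_ci <- function(sample, level = 0.95, n_boot = 10000L, seed = 1L) {
  stopifnot(is.numeric(sample), length(sample) >= 2, level > 0, level < 1)
  if (stats::sd(sample) == 0) return(c(sample[1], sample[1]))
  n <- length(sample)
  boot_means <- with_seed(seed, {
    colMeans(matrix(base::sample(sample, n * n_boot, replace = TRUE),
                    nrow = n, ncol = n_boot))
  })
  unname(stats::quantile(boot_means, c((1 - level) / 2, (1 + level) / 2)))
}

#' Two-sided Mann-Whitney U test
#'
#' Standard rank-sum comparison with tie correction, used for
#' intact-versus-control score comparisons. Thin wrapper around
#' [stats::wilcox.test()]; the reported `U` is the statistic for
#' `sample_a`.
#'
#' @param sample_a,sample_b Non-empty numeric vectors.
#' @return List with `U` and two-sided `p`.
#' @export
ranksum <- function(sample_a, sample_b) {
  stopifnot(length(sample_a) >= 1, length(sample_b) >= 1)
  wt <- suppressWarnings(stats::wilcox.test(sample_a, sample_b, exact = FALSE,
                                            correct = TRUE))
  list(U = unname(wt$statistic), p = wt$p.value)
}

#' Per-element significance report
#'
#' Applies the mean-shift bootstrap test to each element's sample against a
#' shared null mean and flags significance at the Bonferroni-corrected
#' level `alpha / n_tests`.
#'
#' @param samples Named list of numeric vectors (one per element).
#' @param h0_mean Null mean shared by all tests.
#' @param alpha Family-wise level (default 0.05).
#' @param n_boot Bootstrap resamples per test.
#' @param side Test sidedness (default two-sided).
#' @param seed Integer seed.
#' @return A `test_report` data.frame: element, statistic (observed mean),
#'   p, corrected_alpha, significant.
#' @export
significance_report <- function(samples, h0_mean, alpha = 0.05,
                                n_boot = 10000L, side = "two_sided", seed = 1L) {
  stopifnot(is.list(samples), !is.null(names(samples)))
  corrected <- bonferroni_alpha(alpha, length(samples))
  rows <- lapply(names(samples), function(el) {
    bt <- bootstrap_p(samples[[el]], h0_mean, n_boot = n_boot, side = side,
                      seed = derive_seed(seed, "sig", el))
    data.frame(element = el, statistic = bt$observed_mean, p = bt$p_value,
               corrected_alpha = corrected, significant = bt$p_value < corrected,
               stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, rows), class = c("test_report", "data.frame"))
}

#' Significance of SPA effects against the intact performance
#'
#' Tests each element's lesioned score distribution against the intact
#' mean (the null being "this lesion leaves performance at the intact
#' level").
#'
#' @param spa_result An [spa()] result.
#' @inheritParams significance_report
#' @return A `test_report` data.frame.
#' @export
spa_significance <- function(spa_result, alpha = 0.05, n_boot = 10000L, seed = 1L) {
  stopifnot(inherits(spa_result, "spa_result"))
  significance_report(attr(spa_result, "distributions"),
                      h0_mean = mean(attr(spa_result, "intact")),
                      alpha = alpha, n_boot = n_boot, seed = seed)
}

#' Significance of Shapley values against a zero-centred null
#'
#' Tests each element's per-permutation contribution samples against a
#' null mean of 0 (a Shapley value of zero is the null player).
#'
#' @param shapley_tbl A sampled `shapley_table`.
#' @inheritParams significance_report
#' @return A `test_report` data.frame.
#' @export
shapley_significance <- function(shapley_tbl, alpha = 0.05, n_boot = 10000L, seed = 1L) {
  contrib <- attr(shapley_tbl, "contributions")
  if (!is.matrix(contrib)) {
    stop("shapley significance needs per-permutation contributions (sampled_shapley)")
  }
  samples <- lapply(colnames(contrib), function(el) contrib[, el])
  names(samples) <- colnames(contrib)
  significance_report(samples, h0_mean = 0, alpha = alpha, n_boot = n_boot,
                      seed = seed)
}
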