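# Poisson-Gamma model of the relative mutation rate R = lambda1/lambda2.
#
# Per-position counts Y_i in the modification region are Poisson(lambda1),
# background counts Poisson(lambda2), with Gamma priors on both rates.
# Conjugacy gives closed-form Gamma posteriors; the test reports the
# posterior probability of the null H0: R <= 1.

#' Gamma prior on a Poisson rate (shape-rate parametrization)
#'
#' The default `(0.001, 0.001)` is weakly informative: with any appreciable
#' number of observed positions the data dominate. Under shape-rate,
#' `mean = shape / rate`.
#'
#' @param shape,rate Strictly positive finite numerics.
#' @return Object of class `gamma_dist`.
#' @export
gamma_prior <- function(shape = 0.001, rate = 0.001) {
  stopifnot(is.finite(shape), is.finite(rate), shape > 0, rate > 0)
  structure(list(shape = shape, rate = rate), class = "gamma_dist")
}

#' @export
print.gamma_dist <- function(x, ...) {
  cat(sprintf("Gamma(shape = %g, rate = %g), mean %.4g\n",
              x$shape, x$rate, x$shape / x$rate))
  invisible(x)
}

#' Conjugate posterior update for per-position Poisson counts
#'
#' With counts \eqn{Y_1..Y_m \sim Poisson(\lambda)} and prior
#' \eqn{\lambda \sim Gamma(\alpha, \beta)} (shape-rate), the posterior is
#' \eqn{Gamma(\alpha + \sum Y_i,\ \beta + m)}.
#'
#' @param prior A `gamma_dist` prior.
#' @param counts Non-negative integer vector of per-position counts; must be
#'   non-empty (a region with no positions is untestable).
#' @return The posterior as a `gamma_dist`.
#' @examples
#' posterior_update(gamma_prior(1, 1), c(2, 0, 1))  # Gamma(4, 4)
#' @export
posterior_update <- function(prior, counts) {
  stopifnot(inherits(prior, "gamma_dist"))
  if (length(counts) == 0) stop("empty count vector: region untestable")
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  gamma_prior(shape = prior$shape + sum(counts),
              rate = prior$rate + length(counts))
}

#' Exact posterior probability of the null, P(lambda1 <= lambda2 | Y)
#'
#' For independent posteriors \eqn{\lambda_1 \sim Gamma(a_1, b_1)} and
#' \eqn{\lambda_2 \sim Gamma(a_2, b_2)},
#' \deqn{P(\lambda_1 \le \lambda_2) = I_x(a_1, a_2), \quad x = b_1/(b_1+b_2),}
#' the regularized incomplete beta function (because
#' \eqn{b_1\lambda_1 / (b_1\lambda_1 + b_2\lambda_2) \sim Beta(a_1, a_2)}).
#' This is the deterministic reference path for the Monte-Carlo estimate.
#'
#' @param post_mod,post_bg `gamma_dist` posteriors for the modification and
#'   background rates.
#' @return The posterior null probability, used as the one-sided p-value.
#' @examples
#' p_value_exact(gamma_prior(2, 1), gamma_prior(1, 1))  # 0.25
#' @export
p_value_exact <- function(post_mod, post_bg) {
  stopifnot(inherits(post_mod, "gamma_dist"), inherits(post_bg, "gamma_dist"))
  x <- post_mod$rate / (post_mod$rate + post_bg$rate)
  stats::pbeta(x, post_mod$shape, post_bg$shape)
}

#' Monte-Carlo posterior probability of the null
#'
#' Estimates \eqn{P(R \le 1 | Y)} with \eqn{R = \lambda_1/\lambda_2} by paired
#' sampling from the two conjugate posteriors. Because the posteriors are
#' available in closed form the draws are exact and independent; the
#' `burn_in` leading draws are nonetheless discarded, matching the
#' conventional iterations/burn-in interface of MCMC samplers.
#'
#' @param post_mod,post_bg `gamma_dist` posteriors.
#' @param iterations Total draws (default 10000); must exceed `burn_in`.
#' @param burn_in Leading draws to discard (default 1000).
#' @param seed Optional integer seed for reproducibility.
#' @return List with `p_value` (fraction of retained draws with
#'   \eqn{\lambda_1 \le \lambda_2}), `r_mean` (draw-wise mean of
#'   \eqn{\lambda_1/\lambda_2}), and `n_draws` retained.
#' @export
p_value_mc <- function(post_mod, post_bg, iterations = 10000L,
                       burn_in = 1000L, seed = NULL) {
  stopifnot(inherits(post_mod, "gamma_dist"), inherits(post_bg, "gamma_dist"))
  if (burn_in < 0) stop("burn_in must be >= 0")
  if (iterations <= burn_in) stop("iterations must exceed burn_in")
  if (!is.null(seed)) set.seed(seed)
  l1 <- stats::rgamma(iterations, shape = post_mod$shape, rate = post_mod$rate)
  l2 <- stats::rgamma(iterations, shape = post_bg$shape, rate = post_bg$rate)
  keep <- seq.int(burn_in + 1L, iterations)
  l1 <- l1[keep]; l2 <- l2[keep]
  list(p_value = mean(l1 <= l2), r_mean = mean(l1 / l2),
       n_draws = length(keep))
}

#' Posterior mean of the relative rate R = lambda1/lambda2
#'
#' Analytic form for independent Gamma posteriors:
#' \eqn{E[R] = E[\lambda_1] E[1/\lambda_2] = a_1 b_2 / (b_1 (a_2 - 1))},
#' finite only when the background shape exceeds 1 (Inf otherwise).
#'
#' @param post_mod,post_bg `gamma_dist` posteriors.
#' @return Numeric posterior mean of R (possibly `Inf`).
#' @export
posterior_r_mean <- function(post_mod, post_bg) {
  if (post_bg$shape <= 1) return(Inf)
  (post_mod$shape * post_bg$rate) / (post_mod$rate * (post_bg$shape - 1))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up FDR adjustment (via [stats::p.adjust()]), returned in the
#' original input order. Inputs outside `[0, 1]` are an error.
#'
#' @param p_values Numeric vector of p-values.
#' @return Adjusted q-values in `[0, 1]`, same length and order.
#' @export
bh_adjust <- function(p_values) {
  if (length(p_values) == 0) return(numeric(0))
  if (any(is.na(p_values)) || any(p_values < 0) || any(p_values > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Test one protein for modification-region mutation enrichment
#'
#' Updates the two Gamma priors with the regional count vectors and computes
#' the posterior probability of H0: R <= 1. `method = "exact"` (default) uses
#' the incomplete-beta closed form and the analytic posterior mean of R;
#' `method = "mc"` uses paired posterior sampling, honoring
#' `iterations`/`burn_in`/`seed`.
#'
#' @param partition A `region_partition` with non-empty background
#'   (`k < n`); a fully covered protein is untestable.
#' @param counts Matching `count_vector` from [count_by_position()].
#' @param prior_mod,prior_bg Gamma priors for the two rates.
#' @param method `"exact"` or `"mc"`.
#' @param iterations,burn_in,seed Monte-Carlo settings (`method = "mc"`).
#' @return One-row data.frame: accession, ptm_type, k, n, mod_mutations,
#'   bg_mutations, r_mean, p_value.
#' @export
test_protein <- function(partition, counts,
                         prior_mod = gamma_prior(), prior_bg = gamma_prior(),
                         method = c("exact", "mc"),
                         iterations = 10000L, burn_in = 1000L, seed = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(partition, "region_partition"), inherits(counts, "count_vector"))
  if (partition$k == 0) stop("empty modification region: protein untestable")
  if (partition$k == partition$n) {
    stop("no background region (k = n): protein untestable")
  }
  post_mod <- posterior_update(prior_mod, counts$mod_counts)
  post_bg <- posterior_update(prior_bg, counts$bg_counts)
  if (method == "exact") {
    p <- p_value_exact(post_mod, post_bg)
    r_mean <- posterior_r_mean(post_mod, post_bg)
  } else {
    mc <- p_value_mc(post_mod, post_bg, iterations = iterations,
                     burn_in = burn_in, seed = seed)
    p <- mc$p_value
    r_mean <- mc$r_mean
  }
  data.frame(
    accession = partition$accession, ptm_type = partition$ptm_type,
    k = partition$k, n = partition$n,
    mod_mutations = counts$mod_total, bg_mutations = counts$bg_total,
    r_mean = r_mean, p_value = p,
    stringsAsFactors = FALSE
  )
}

#' Apply FDR correction across a run and flag drivers
#'
#' Assigns BH q-values over all tested proteins of one run (one cohort, one
#' PTM type — the multiple-testing family), flags drivers by the strict
#' comparison `q_value < q_threshold`, and sorts by q, then p, then accession
#' for deterministic output.
#'
#' @param results Data.frame of rows from [test_protein()].
#' @param q_threshold Significance level on the q-value (default 0.05).
#' @return The results with `q_value` and `is_driver` columns, sorted.
#' @export
call_drivers <- function(results, q_threshold = 0.05) {
  if (is.null(results) || nrow(results) == 0) {
    out <- data.frame(accession = character(), ptm_type = character(),
                      k = integer(), n = integer(), mod_mutations = integer(),
                      bg_mutations = integer(), r_mean = numeric(),
                      p_value = numeric(), q_value = numeric(),
                      is_driver = logical(), stringsAsFactors = FALSE)
    return(out)
  }
  if (q_threshold <= 0 || q_threshold > 1) stop("q_threshold must be in (0, 1]")
  results$q_value <- bh_adjust(results$p_value)
  results$is_driver <- results$q_value < q_threshold
  ord <- order(results$q_value, results$p_value, results$accession)
  results <- results[ord, , drop = FALSE]
  rownames(results) <- NULL
  results
}
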