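test_that("conjugate update adds counts to shape and positions to rate", {
  post <- posterior_update(gamma_prior(1, 1), c(2, 0, 1))
  expect_equal(c(post$shape, post$rate), c(4, 4))

  post2 <- posterior_update(gamma_prior(0.001, 0.001), rep(0, 10))
  expect_equal(c(post2$shape, post2$rate), c(0.001, 10.001))

  post3 <- posterior_update(gamma_prior(2, 3), 5)
  expect_equal(c(post3$shape, post3$rate), c(7, 4))

  expect_error(posterior_update(gamma_prior(), integer(0)), "untestable")
  expect_error(posterior_update(gamma_prior(), c(1, -1)), "non-negative")
  expect_error(gamma_prior(0, 1))
})

test_that("exact null probability is the regularized incomplete beta", {
  expect_equal(p_value_exact(gamma_prior(1, 1), gamma_prior(1, 1)), 0.5)
  expect_equal(p_value_exact(gamma_prior(2, 1), gamma_prior(1, 1)), 0.25)
  # complementarity: swapping the posteriors flips the probability
  a <- gamma_prior(3, 2); b <- gamma_prior(2, 5)
  expect_equal(p_value_exact(a, b) + p_value_exact(b, a), 1)
})

test_that("Monte-Carlo estimator agrees with the closed form", {
  a <- gamma_prior(3, 2); b <- gamma_prior(2, 5)
  p_ex <- p_value_exact(a, b)
  mc <- p_value_mc(a, b, iterations = 1e5, burn_in = 0, seed = 99)
  se <- sqrt(p_ex * (1 - p_ex) / mc$n_draws)
  expect_lt(abs(mc$p_value - p_ex), 3 * se)

  sym <- p_value_mc(gamma_prior(4, 4), gamma_prior(4, 4),
                    iterations = 2e4, burn_in = 0, seed = 1)
  expect_lt(abs(sym$p_value - 0.5), 3 * sqrt(0.25 / 2e4))

  strong <- p_value_mc(gamma_prior(50, 1), gamma_prior(1, 1),
                       iterations = 2e4, burn_in = 0, seed = 1)
  expect_lt(strong$p_value, 1e-3)
  expect_lt(p_value_exact(gamma_prior(50, 1), gamma_prior(1, 1)), 1e-6)

  # burn-in discards leading draws; fixed seed reproduces exactly
  m1 <- p_value_mc(a, b, iterations = 5000, burn_in = 1000, seed = 7)
  m2 <- p_value_mc(a, b, iterations = 5000, burn_in = 1000, seed = 7)
  expect_identical(m1, m2)
  expect_equal(m1$n_draws, 4000)
  expect_error(p_value_mc(a, b, iterations = 100, burn_in = 100), "exceed")
})

test_that("analytic posterior mean of R matches draw-wise mean", {
  a <- gamma_prior(12, 20); b <- gamma_prior(30, 90)
  r_exact <- posterior_r_mean(a, b)
  mc <- p_value_mc(a, b, iterations = 2e5, burn_in = 0, seed = 3)
  expect_lt(abs(mc$r_mean - r_exact) / r_exact, 0.05)
  expect_equal(posterior_r_mean(gamma_prior(1, 1), gamma_prior(0.5, 1)), Inf)
})

test_that("BH adjustment matches an independent step-up implementation", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.5), 0.5)
  expect_equal(bh_adjust(c(0, 1)), c(0, 1))
  set.seed(21)
  for (i in 1:100) {
    p <- runif(sample(1:30, 1))
    expect_equal(bh_adjust(p), bh_oracle(p))
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("protein-level test points in the right direction", {
  part <- make_partition(100, 10)          # k = 15, bg = 85
  # depletion: all mutations in the background
  recs_bg <- do.call(rbind, lapply(sample(c(30:45, 60:80), 10),
                                   function(p) mut_row("S1", "P1", p)))
  res_dep <- test_protein(part, count_by_position(part, recs_bg))
  expect_gt(res_dep$p_value, 0.5)

  # enrichment: 10 mutations inside the 15-residue region, none outside
  recs_mod <- do.call(rbind, lapply(rep(c(5, 10, 15), c(4, 3, 3)),
                                    function(p) mut_row("S1", "P1", p)))
  res_enr <- test_protein(part, count_by_position(part, recs_mod))
  expect_lt(res_enr$p_value, 0.01)
  expect_gt(res_enr$r_mean, 1)
  expect_equal(res_enr$mod_mutations, 10)
  expect_equal(res_enr$bg_mutations, 0)

  # symmetry: equal-size regions with identical counts
  part_sym <- make_partition(30, 8)        # k = 15, bg = 15
  recs_sym <- rbind(mut_row("S1", "P1", 8), mut_row("S1", "P1", 25))
  res_sym <- test_protein(part_sym, count_by_position(part_sym, recs_sym))
  expect_equal(res_sym$p_value, 0.5)

  expect_error(test_protein(make_partition(15, 8),
                            count_by_position(make_partition(15, 8),
                                              mut_row("S1", "P1", 1))),
               "no background")
})

test_that("weak priors wash out once both regions carry appreciable counts", {
  part <- make_partition(300, c(50, 150))
  set.seed(8)
  recs <- do.call(rbind, lapply(sample(300, 300, replace = TRUE),
                                function(p) mut_row("S1", "P1", p)))
  cv <- count_by_position(part, recs)
  p_weak <- test_protein(part, cv)$p_value
  p_unit <- test_protein(part, cv, prior_mod = gamma_prior(1, 1),
                         prior_bg = gamma_prior(1, 1))$p_value
  expect_lt(abs(p_weak - p_unit), 0.01)
})

test_that("driver calling applies BH within the run and sorts deterministically", {
  res1 <- data.frame(accession = "P1", ptm_type = "Phosphorylation",
                     k = 15L, n = 100L, mod_mutations = 5L, bg_mutations = 1L,
                     r_mean = 3, p_value = 0.01, stringsAsFactors = FALSE)
  out1 <- call_drivers(res1)
  expect_equal(out1$q_value, 0.01)
  expect_true(out1$is_driver)

  res2 <- rbind(res1, transform(res1, accession = "P2", p_value = 0.9))
  res2$p_value <- c(0.03, 0.9)
  out2 <- call_drivers(res2)
  expect_equal(out2$q_value, c(0.06, 0.9))
  expect_false(any(out2$is_driver))
  expect_true(all(call_drivers(res2, q_threshold = 1)$is_driver))

  expect_equal(nrow(call_drivers(NULL)), 0)
})
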