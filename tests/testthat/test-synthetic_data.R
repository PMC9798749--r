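test_that("latent scores are deterministic, independent across columns, and reject bad icc", {
  spec <- generative_spec(n_subjects = 10000, n_specific = 2,
                          loading_general = rep(0.6, 6),
                          loading_specific = rep(0.4, 6),
                          item_factor = rep(1:2, each = 3),
                          icc_family = 0, seed = 3L)
  lat1 <- simulate_latent_scores(spec)
  lat2 <- simulate_latent_scores(spec)
  expect_identical(lat1, lat2)

  spec_b <- generative_spec(n_subjects = 10000, n_specific = 2,
                            loading_general = rep(0.6, 6),
                            loading_specific = rep(0.4, 6),
                            item_factor = rep(1:2, each = 3),
                            icc_family = 0, seed = 4L)
  expect_false(identical(simulate_latent_scores(spec_b), lat1))

  C <- cor(lat1[, c("general", "specific1", "specific2")])
  expect_lt(max(abs(C[upper.tri(C)])), 0.05)

  expect_error(generative_spec(n_subjects = 10, n_specific = 1,
                               loading_general = 0.6, loading_specific = 0.4,
                               item_factor = 1, icc_family = 1.2),
               "icc_family")
})

test_that("family clustering plants the requested intra-family correlation", {
  spec <- generative_spec(n_subjects = 20000, n_specific = 1,
                          loading_general = rep(0.6, 4),
                          loading_specific = rep(0.4, 4),
                          item_factor = rep(1, 4),
                          cluster_sizes = rep(2L, 10000),
                          icc_family = 0.5, seed = 9L)
  lat <- simulate_latent_scores(spec)
  g <- matrix(lat$general, nrow = 2)   # columns are families of two
  expect_lt(abs(cor(g[1, ], g[2, ]) - 0.5), 0.03)
})

test_that("item responses follow the planted measurement model", {
  # symmetric binary threshold -> half the mass in category 1
  spec <- generative_spec(n_subjects = 20000, n_specific = 1,
                          loading_general = rep(0.6, 2),
                          loading_specific = rep(0.4, 2),
                          item_factor = c(1, 1),
                          item_levels = c("binary", "binary"),
                          thresholds = list(0, 0), seed = 5L)
  items <- simulate_item_responses(simulate_latent_scores(spec), spec)
  expect_equal(mean(items[[1]]), 0.5, tolerance = 0.02)

  # null loadings: items unrelated to the latent scores
  spec0 <- generative_spec(n_subjects = 10000, n_specific = 1,
                           loading_general = rep(0, 3),
                           loading_specific = rep(0, 3),
                           item_factor = rep(1, 3), seed = 6L)
  lat0 <- simulate_latent_scores(spec0)
  it0 <- simulate_item_responses(lat0, spec0)
  expect_lt(max(abs(cor(it0, lat0[, c("general", "specific1")]))), 0.03)

  # non-increasing thresholds rejected
  expect_error(generative_spec(n_subjects = 10, n_specific = 1,
                               loading_general = 0.5, loading_specific = 0.3,
                               item_factor = 1, item_levels = "ordinal",
                               thresholds = list(c(0.5, 0.5))),
               "increasing")
})

test_that("polychoric of two general-only items recovers the planted cross-loading product", {
  # lambda_g = 0.7 each, no specific overlap: population corr = 0.49
  spec <- generative_spec(n_subjects = 4000, n_specific = 2,
                          loading_general = rep(0.7, 2),
                          loading_specific = rep(0.3, 2),
                          item_factor = c(1, 2),
                          item_levels = c("ordinal", "ordinal"),
                          thresholds = list(c(-0.6, 0.6), c(-0.6, 0.6)),
                          seed = 8L)
  items <- simulate_item_responses(simulate_latent_scores(spec), spec)
  tab <- table(items[[1]], items[[2]])
  expect_lt(abs(polychoric_pair(tab)$rho - 0.49), 0.04)
})

test_that("population item moments match the loading closed form", {
  spec <- default_cohort_spec(n_subjects = 10000, n_specific = 3,
                              items_per_factor = 5, icc_family = 0,
                              missing_rate = 0, levels = "continuous",
                              seed = 10L)
  items <- simulate_item_responses(simulate_latent_scores(spec), spec)
  expect_lt(max(abs(cor(items) - population_correlation(spec))), 0.05)
})

test_that("planted outcome effects are recoverable and invalid R2 is rejected", {
  spec <- generative_spec(n_subjects = 10000, n_specific = 6,
                          loading_general = rep(0.6, 12),
                          loading_specific = rep(0.4, 12),
                          item_factor = rep(1:6, each = 2), seed = 12L)
  lat <- simulate_latent_scores(spec)
  cov <- simulate_covariates(lat, seed = 12L)

  # null betas: nothing to explain
  os0 <- outcome_spec(beta_general = 0, beta_specific = rep(0, 6),
                      beta_covariates = c(age = 0, sex = 0), seed = 12L)
  out0 <- simulate_outcomes(lat, cov, os0)
  fit0 <- standardized_linear_model(out0$y, lat[, 2:8])
  expect_lt(abs(fit0$adj_r2), 0.02)

  # planted full-model R2 of 0.38 recovered
  os <- outcome_spec(beta_general = 0.285,
                     beta_specific = rep(sqrt(0.2588 / 6), 6),
                     beta_covariates = c(age = 0.15, sex = 0.1323),
                     seed = 12L)
  out <- simulate_outcomes(lat, cov, os)
  fit <- standardized_linear_model(
    out$y, lat[, 2:8], cov[, c("age", "sex")])
  expect_lt(abs(fit$adj_r2 - 0.38), 0.03)

  # planted odds ratio recovered
  osl <- outcome_spec(beta_general = 0.2, beta_specific = rep(0, 6),
                      beta_covariates = c(age = 0, sex = 0),
                      logistic_or_general = 1.4, seed = 13L)
  outl <- simulate_outcomes(lat, cov, osl)
  lg <- logistic_model(outl$obesity, lat[, "general", drop = FALSE])
  expect_gt(lg$table$or[1], 1.3)
  expect_lt(lg$table$or[1], 1.5)

  expect_error(outcome_spec(beta_general = 0.9,
                            beta_specific = rep(0.4, 6)),
               "R\\^2")
})
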