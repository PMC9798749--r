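# planted 1 general + k specific model helpers
make_bifactor_pop <- function(n_specific = 3, per = 5, lg = 0.6, ls = 0.45,
                              weak = integer(0), weak_ls = 0.1) {
  p <- n_specific * per
  a <- rep(seq_len(n_specific), each = per)
  lgv <- rep(lg, p)
  lsv <- rep(ls, p)
  lsv[weak] <- weak_ls
  L <- matrix(0, p, 1 + n_specific)
  L[, 1] <- lgv
  L[cbind(seq_len(p), a + 1L)] <- lsv
  R <- tcrossprod(L)
  diag(R) <- 1
  nm <- sprintf("item%03d", seq_len(p))
  dimnames(R) <- list(nm, nm)
  list(R = R, a = a, lg = lgv, ls = lsv, items = nm,
       spec = bifactor_spec(nm, a, n_specific))
}

test_that("configure_bifactor assigns by largest loading with tie and exclusion rules", {
  L <- rbind(c(0.7, 0.05), c(0.65, 0.1), c(0.6, 0.0),
             c(0.1, 0.7), c(0.0, 0.65), c(0.05, 0.6),
             c(0.35, 0.35),   # tie -> factor 1
             c(0.2, 0.15))    # sub-threshold -> excluded
  rownames(L) <- sprintf("v%d", 1:8)
  rot <- structure(list(loadings = L, Phi = diag(2), rotation = "oblimin"),
                   class = "rotated_solution")
  spec <- suppressWarnings(configure_bifactor(rot, cutoff = 0.30))
  expect_identical(spec$excluded, "v8")
  expect_identical(spec$ties, "v7")
  expect_equal(unname(spec$assignment[c("v1", "v4", "v7")]), c(1L, 2L, 1L))
})

test_that("a sparse specific factor triggers the identification warning", {
  L <- rbind(c(0.7, 0.05), c(0.65, 0.1), c(0.6, 0.0), c(0.55, 0.1),
             c(0.1, 0.7), c(0.0, 0.65))
  rownames(L) <- sprintf("v%d", 1:6)
  rot <- structure(list(loadings = L, Phi = diag(2)),
                   class = "rotated_solution")
  expect_warning(configure_bifactor(rot, cutoff = 0.30), "< 3 items")
})

test_that("ULS bifactor fitting recovers a planted model exactly at population level", {
  pop <- make_bifactor_pop()
  fit <- fit_bifactor(pop$R, pop$spec, N = 4000)
  expect_lt(max(abs(fit$lambda_g - pop$lg)), 1e-3)
  expect_lt(max(abs(fit$lambda_s - pop$ls)), 1e-3)
  expect_lt(fit$F_min, 1e-8)
  # variance decomposition holds item by item
  expect_equal(unname(fit$lambda_g^2 + fit$lambda_s^2 + fit$psi),
               rep(1, length(pop$items)), tolerance = 1e-6)
})

test_that("fixing all specific loadings to zero reproduces the one-factor minres solution", {
  lam <- seq(0.4, 0.75, length.out = 9)
  R <- tcrossprod(lam)
  diag(R) <- 1
  nm <- sprintf("item%03d", 1:9)
  dimnames(R) <- list(nm, nm)
  # assignment 0: every item loads on the general factor only
  fit <- fit_bifactor(R, bifactor_spec(nm, rep(0L, 9), 1), N = 1000)
  one <- extract_minres(R, 1)
  expect_lt(max(abs(fit$lambda_g - one$loadings[, 1])), 1e-3)
  expect_identical(unname(fit$lambda_s), rep(0, 9))
})

test_that("pruning removes exactly the planted weak items and is idempotent", {
  pop <- make_bifactor_pop(n_specific = 4, per = 6, weak = c(2, 9, 16, 23))
  fit <- fit_bifactor(pop$R, pop$spec, N = 4000)
  pr <- prune_and_refit(fit, pop$R, N = 4000, cutoff = 0.30)
  expect_setequal(pr$removed$item, pop$items[c(2, 9, 16, 23)])
  expect_equal(length(pr$spec$items), 20L)
  # no further change on re-run
  pr2 <- prune_and_refit(pr$fit, pop$R, N = 4000, cutoff = 0.30)
  expect_equal(nrow(pr2$removed), 0L)
  expect_identical(pr2$spec$items, pr$spec$items)
  # a fit with nothing below the cutoff is untouched
  pop_ok <- make_bifactor_pop()
  fit_ok <- fit_bifactor(pop_ok$R, pop_ok$spec, N = 4000)
  pr_ok <- prune_and_refit(fit_ok, pop_ok$R, N = 4000, cutoff = 0.30)
  expect_equal(nrow(pr_ok$removed), 0L)
})

test_that("fit indices match their definitions", {
  # perfect-fit limit: T = df
  fake <- list(T = 100, df = 100, N = 1001, T_baseline = 2000,
               df_baseline = 120, R = NULL, Sigma = NULL)
  fi <- fit_indices(fake)
  expect_equal(fi$rmsea, 0)
  expect_equal(fi$cfi, 1)
  # plug-in arithmetic case
  fake2 <- list(T = 200, df = 100, N = 1001, T_baseline = 2000,
                df_baseline = 120, R = NULL, Sigma = NULL)
  fi2 <- fit_indices(fake2)
  expect_equal(fi2$rmsea, sqrt(100 / 100000), tolerance = 1e-4)
  expect_equal(fi2$cfi, 1 - 100 / 1880, tolerance = 1e-4)
  # population matrix from the fitted model has zero residual
  pop <- make_bifactor_pop()
  fit <- fit_bifactor(pop$R, pop$spec, N = 4000)
  fi3 <- fit_indices(fit)
  expect_lt(fi3$srmr, 1e-6)
  expect_equal(fi3$cfi, 1)
  expect_equal(fi3$rmsea, 0)
  expect_error(fit_indices(list(T = 1, df = 0, N = 100)), "saturated")
})

test_that("bifactor indices match hand-computed closed forms", {
  # 12 items, all lambda_g = 0.6, lambda_s = 0.4, two specifics of 6
  p <- 12
  a <- rep(1:2, each = 6)
  nm <- sprintf("item%03d", 1:p)
  lg <- rep(0.6, p)
  ls <- rep(0.4, p)
  L <- matrix(0, p, 3)
  L[, 1] <- lg
  L[cbind(1:p, a + 1)] <- ls
  R <- tcrossprod(L)
  diag(R) <- 1
  dimnames(R) <- list(nm, nm)
  fit <- fit_bifactor(R, bifactor_spec(nm, a, 2), N = 1000)
  bi <- bifactor_indices(fit)
  expect_equal(bi$ecv, (12 * 0.36) / (12 * 0.36 + 12 * 0.16),
               tolerance = 1e-4)   # 0.6923
  # omega_h by hand: (sum lg)^2 / ((sum lg)^2 + sum_s (sum ls_s)^2 + sum psi)
  omega_h_hand <- (12 * 0.6)^2 /
    ((12 * 0.6)^2 + 2 * (6 * 0.4)^2 + 12 * (1 - 0.36 - 0.16))
  expect_equal(bi$omega_h, omega_h_hand, tolerance = 1e-4)
  omega_hs_hand <- (6 * 0.4)^2 /
    ((6 * 0.6)^2 + (6 * 0.4)^2 + 6 * (1 - 0.36 - 0.16))
  expect_equal(unname(bi$omega_hs), rep(omega_hs_hand, 2), tolerance = 1e-4)

  # degenerate: no specific variance anywhere
  lam <- rep(0.6, 9)
  R1 <- tcrossprod(lam)
  diag(R1) <- 1
  nm1 <- sprintf("item%03d", 1:9)
  dimnames(R1) <- list(nm1, nm1)
  fit1 <- fit_bifactor(R1, bifactor_spec(nm1, rep(0L, 9), 3), N = 1000)
  bi1 <- bifactor_indices(fit1)
  expect_equal(bi1$ecv, 1, tolerance = 1e-3)
  expect_true(all(is.na(bi1$omega_hs)))
})

test_that("regression scores hit the identity limit and the model-implied correlations", {
  # single-item identity limit: lambda_g = 1 means the score is the item
  fit1 <- structure(list(lambda_g = c(item001 = 1),
                         lambda_s = c(item001 = 0),
                         psi = c(item001 = 0),
                         assignment = c(item001 = 1L),
                         R = matrix(1, 1, 1, dimnames = list("item001", "item001")),
                         Sigma = matrix(1, 1, 1,
                                        dimnames = list("item001", "item001")),
                         spec = bifactor_spec("item001", 1L, 1)),
                    class = "bifactor_fit")
  x <- matrix(scale(rnorm(50)), dimnames = list(NULL, "item001"))
  sc1 <- factor_scores(x, fit1)
  expect_equal(unname(sc1$scores[, 1]), as.numeric(scale(x)), tolerance = 1e-10)

  # planted model: general-score recovery tracks determinacy, and empirical
  # score correlations match the model-implied correlation of regression
  # scores (Lambda' R^-1 Lambda, normalized)
  spec <- default_cohort_spec(n_subjects = 10000, n_specific = 4,
                              items_per_factor = 8, icc_family = 0,
                              missing_rate = 0, levels = "continuous",
                              seed = 51L)
  lat <- simulate_latent_scores(spec)
  items <- simulate_item_responses(lat, spec)
  R <- population_correlation(spec)
  fit <- fit_bifactor(R, bifactor_spec(colnames(R), spec$item_factor,
                                       spec$n_specific), N = 10000)
  X <- standardize_items(items, manifest_from_spec(spec))
  sc <- factor_scores(X, fit)
  fd_g <- sc$determinacy[["general"]]
  expect_gte(fd_g, 0.9)
  expect_gte(cor(sc$scores[, 1], lat$general), 0.9)
  expect_equal(cor(sc$scores[, 1], lat$general), fd_g, tolerance = 0.03)

  L <- expofactor:::.bifactor_lambda(fit)
  M <- t(L) %*% solve(R[rownames(L), rownames(L)]) %*% L
  implied <- diag(1 / sqrt(diag(M))) %*% M %*% diag(1 / sqrt(diag(M)))
  expect_lt(max(abs(cor(sc$scores) - implied)), 0.05)

  # missing entries drop rows with a count
  X2 <- X
  X2[1:10, 1] <- NA
  sc2 <- factor_scores(X2, fit)
  expect_equal(sc2$n_dropped, 10L)
  expect_equal(nrow(sc2$scores), nrow(X) - 10L)
})
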