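test_that("bivariate normal CDF matches closed forms and quadrature", {
  # median-dichotomized closed form: P(X<=0, Y<=0) = 1/4 + asin(rho)/(2*pi)
  for (r in c(-0.95, -0.5, 0, 0.3, 0.8, 0.99))
    expect_equal(pbvnorm(0, 0, r), 0.25 + asin(r) / (2 * pi),
                 tolerance = 1e-12)
  # independence factorizes
  expect_equal(pbvnorm(0.7, -1.1, 0), pnorm(0.7) * pnorm(-1.1),
               tolerance = 1e-15)
  # perfect correlation collapses to min/max marginals
  expect_equal(pbvnorm(0.5, 1.5, 1), pnorm(0.5), tolerance = 1e-12)
  expect_equal(pbvnorm(0.5, -0.2, -1), pnorm(0.5) + pnorm(-0.2) - 1,
               tolerance = 1e-12)
  # against a fine one-dimensional quadrature in rho
  for (case in list(c(0.8, -0.4, 0.6), c(1.5, 1.2, 0.97),
                    c(-2, 0.3, -0.85), c(0.1, 2.5, 0.45))) {
    h <- case[1]; k <- case[2]; r <- case[3]
    ts <- seq(0, r, length.out = 20001)
    f <- exp(-(h^2 - 2 * ts * h * k + k^2) / (2 * (1 - ts^2))) /
      (2 * pi * sqrt(1 - ts^2))
    ref <- pnorm(h) * pnorm(k) +
      sum((f[-1] + f[-length(f)]) / 2) * (ts[2] - ts[1])
    expect_lt(abs(pbvnorm(h, k, r) - ref), 1e-7)
  }
})

test_that("thresholds are inverse-normal cumulative proportions", {
  expect_equal(estimate_thresholds(c(50, 50))$tau, 0, tolerance = 1e-12)
  expect_equal(estimate_thresholds(c(1587, 6826, 1587))$tau,
               qnorm(c(0.1587, 0.8413)), tolerance = 1e-12)
  expect_equal(estimate_thresholds(c(10, 20, 70))$tau,
               qnorm(c(0.1, 0.3)), tolerance = 1e-10)
  expect_warning(out <- estimate_thresholds(c(30, 0, 70)), "merged")
  expect_equal(out$tau, qnorm(0.3), tolerance = 1e-12)
  expect_error(suppressWarnings(estimate_thresholds(c(100, 0))), "categories")
})

test_that("polychoric estimation handles independence, perfection and matches the grid oracle", {
  expect_lt(abs(polychoric_pair(matrix(25, 2, 2))$rho), 1e-6)
  expect_warning(pp <- polychoric_pair(matrix(c(50, 0, 0, 50), 2)),
                 "boundary")
  expect_equal(pp$rho, 0.999)
  tab <- matrix(c(40, 10, 10, 40), 2)
  expect_lt(abs(polychoric_pair(tab)$rho - grid_polychoric(tab)), 1e-3)
  # a handful of random mixed-size tables against the brute-force grid
  set.seed(11)
  for (i in 1:8) {
    tab <- random_polychoric_table(800, runif(1, -0.7, 0.7),
                                   sample(2:4, 1), sample(2:4, 1))
    tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
    if (nrow(tab) < 2 || ncol(tab) < 2) next
    expect_lt(abs(polychoric_pair(tab)$rho - grid_polychoric(tab)), 1e-3)
  }
})

test_that("polyserial estimation is consistent and self-consistent", {
  set.seed(21)
  x <- rnorm(5000)
  # ordinal variable cut from x itself: latent correlation at the boundary
  y_self <- as.integer(x > 0)
  expect_gt(polyserial_pair(x, y_self)$rho, 0.97)
  # independent columns
  y_ind <- as.integer(rnorm(5000) > 0.3)
  expect_lt(abs(polyserial_pair(x, y_ind)$rho), 0.05)
  # planted latent correlation 0.6 with 3 categories
  z <- 0.6 * x + sqrt(1 - 0.36) * rnorm(5000)
  y <- findInterval(z, c(-0.5, 0.5))
  expect_lt(abs(polyserial_pair(x, y)$rho - 0.6), 0.05)
  expect_error(polyserial_pair(rep(1, 100), y_ind[1:100]), "variance")
})

test_that("mixed correlation matrix dispatches by level and honors pairwise deletion", {
  spec <- default_cohort_spec(n_subjects = 10000, n_specific = 2,
                              items_per_factor = 4, icc_family = 0,
                              missing_rate = 0, seed = 31L)
  cohort <- simulate_cohort(spec)
  mc <- mixed_correlation_matrix(cohort$items, cohort$manifest)
  lev <- cohort$manifest$level
  for (i in 1:7) for (j in (i + 1):8) {
    expected <- if (lev[i] == "continuous" && lev[j] == "continuous") "pearson"
    else if (lev[i] != "continuous" && lev[j] != "continuous") "polychoric"
    else "polyserial"
    expect_identical(mc$method[i, j], expected)
  }
  # contract: symmetric, unit diagonal, PSD
  expect_true(isSymmetric(mc$R))
  expect_equal(unname(diag(mc$R)), rep(1, 8))
  expect_gte(min(eigen(mc$R, symmetric = TRUE, only.values = TRUE)$values),
             -1e-10)

  # all-continuous table reduces to the Pearson matrix
  specc <- default_cohort_spec(n_subjects = 2000, n_specific = 2,
                               items_per_factor = 3, icc_family = 0,
                               missing_rate = 0, levels = "continuous",
                               seed = 32L)
  cc <- simulate_cohort(specc)
  mcc <- mixed_correlation_matrix(cc$items, cc$manifest)
  expect_equal(unname(mcc$R), unname(cor(cc$items)), tolerance = 1e-12)

  # MCAR missingness moves entries by less than 0.05
  specm <- default_cohort_spec(n_subjects = 10000, n_specific = 2,
                               items_per_factor = 4, icc_family = 0,
                               missing_rate = 0.10, seed = 31L)
  cm <- simulate_cohort(specm)
  mcm <- mixed_correlation_matrix(cm$items, cm$manifest)
  expect_lt(max(abs(mcm$R - mc$R)), 0.05)

  # too few complete pairs is an error naming the columns
  bad <- cohort$items[1:30, ]
  bad[[1]][1:25] <- NA
  bad[[2]][6:30] <- NA
  expect_error(mixed_correlation_matrix(bad, cohort$manifest),
               "item001.*item002")
})

test_that("nearest_psd clips eigenvalues, preserves PSD inputs, and is idempotent", {
  R_ok <- diag(3)
  R_ok[1, 2] <- R_ok[2, 1] <- 0.4
  expect_identical(nearest_psd(R_ok), R_ok)
  R_bad <- matrix(c(1, 0.9, 0.9, 0.9, 1, -0.9, 0.9, -0.9, 1), 3)
  S <- nearest_psd(R_bad)
  expect_equal(unname(diag(S)), rep(1, 3))
  expect_gte(min(eigen(S, symmetric = TRUE, only.values = TRUE)$values), 0)
  expect_identical(nearest_psd(S), S)
})
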