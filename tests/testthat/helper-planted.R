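# Builders for planted factor structures and independent oracles used across
# the test files.

# simple-structure loading matrix: `per` items per factor with the given
# primary loadings recycled within each block
planted_simple_loadings <- function(k, per, primary = c(0.7, 0.65, 0.6, 0.55, 0.5)) {
  p <- k * per
  L <- matrix(0, p, k)
  for (f in seq_len(k))
    L[((f - 1) * per + 1):(f * per), f] <- rep_len(primary, per)
  L
}

# population correlation from oblique loadings
planted_population_R <- function(L, Phi = diag(ncol(L))) {
  R <- L %*% Phi %*% t(L)
  diag(R) <- 1
  R
}

# Tucker congruence of matched columns
column_congruence <- function(A, B) {
  vapply(seq_len(ncol(A)), function(j)
    sum(A[, j] * B[, j]) / sqrt(sum(A[, j]^2) * sum(B[, j]^2)), numeric(1))
}

# Independent grid-search ML oracle for the polychoric correlation:
# thresholds from the margins, then the profile likelihood evaluated on a
# rho grid via cumulative-trapezoid integration of the bivariate normal
# density in rho (a route sharing no code with polychoric_pair/pbvnorm).
grid_polychoric <- function(tab, step = 1e-4, bound = 0.99) {
  tab <- as.matrix(tab)
  a <- stats::qnorm(cumsum(rowSums(tab))[-nrow(tab)] / sum(tab))
  b <- stats::qnorm(cumsum(colSums(tab))[-ncol(tab)] / sum(tab))
  rho <- seq(-bound + step, bound - step, by = step)
  i0 <- which.min(abs(rho))       # index of rho = 0
  # Phi2(h, k, rho) along the rho grid for one (h, k) pair:
  #   Phi(h)Phi(k) + integral_0^rho phi2(h, k; t) dt
  phi2_path <- function(h, k) {
    f <- exp(-(h^2 - 2 * rho * h * k + k^2) / (2 * (1 - rho^2))) /
      (2 * pi * sqrt(1 - rho^2))
    out <- numeric(length(rho))
    up <- i0:length(rho)
    out[up] <- c(0, cumsum((f[up][-1] + f[up][-length(up)]) / 2 * step))
    dn <- i0:1
    out[dn] <- -c(0, cumsum((f[dn][-1] + f[dn][-length(dn)]) / 2 * step))
    stats::pnorm(h) * stats::pnorm(k) + out
  }
  aa <- c(-Inf, a, Inf)
  bb <- c(-Inf, b, Inf)
  Fg <- array(0, c(length(aa), length(bb), length(rho)))
  for (i in seq_along(aa)) for (j in seq_along(bb)) {
    h <- aa[i]; k <- bb[j]
    Fg[i, j, ] <- if (h == -Inf || k == -Inf) 0
    else if (h == Inf && k == Inf) 1
    else if (h == Inf) stats::pnorm(k)
    else if (k == Inf) stats::pnorm(h)
    else phi2_path(h, k)
  }
  ll <- numeric(length(rho))
  for (i in seq_len(nrow(tab))) for (j in seq_len(ncol(tab))) {
    if (tab[i, j] == 0) next
    P <- Fg[i + 1, j + 1, ] - Fg[i, j + 1, ] - Fg[i + 1, j, ] + Fg[i, j, ]
    ll <- ll + tab[i, j] * log(pmax(P, 1e-300))
  }
  rho[which.max(ll)]
}

# random ordinal contingency table from a latent bivariate normal sample
random_polychoric_table <- function(n, rho, k1, k2) {
  z1 <- stats::rnorm(n)
  z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(n)
  t1 <- sort(stats::runif(k1 - 1, -1.2, 1.2))
  t2 <- sort(stats::runif(k2 - 1, -1.2, 1.2))
  table(factor(findInterval(z1, t1), levels = 0:(k1 - 1)),
        factor(findInterval(z2, t2), levels = 0:(k2 - 1)))
}
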