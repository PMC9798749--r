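#' Estimate latent-normal thresholds from category frequencies
#'
#' Under the latent-response model an observed k-category item arises by
#' cutting a standard normal variable at k-1 thresholds; the maximum
#' likelihood estimate of threshold j is the standard normal quantile of the
#' cumulative proportion through category j.
#'
#' @param counts vector of category frequencies in category order.
#' @return list with \code{tau} (length k-1, strictly increasing) and
#'   \code{counts} (after merging any empty categories, with a warning).
#' @export
#' @examples
#' estimate_thresholds(c(50, 50))$tau   # 0
estimate_thresholds <- function(counts) {
  stopifnot(is.numeric(counts), all(counts >= 0))
  if (any(counts == 0)) {
    warning("empty categories merged with their neighbour")
    counts <- counts[counts > 0]
  }
  if (length(counts) < 2L)
    stop("at least 2 nonempty categories required")
  n <- sum(counts)
  cum <- cumsum(counts)[-length(counts)] / n
  list(tau = stats::qnorm(cum), counts = counts)
}

# Cell probabilities of a bivariate normal contingency table given row
# thresholds a, column thresholds b and correlation rho.
.polychoric_cell_probs <- function(a, b, rho) {
  aa <- c(-Inf, a, Inf)
  bb <- c(-Inf, b, Inf)
  na <- length(aa)
  nb <- length(bb)
  # CDF grid; boundaries use univariate marginals
  Fg <- matrix(0, na, nb)
  for (i in seq_len(na)) for (j in seq_len(nb)) {
    x <- aa[i]
    y <- bb[j]
    Fg[i, j] <- if (x == -Inf || y == -Inf) 0
    else if (x == Inf && y == Inf) 1
    else if (x == Inf) stats::pnorm(y)
    else if (y == Inf) stats::pnorm(x)
    else pbvnorm(x, y, rho)
  }
  P <- Fg[-1, -1, drop = FALSE] - Fg[-na, -1, drop = FALSE] -
    Fg[-1, -nb, drop = FALSE] + Fg[-na, -nb, drop = FALSE]
  pmax(P, 0)
}

.polychoric_loglik <- function(rho, tab, a, b) {
  P <- .polychoric_cell_probs(a, b, rho)
  sum(tab * log(pmax(P, 1e-300)))
}

#' Two-step maximum-likelihood polychoric correlation
#'
#' Thresholds are estimated from the table margins by inverse-normal
#' transformation of cumulative proportions; the correlation then maximizes
#' the bivariate-normal cell likelihood over (-0.999, 0.999). Rows/columns
#' with zero margins are merged with a warning; a boundary estimate (perfect
#' association) is returned clipped at ±0.999 with a warning.
#'
#' @param tab contingency table (matrix of counts), at least 2x2 after
#'   merging empty margins.
#' @return list with \code{rho}, \code{tau_row}, \code{tau_col},
#'   \code{loglik}, \code{n}.
#' @export
polychoric_pair <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(all(tab >= 0), sum(tab) > 0)
  rz <- rowSums(tab) == 0
  cz <- colSums(tab) == 0
  if (any(rz) || any(cz)) {
    warning("zero row/column margins dropped (categories merged)")
    tab <- tab[!rz, !cz, drop = FALSE]
  }
  if (nrow(tab) < 2L || ncol(tab) < 2L)
    stop("table must be at least 2x2 after merging empty categories")
  a <- estimate_thresholds(rowSums(tab))$tau
  b <- estimate_thresholds(colSums(tab))$tau
  opt <- stats::optimize(.polychoric_loglik, c(-0.999, 0.999),
                         tab = tab, a = a, b = b,
                         maximum = TRUE, tol = 1e-9)
  rho <- opt$maximum
  # optimize() cannot land exactly on the boundary; snap if the likelihood is
  # still increasing there (perfect or near-perfect association)
  for (bnd in c(-0.999, 0.999)) {
    if (.polychoric_loglik(bnd, tab, a, b) >= opt$objective) {
      rho <- bnd
      warning("polychoric estimate at boundary; association is (near) perfect")
    }
  }
  list(rho = rho, tau_row = a, tau_col = b,
       loglik = .polychoric_loglik(rho, tab, a, b), n = sum(tab))
}

.polyserial_negloglik <- function(rho, z, y, tau) {
  s <- sqrt(1 - rho^2)
  tt <- c(-Inf, tau, Inf)
  upper <- stats::pnorm((tt[y + 2L] - rho * z) / s)
  lower <- stats::pnorm((tt[y + 1L] - rho * z) / s)
  -sum(log(pmax(upper - lower, 1e-300)))
}

#' Two-step maximum-likelihood polyserial correlation
#'
#' The continuous variable is standardized; ordinal thresholds come from the
#' ordinal margins; the latent correlation maximizes the conditional
#' likelihood of the ordinal responses given the continuous scores.
#'
#' @param x continuous values.
#' @param y ordinal values coded 0..k-1 (integer codes; any coding with
#'   ordered unique values is re-coded).
#' @return list with \code{rho}, \code{tau}, \code{n}.
#' @export
polyserial_pair <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]
  y <- y[ok]
  if (length(x) < 10L) stop("need at least 10 complete pairs")
  if (stats::sd(x) == 0) stop("continuous column has zero variance")
  lev <- sort(unique(y))
  if (length(lev) < 2L) stop("ordinal column has a single category")
  y <- match(y, lev) - 1L
  tau <- estimate_thresholds(tabulate(y + 1L, nbins = length(lev)))$tau
  z <- as.numeric(scale(x))
  opt <- stats::optimize(.polyserial_negloglik, c(-0.999, 0.999),
                         z = z, y = y, tau = tau, tol = 1e-9)
  list(rho = opt$minimum, tau = tau, n = length(x))
}

#' Nearest positive-semidefinite correlation matrix by eigenvalue clipping
#'
#' Pairwise-deleted mixed correlation matrices need not be PSD. Eigenvalues
#' below \code{floor} are raised to it, the matrix is reassembled and
#' rescaled to unit diagonal. A PSD input is returned unchanged, so the
#' operation is idempotent.
#'
#' @param R symmetric matrix with unit diagonal.
#' @param floor eigenvalue floor (default 1e-6).
#' @return PSD correlation matrix.
#' @export
nearest_psd <- function(R, floor = 1e-6) {
  stopifnot(isSymmetric(unname(R), tol = 1e-8))
  if (any(abs(diag(R) - 1) > 1e-8)) stop("R must have unit diagonal")
  e <- eigen(R, symmetric = TRUE)
  if (min(e$values) >= 0) return(R)
  v <- pmax(e$values, floor)
  S <- e$vectors %*% (v * t(e$vectors))
  d <- 1 / sqrt(diag(S))
  S <- S * tcrossprod(d)
  diag(S) <- 1
  S <- (S + t(S)) / 2
  dimnames(S) <- dimnames(R)
  S
}

#' Mixed-type correlation matrix with pairwise deletion
#'
#' Dispatches per pair on the declared measurement levels: Pearson for
#' continuous-continuous, polyserial for continuous-ordinal, polychoric for
#' ordinal/binary pairs. Each pair uses its pairwise-complete observations;
#' the assembled matrix is smoothed to the nearest PSD correlation matrix if
#' indefinite.
#'
#' @param items data frame of item columns (ordinal coded 0..k-1, NA for
#'   missing).
#' @param manifest data frame with columns \code{name} and \code{level}
#'   covering every item column.
#' @param min_pairs minimum pairwise-complete observations per pair.
#' @return object of class \code{mixed_cor}: list with \code{R},
#'   \code{method} (per-pair tag matrix), \code{pairwise_n},
#'   \code{thresholds} (per ordinal variable, from its full margin),
#'   \code{smoothed} flag.
#' @export
mixed_correlation_matrix <- function(items, manifest, min_pairs = 10L) {
  stopifnot(all(names(items) %in% manifest$name))
  lev <- manifest$level[match(names(items), manifest$name)]
  p <- ncol(items)
  X <- items
  R <- diag(1, p)
  meth <- matrix("", p, p)
  np <- matrix(NA_integer_, p, p)
  diag(np) <- colSums(!is.na(X))
  ordinal <- lev %in% c("ordinal", "binary")
  thresholds <- stats::setNames(vector("list", p), names(items))
  for (j in which(ordinal)) {
    yj <- X[[j]][!is.na(X[[j]])]
    kj <- sort(unique(yj))
    thresholds[[j]] <- estimate_thresholds(tabulate(match(yj, kj)))$tau
  }
  for (i in seq_len(p - 1L)) {
    for (j in (i + 1L):p) {
      ok <- !is.na(X[[i]]) & !is.na(X[[j]])
      n_ij <- sum(ok)
      if (n_ij < min_pairs)
        stop(sprintf("columns %s and %s share only %d complete observations",
                     names(items)[i], names(items)[j], n_ij))
      xi <- X[[i]][ok]
      xj <- X[[j]][ok]
      if (!ordinal[i] && !ordinal[j]) {
        r <- stats::cor(xi, xj)
        m <- "pearson"
      } else if (ordinal[i] && ordinal[j]) {
        tab <- table(factor(xi, levels = sort(unique(xi))),
                     factor(xj, levels = sort(unique(xj))))
        r <- polychoric_pair(tab)$rho
        m <- "polychoric"
      } else {
        if (ordinal[i]) r <- polyserial_pair(xj, xi)$rho
        else r <- polyserial_pair(xi, xj)$rho
        m <- "polyserial"
      }
      R[i, j] <- R[j, i] <- r
      meth[i, j] <- meth[j, i] <- m
      np[i, j] <- np[j, i] <- n_ij
    }
  }
  dimnames(R) <- list(names(items), names(items))
  ev_min <- min(eigen(R, symmetric = TRUE, only.values = TRUE)$values)
  smoothed <- ev_min < 0
  if (smoothed) R <- nearest_psd(R)
  structure(list(R = R, method = meth, pairwise_n = np,
                 thresholds = thresholds, smoothed = smoothed,
                 levels = stats::setNames(lev, names(items))),
            class = "mixed_cor")
}

#' Write a mixed correlation matrix with its metadata sidecar
#' @param mc a \code{mixed_cor}.
#' @param path CSV path for the matrix; metadata JSON written alongside.
#' @return invisibly, both paths.
#' @export
write_mixed_cor <- function(mc, path) {
  df <- data.frame(variable = rownames(mc$R), round(mc$R, 6),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  meta <- list(smoothed = mc$smoothed,
               levels = as.list(mc$levels),
               pairwise_n_range = range(mc$pairwise_n, na.rm = TRUE),
               methods_used = sort(unique(mc$method[mc$method != ""])))
  meta_path <- sub("\\.csv$", ".meta.json", path)
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, digits = NA)
  invisible(c(path, meta_path))
}
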