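#' Minimum-residual (minres) factor extraction
#'
#' Finds uniquenesses minimizing the sum of squared off-diagonal residuals of
#' \eqn{R - \Lambda\Lambda'}, with loadings taken from the leading
#' eigenvectors of the reduced correlation matrix at each step. Columns are
#' ordered by decreasing sum of squared loadings and signed so the first
#' non-negligible entry is non-negative.
#'
#' @param R correlation matrix (PSD).
#' @param k number of factors, 1 <= k < ncol(R).
#' @return list with \code{loadings}, \code{communalities}, \code{uniquenesses},
#'   \code{k}, \code{objective} (sum of squared off-diagonal residuals),
#'   \code{heywood} flag.
#' @export
extract_minres <- function(R, k) {
  if (inherits(R, "mixed_cor")) R <- R$R
  p <- ncol(R)
  stopifnot(k >= 1, k < p)
  off <- upper.tri(R)
  loadings_for <- function(psi) {
    Rs <- R
    diag(Rs) <- 1 - psi
    e <- eigen(Rs, symmetric = TRUE)
    vals <- pmax(e$values[seq_len(k)], 0)
    e$vectors[, seq_len(k), drop = FALSE] %*% diag(sqrt(vals), k)
  }
  objective <- function(psi) {
    L <- loadings_for(psi)
    sum((R - tcrossprod(L))[off]^2)
  }
  # start at 1 - squared multiple correlation (ridge-protected)
  smc <- tryCatch({
    Ri <- solve(R + diag(1e-8, p))
    1 - 1 / diag(Ri)
  }, error = function(e) rep(0.5, p))
  start <- pmin(pmax(1 - smc, 0.01), 1)
  fit <- stats::optim(start, objective, method = "L-BFGS-B",
                      lower = rep(0.005, p), upper = rep(1, p),
                      control = list(maxit = 1000, factr = 1e4))
  psi <- fit$par
  heywood <- any(psi <= 0.005 + 1e-12)
  if (heywood)
    warning("Heywood case: communality capped at 0.995")
  L <- loadings_for(psi)
  L <- .canonicalize_loadings(L)$loadings
  h2 <- rowSums(L^2)
  rownames(L) <- rownames(R)
  list(loadings = L, communalities = h2, uniquenesses = 1 - h2,
       k = k, objective = fit$value, heywood = heywood)
}

# ---- gradient-projection rotation engine (oblique) ----------------------

# Quartimin criterion (direct oblimin, gamma = 0).
.vgq_quartimin <- function(L) {
  k <- ncol(L)
  L2 <- L^2
  X <- L2 %*% (matrix(1, k, k) - diag(k))
  list(f = sum(L2 * X) / 4, Gq = L * X)
}

# Partially specified target: penalize loadings in cells the target fixes
# at zero (weight matrix W is 1 there, 0 in free cells).
.vgq_target <- function(L, W, Target = 0) {
  D <- W * (L - Target)
  list(f = sum(D^2), Gq = 2 * D)
}

# Oblique gradient-projection algorithm (Jennrich's GPA): rotates an
# unrotated loading matrix A to minimize criterion vgq over oblique
# transformations. Returns pattern matrix, factor correlations and the
# criterion trajectory.
.gpa_oblique <- function(A, vgq, Tmat = diag(ncol(A)),
                         maxit = 1000, eps = 1e-6) {
  al <- 1
  Ti <- solve(Tmat)
  L <- A %*% t(Ti)
  V <- vgq(L)
  f <- V$f
  G <- -t(t(L) %*% V$Gq %*% Ti)
  trace <- numeric(0)
  converged <- FALSE
  for (iter in seq_len(maxit)) {
    Gp <- G - Tmat %*% diag(colSums(Tmat * G), ncol(A))
    s <- sqrt(sum(Gp^2))
    trace <- c(trace, f)
    if (s < eps) {
      converged <- TRUE
      break
    }
    al <- 2 * al
    for (half in 0:10) {
      X <- Tmat - al * Gp
      Tt <- X %*% diag(1 / sqrt(colSums(X^2)), ncol(A))
      Ti <- solve(Tt)
      L <- A %*% t(Ti)
      Vt <- vgq(L)
      if (Vt$f < f - 0.5 * s^2 * al) break
      al <- al / 2
    }
    Tmat <- Tt
    f <- Vt$f
    G <- -t(t(L) %*% Vt$Gq %*% Ti)
  }
  if (!converged)
    stop(paste0("rotation did not converge in ", maxit,
                " iterations; criterion trajectory: ",
                paste(signif(utils::tail(trace, 5), 6), collapse = ", ")))
  Phi <- crossprod(Tmat)
  list(loadings = L, Phi = Phi, f = f, iterations = iter)
}

#' Direct oblimin (quartimin) rotation
#'
#' Oblique rotation minimizing the quartimin criterion (oblimin with
#' \eqn{\gamma = 0}) by gradient projection, started from the identity and a
#' set of seeded random rotations to avoid local minima; the solution with
#' the lowest criterion wins. The model-implied matrix
#' \eqn{\Lambda\Phi\Lambda'} is invariant under rotation.
#'
#' @param L0 unrotated loading matrix (or result of
#'   \code{\link{extract_minres}}).
#' @param n_starts random starts in addition to the identity start.
#' @param seed seed for the random starts.
#' @return object of class \code{rotated_solution}: \code{loadings} (pattern
#'   matrix), \code{Phi}, \code{rotation}, \code{iterations}.
#' @export
rotate_oblimin <- function(L0, n_starts = 10, seed = 1L) {
  if (is.list(L0)) L0 <- L0$loadings
  k <- ncol(L0)
  stopifnot(k >= 2)
  starts <- c(list(diag(k)),
              .with_seed(.child_seed(seed, "oblimin"), {
                lapply(seq_len(n_starts), function(i) {
                  qr.Q(qr(matrix(stats::rnorm(k * k), k, k)))
                })
              }))
  best <- NULL
  for (Tm in starts) {
    sol <- tryCatch(.gpa_oblique(L0, .vgq_quartimin, Tmat = Tm),
                    error = function(e) NULL)
    if (!is.null(sol) && (is.null(best) || sol$f < best$f)) best <- sol
  }
  if (is.null(best)) stop("oblimin rotation failed from every start")
  can <- .canonicalize_loadings(best$loadings, best$Phi)
  structure(list(loadings = can$loadings, Phi = can$Phi,
                 rotation = "oblimin", iterations = best$iterations,
                 criterion = best$f),
            class = "rotated_solution")
}

#' Oblique target rotation against a partially specified target
#'
#' Minimizes the sum of squared loadings in the cells a 0/1 weight matrix
#' marks as zero-targeted, leaving other cells free.
#'
#' @param L0 unrotated loadings.
#' @param W items x k 0/1 matrix; 1 marks a cell targeted at zero.
#' @return \code{rotated_solution} with rotation tag \code{"target"}.
#' @export
rotate_target <- function(L0, W) {
  if (is.list(L0)) L0 <- L0$loadings
  stopifnot(ncol(L0) == ncol(W), nrow(L0) == nrow(W))
  sol <- .gpa_oblique(L0, function(L) .vgq_target(L, W))
  structure(list(loadings = sol$loadings, Phi = sol$Phi,
                 rotation = "target", iterations = sol$iterations,
                 criterion = sol$f),
            class = "rotated_solution")
}

# zero-pattern of a loading matrix at cutoff c, as a 0/1 weight matrix
# (1 = targeted at zero), after aligning columns to a reference order.
.target_weights <- function(L, cutoff) (abs(L) < cutoff) * 1

#' Iterated target rotation (ITR)
#'
#' Alternates oblique target rotation with rebuilding the zero-pattern
#' target from the rotated pattern at cutoff \code{cutoff}, starting from the
#' oblimin solution, until the zero pattern stabilizes. Designed to recover
#' complex structure (cross-loadings) that simple-structure rotations
#' suppress. If the pattern cycles, the visited solution with the lowest
#' target criterion is returned with a warning.
#'
#' @param L0 unrotated loadings (or \code{extract_minres} result).
#' @param cutoff absolute loading below which a cell is targeted at zero
#'   (default 0.30, matching the conventional salience threshold).
#' @param max_iter maximum target rebuilds.
#' @param seed seed for the initial oblimin's random starts.
#' @return \code{rotated_solution} with tag \code{"itr"}, plus
#'   \code{iterations} (number of target rebuilds) and \code{converged}.
#' @export
iterated_target_rotation <- function(L0, cutoff = 0.30, max_iter = 25,
                                     seed = 1L) {
  if (is.list(L0)) L0 <- L0$loadings
  stopifnot(ncol(L0) >= 2, cutoff > 0, cutoff < 1)
  obl <- rotate_oblimin(L0, seed = seed)
  W <- .target_weights(obl$loadings, cutoff)
  seen <- list()
  sols <- list()
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    sol <- rotate_target(L0, W)
    can <- .canonicalize_loadings(sol$loadings, sol$Phi)
    Wnew <- .target_weights(can$loadings, cutoff)
    key <- paste(Wnew, collapse = "")
    sols[[it]] <- list(sol = sol, can = can, W = Wnew)
    if (identical(Wnew, W)) {
      converged <- TRUE
      break
    }
    prev_keys <- vapply(seen, identity, character(1))
    if (key %in% prev_keys) {
      warning("ITR target pattern cycled; returning lowest-criterion solution")
      crit <- vapply(sols, function(s) s$sol$criterion, numeric(1))
      it <- which.min(crit)
      sol <- sols[[it]]$sol
      can <- sols[[it]]$can
      break
    }
    seen[[length(seen) + 1L]] <- key
    W <- Wnew
  }
  structure(list(loadings = can$loadings, Phi = can$Phi,
                 rotation = "itr", iterations = it,
                 converged = converged, criterion = sol$criterion,
                 cutoff = cutoff, oblimin = obl),
            class = "rotated_solution")
}

#' Horn's parallel analysis for factor retention
#'
#' Compares the eigenvalues of the observed correlation matrix with the 95th
#' percentile of eigenvalues from correlation matrices of seeded random
#' normal data of the same dimensions; retained factors are the leading
#' eigenvalues exceeding their threshold.
#'
#' @param R correlation matrix (or \code{mixed_cor}).
#' @param n_subjects sample size behind \code{R}.
#' @param n_resamples random datasets (default 100).
#' @param quantile percentile of the null eigenvalue distribution.
#' @param seed seed.
#' @return list with \code{k}, \code{eigenvalues}, \code{thresholds}.
#' @export
retain_factors <- function(R, n_subjects, n_resamples = 100,
                           quantile = 0.95, seed = 1L) {
  if (inherits(R, "mixed_cor")) R <- R$R
  p <- ncol(R)
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  null_ev <- .with_seed(.child_seed(seed, "parallel"), {
    t(vapply(seq_len(n_resamples), function(b) {
      X <- matrix(stats::rnorm(n_subjects * p), n_subjects, p)
      eigen(stats::cor(X), symmetric = TRUE, only.values = TRUE)$values
    }, numeric(p)))
  })
  thr <- apply(null_ev, 2, stats::quantile, probs = quantile)
  exceeds <- ev > thr
  k <- if (exceeds[1]) which.min(c(exceeds, FALSE)) - 1L else 0L
  if (k == 0L)
    stop("parallel analysis retains no factors; inspect the correlation matrix")
  list(k = as.integer(k), eigenvalues = ev, thresholds = as.numeric(thr))
}
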