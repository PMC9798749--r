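#' Derive a bifactor model specification from a rotated EFA solution
#'
#' Each item is assigned to the specific factor carrying its largest
#' absolute pattern loading; items whose largest absolute loading falls below
#' \code{cutoff} are excluded (logged). Ties go to the lower factor index
#' (logged). Every retained item also loads on the general factor.
#'
#' @param rotated a \code{rotated_solution} (pattern matrix used).
#' @param cutoff salience cutoff (default 0.30).
#' @return object of class \code{bifactor_spec}: \code{items},
#'   \code{assignment} (factor index per item), \code{n_specific},
#'   \code{excluded}, \code{ties}, \code{cutoff}.
#' @export
configure_bifactor <- function(rotated, cutoff = 0.30) {
  L <- rotated$loadings
  p <- nrow(L)
  items <- rownames(L)
  if (is.null(items)) items <- sprintf("item%03d", seq_len(p))
  amax <- apply(abs(L), 1, max)
  excluded <- items[amax < cutoff]
  keep <- amax >= cutoff
  ties <- character(0)
  assignment <- integer(sum(keep))
  kept_items <- items[keep]
  Lk <- L[keep, , drop = FALSE]
  for (i in seq_len(nrow(Lk))) {
    a <- abs(Lk[i, ])
    best <- which(a >= max(a) - 1e-12)
    if (length(best) > 1L) ties <- c(ties, kept_items[i])
    assignment[i] <- best[1]
  }
  n_spec <- ncol(L)
  tab <- tabulate(assignment, nbins = n_spec)
  if (any(tab > 0 & tab < 3))
    warning(sprintf("specific factor(s) %s have < 3 items: identification risk",
                    paste(which(tab > 0 & tab < 3), collapse = ", ")))
  structure(list(items = kept_items,
                 assignment = stats::setNames(assignment, kept_items),
                 n_specific = n_spec,
                 excluded = excluded, ties = ties, cutoff = cutoff),
            class = "bifactor_spec")
}

#' Construct a bifactor model specification directly
#'
#' Used when the item-to-factor configuration is known a priori (for example
#' the planted configuration of a simulation) rather than derived from an
#' EFA pattern via \code{\link{configure_bifactor}}.
#'
#' @param items character vector of item names.
#' @param assignment integer vector (one specific factor index per item; 0
#'   for an item loading on the general factor only, which nests the
#'   one-factor model).
#' @param n_specific number of specific factors.
#' @param cutoff salience cutoff carried along for pruning (default 0.30).
#' @return a \code{bifactor_spec}.
#' @export
bifactor_spec <- function(items, assignment, n_specific,
                          cutoff = 0.30) {
  stopifnot(length(items) == length(assignment),
            all(assignment %in% c(0L, seq_len(n_specific))))
  structure(list(items = items,
                 assignment = stats::setNames(as.integer(assignment), items),
                 n_specific = as.integer(n_specific),
                 excluded = character(0), ties = character(0),
                 cutoff = cutoff),
            class = "bifactor_spec")
}

# model-implied correlation matrix from general/specific loadings;
# assignment 0 marks general-only items (no shared specific variance)
.bifactor_sigma <- function(lg, ls, assignment) {
  S <- tcrossprod(lg)
  same <- outer(assignment, assignment, `==`) & assignment > 0
  S <- S + tcrossprod(ls) * same
  diag(S) <- 1
  S
}

#' Fit a bifactor model by unweighted least squares on a correlation matrix
#'
#' Minimizes \eqn{F = \sum_{i<j} (r_{ij} - \sigma_{ij}(\theta))^2} where
#' \eqn{\Sigma(\theta) = \lambda_g\lambda_g' + \sum_s \lambda_s\lambda_s' +
#' \mathrm{diag}(\psi)} with orthogonal general and specific factors and each
#' item on exactly one specific factor. Seeded multi-start L-BFGS-B with
#' analytic gradients; signs are canonicalized so every factor's mean loading
#' is non-negative. The chi-square analogue is \eqn{T = (N-1) F_{min}}; the
#' baseline (independence) model supplies \eqn{T_b}.
#'
#' @param R correlation matrix (or \code{mixed_cor}).
#' @param spec a \code{bifactor_spec}.
#' @param N number of subjects behind \code{R}.
#' @param n_starts optimization starts (default 5).
#' @param seed seed for start perturbations.
#' @return object of class \code{bifactor_fit}: \code{lambda_g},
#'   \code{lambda_s}, \code{psi}, \code{assignment}, \code{F_min}, \code{T},
#'   \code{df}, \code{T_baseline}, \code{df_baseline}, \code{N},
#'   \code{converged}, \code{R} (the matrix fitted), \code{Sigma}.
#' @export
fit_bifactor <- function(R, spec, N, n_starts = 5, seed = 1L) {
  if (inherits(R, "mixed_cor")) R <- R$R
  stopifnot(inherits(spec, "bifactor_spec"))
  idx <- match(spec$items, colnames(R))
  if (anyNA(idx)) stop("spec items missing from correlation matrix")
  R <- R[idx, idx, drop = FALSE]
  p <- length(spec$items)
  a <- unname(spec$assignment)
  same <- outer(a, a, `==`) & a > 0
  diag(same) <- FALSE
  off <- upper.tri(R)
  no_specific <- a == 0L

  obj <- function(par) {
    lg <- par[1:p]
    ls <- par[(p + 1):(2 * p)]
    E <- R - tcrossprod(lg) - tcrossprod(ls) * same
    diag(E) <- 0
    sum(E[off]^2)
  }
  grad <- function(par) {
    lg <- par[1:p]
    ls <- par[(p + 1):(2 * p)]
    E <- R - tcrossprod(lg) - tcrossprod(ls) * same
    diag(E) <- 0
    c(-2 * drop(E %*% lg), -2 * drop((E * same) %*% ls))
  }

  # principal-component start for the general factor
  e1 <- eigen(R, symmetric = TRUE)
  lg0 <- e1$vectors[, 1] * sqrt(max(e1$values[1], 0))
  if (mean(lg0) < 0) lg0 <- -lg0
  lg0 <- pmin(pmax(lg0, -0.9), 0.9)
  starts <- list(c(lg0, rep(0.3, p)))
  starts <- c(starts, .with_seed(.child_seed(seed, "bifactor"), {
    lapply(seq_len(n_starts - 1L), function(i)
      c(lg0 + stats::rnorm(p, 0, 0.1),
        stats::runif(p, 0.1, 0.5)))
  }))
  lower <- rep(-0.999, 2 * p)
  upper <- rep(0.999, 2 * p)
  # general-only items: specific loading pinned at zero
  lower[p + which(no_specific)] <- 0
  upper[p + which(no_specific)] <- 0
  starts <- lapply(starts, function(s) {
    s[p + which(no_specific)] <- 0
    s
  })

  best <- NULL
  trajectories <- list()
  for (s in starts) {
    fit <- tryCatch(
      stats::optim(s, obj, grad, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(maxit = 2000, factr = 1e3)),
      error = function(e) NULL)
    if (is.null(fit)) next
    trajectories[[length(trajectories) + 1L]] <- fit$value
    if (fit$convergence == 0 && (is.null(best) || fit$value < best$value))
      best <- fit
  }
  if (is.null(best))
    stop(paste0("bifactor fit failed to converge across starts; best F: ",
                paste(signif(unlist(trajectories), 6), collapse = ", ")))
  lg <- best$par[1:p]
  ls <- best$par[(p + 1):(2 * p)]
  if (mean(lg) < 0) lg <- -lg
  for (f in sort(unique(a[a > 0]))) {
    m <- a == f
    if (mean(ls[m]) < 0) ls[m] <- -ls[m]
  }
  # Heywood guard: shrink the loading pair of any item whose communality
  # exceeds 0.995 so uniqueness stays positive
  h2 <- lg^2 + ls^2
  hey <- h2 > 0.995
  if (any(hey)) {
    warning(sprintf("%d item(s) Heywood-capped at communality 0.995", sum(hey)))
    shrink <- sqrt(0.995 / h2[hey])
    lg[hey] <- lg[hey] * shrink
    ls[hey] <- ls[hey] * shrink
  }
  psi <- 1 - lg^2 - ls^2
  Sigma <- .bifactor_sigma(lg, ls, a)
  Fmin <- sum((R - Sigma)[off]^2)
  n_pairs <- p * (p - 1) / 2
  df <- n_pairs - 2 * p
  F_b <- sum(R[off]^2)
  names(lg) <- names(ls) <- names(psi) <- spec$items
  dimnames(Sigma) <- dimnames(R)
  structure(list(lambda_g = lg, lambda_s = ls, psi = psi,
                 assignment = spec$assignment,
                 F_min = Fmin, T = (N - 1) * Fmin, df = df,
                 T_baseline = (N - 1) * F_b, df_baseline = n_pairs,
                 N = N, converged = TRUE, R = R, Sigma = Sigma,
                 spec = spec),
            class = "bifactor_fit")
}

#' Iteratively prune weak specific loadings and refit
#'
#' Removes items whose absolute specific-factor loading falls below
#' \code{cutoff}, refits, and repeats until none remain below the cutoff or a
#' specific factor would drop under 3 items (that factor's items are then
#' frozen, with a warning). Mirrors pruning a model from its full item set
#' down to the items with salient within-factor associations.
#'
#' @param fit a converged \code{bifactor_fit}.
#' @param R full correlation matrix the fit came from.
#' @param N sample size.
#' @param cutoff pruning threshold on |specific loading| (default 0.30).
#' @param seed passed to refits.
#' @return list with \code{spec} (pruned), \code{fit} (refitted),
#'   \code{removed} audit data frame (item, round, lambda_s).
#' @export
prune_and_refit <- function(fit, R, N, cutoff = 0.30, seed = 1L) {
  if (inherits(R, "mixed_cor")) R <- R$R
  stopifnot(inherits(fit, "bifactor_fit"))
  spec <- fit$spec
  removed <- list()
  frozen_factors <- integer(0)
  round_i <- 0L
  repeat {
    round_i <- round_i + 1L
    ls <- fit$lambda_s
    a <- spec$assignment
    weak <- names(ls)[abs(ls) < cutoff & unname(a) > 0]
    weak <- weak[!(a[weak] %in% frozen_factors)]
    if (!length(weak)) break
    drop_now <- character(0)
    for (f in sort(unique(unname(a)))) {
      mem <- names(a)[a == f]
      wf <- intersect(weak, mem)
      if (!length(wf)) next
      if (length(mem) - length(wf) < 3) {
        # keep the 3-item identification floor: remove weakest first, then
        # freeze this factor against further pruning
        n_rm <- max(0L, length(mem) - 3L)
        wf <- wf[order(abs(ls[wf]))][seq_len(min(n_rm, length(wf)))]
        frozen_factors <- c(frozen_factors, f)
        warning(sprintf(
          "pruning frozen on specific factor %d at the 3-item floor", f))
      }
      drop_now <- c(drop_now, wf)
    }
    if (!length(drop_now)) break
    for (v in drop_now)
      removed[[length(removed) + 1L]] <-
        data.frame(item = v, round = round_i, lambda_s = unname(ls[v]))
    keep <- setdiff(spec$items, drop_now)
    if (length(keep) < 3) stop("pruning would empty the model")
    spec <- structure(list(items = keep,
                           assignment = spec$assignment[keep],
                           n_specific = spec$n_specific,
                           excluded = c(spec$excluded, drop_now),
                           ties = spec$ties, cutoff = spec$cutoff),
                      class = "bifactor_spec")
    fit <- fit_bifactor(R, spec, N, seed = seed)
  }
  removed_df <- if (length(removed)) do.call(rbind, removed)
  else data.frame(item = character(0), round = integer(0),
                  lambda_s = numeric(0))
  list(spec = spec, fit = fit, removed = removed_df)
}

#' Global fit indices from a bifactor fit
#'
#' \deqn{RMSEA = \sqrt{\max(T - df, 0)/(df (N-1))}}
#' \deqn{CFI = 1 - \max(T - df, 0) / \max(T_b - df_b, T - df, 0)}
#' \deqn{SRMR = \sqrt{\mathrm{mean}_{i<j} (r_{ij} - \hat\sigma_{ij})^2}}
#'
#' @param fit a \code{bifactor_fit}, or a list carrying fields \code{T},
#'   \code{df}, \code{N}, \code{T_baseline}, \code{df_baseline} (and, for
#'   SRMR, \code{R} and \code{Sigma}).
#' @return list with \code{cfi}, \code{rmsea}, \code{srmr} (SRMR is NA when
#'   residuals are unavailable).
#' @export
fit_indices <- function(fit) {
  if (fit$df <= 0) stop("model is saturated (df <= 0)")
  Tst <- fit$T
  df <- fit$df
  num <- max(Tst - df, 0)
  rmsea <- sqrt(num / (df * (fit$N - 1)))
  denom <- max(fit$T_baseline - fit$df_baseline, Tst - df, 0)
  cfi <- if (denom == 0) 1 else 1 - num / denom
  srmr <- NA_real_
  if (!is.null(fit$R) && !is.null(fit$Sigma)) {
    off <- upper.tri(fit$R)
    srmr <- sqrt(mean((fit$R - fit$Sigma)[off]^2))
  }
  list(cfi = cfi, rmsea = rmsea, srmr = srmr)
}

# full orthogonal loading block [lambda_g | specific columns]
.bifactor_lambda <- function(fit) {
  p <- length(fit$lambda_g)
  a <- unname(fit$assignment)
  ns <- fit$spec$n_specific
  L <- matrix(0, p, 1 + ns)
  L[, 1] <- fit$lambda_g
  has_s <- a > 0
  L[cbind(which(has_s), a[has_s] + 1L)] <- fit$lambda_s[has_s]
  colnames(L) <- c("general", paste0("specific", seq_len(ns)))
  rownames(L) <- names(fit$lambda_g)
  L
}

#' Bifactor reliability and determinacy indices
#'
#' Explained common variance
#' \eqn{ECV = \sum \lambda_g^2 / (\sum \lambda_g^2 + \sum_s \sum \lambda_s^2)},
#' omega-hierarchical
#' \eqn{\omega_H = (\sum\lambda_g)^2 / ((\sum\lambda_g)^2 +
#'   \sum_s (\sum_{i \in s}\lambda_s)^2 + \sum\psi)},
#' per-subfactor \eqn{\omega_{HS}} (subfactor variance over total variance of
#' its item set), and factor determinacy
#' \eqn{FD_f = \sqrt{[\Lambda' R^{-1} \Lambda]_{ff}}} using the full
#' orthogonal loading block.
#'
#' @param fit a \code{bifactor_fit}.
#' @param R correlation matrix for determinacy (defaults to the model-implied
#'   matrix).
#' @return list with \code{ecv}, \code{omega_h}, \code{omega_hs} (per
#'   subfactor; NA where a subfactor has no loadings), \code{fd} (per
#'   factor, general first).
#' @export
bifactor_indices <- function(fit, R = fit$Sigma) {
  lg <- fit$lambda_g
  ls <- fit$lambda_s
  psi <- fit$psi
  a <- unname(fit$assignment)
  ns <- fit$spec$n_specific
  ecv <- sum(lg^2) / (sum(lg^2) + sum(ls^2))
  sum_s2 <- vapply(seq_len(ns), function(f) sum(ls[a == f])^2, numeric(1))
  omega_h <- sum(lg)^2 / (sum(lg)^2 + sum(sum_s2) + sum(psi))
  omega_hs <- vapply(seq_len(ns), function(f) {
    m <- a == f
    if (!any(m) || sum(abs(ls[m])) < 1e-12) return(NA_real_)
    sum(ls[m])^2 / (sum(lg[m])^2 + sum(ls[m])^2 + sum(psi[m]))
  }, numeric(1))
  L <- .bifactor_lambda(fit)
  Ri <- tryCatch(solve(R), error = function(e) {
    warning("singular correlation matrix; ridge 1e-8 applied")
    solve(R + diag(1e-8, ncol(R)))
  })
  fd2 <- diag(t(L) %*% Ri %*% L)
  fd <- sqrt(pmax(pmin(fd2, 1), 0))
  names(fd) <- colnames(L)
  list(ecv = ecv, omega_h = omega_h,
       omega_hs = stats::setNames(omega_hs,
                                  paste0("specific", seq_len(ns))),
       fd = fd)
}

#' Standardize item columns for factor scoring
#'
#' Continuous items are z-scored. Ordinal/binary items are replaced by their
#' conditional-normal scores: category c maps to the mean of a standard
#' normal truncated to the category's threshold interval,
#' \eqn{(\phi(\tau_{c-1}) - \phi(\tau_c)) / (\Phi(\tau_c) - \Phi(\tau_{c-1}))},
#' then z-scored — keeping scoring consistent with the latent-response model
#' behind the polychoric correlations.
#'
#' @param items item data frame.
#' @param manifest variable manifest.
#' @param thresholds named list of threshold vectors per ordinal variable
#'   (as returned in \code{mixed_cor$thresholds}); estimated from margins
#'   when NULL.
#' @return numeric matrix of standardized scores (NAs propagated).
#' @export
standardize_items <- function(items, manifest, thresholds = NULL) {
  lev <- manifest$level[match(names(items), manifest$name)]
  out <- matrix(NA_real_, nrow(items), ncol(items),
                dimnames = list(NULL, names(items)))
  for (j in seq_along(items)) {
    x <- items[[j]]
    if (lev[j] == "continuous") {
      out[, j] <- as.numeric(scale(x))
    } else {
      obs <- x[!is.na(x)]
      cats <- sort(unique(obs))
      tau <- thresholds[[names(items)[j]]]
      if (is.null(tau))
        tau <- estimate_thresholds(tabulate(match(obs, cats)))$tau
      tt <- c(-Inf, tau, Inf)
      mu <- (stats::dnorm(tt[-length(tt)]) - stats::dnorm(tt[-1])) /
        (stats::pnorm(tt[-1]) - stats::pnorm(tt[-length(tt)]))
      v <- mu[match(x, cats)]
      out[, j] <- (v - mean(v, na.rm = TRUE)) / stats::sd(v, na.rm = TRUE)
    }
  }
  out
}

#' Regression-method factor scores from a bifactor fit
#'
#' \eqn{\hat F = X R^{-1} \Lambda} on listwise-complete standardized rows;
#' columns are re-standardized and returned with their determinacies. Rows
#' with missing entries are dropped (count reported).
#'
#' @param X standardized item matrix (from \code{\link{standardize_items}});
#'   columns must cover the fitted items.
#' @param fit a \code{bifactor_fit}.
#' @param R correlation matrix used for the weights (defaults to the matrix
#'   the model was fitted to).
#' @return object of class \code{factor_scores}: \code{scores} (subjects x
#'   (1 + n_specific)), \code{determinacy}, \code{n_dropped},
#'   \code{rows_used} (logical index into X).
#' @export
factor_scores <- function(X, fit, R = fit$R) {
  L <- .bifactor_lambda(fit)
  X <- X[, rownames(L), drop = FALSE]
  complete <- stats::complete.cases(X)
  n_dropped <- sum(!complete)
  Xc <- X[complete, , drop = FALSE]
  if (!nrow(Xc)) stop("no listwise-complete rows to score")
  R <- R[rownames(L), rownames(L)]
  W <- solve(R, L)
  S <- Xc %*% W
  S <- scale(S)
  attr(S, "scaled:center") <- NULL
  attr(S, "scaled:scale") <- NULL
  det <- bifactor_indices(fit, R = R)$fd
  structure(list(scores = S, determinacy = det,
                 n_dropped = n_dropped, rows_used = complete),
            class = "factor_scores")
}
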