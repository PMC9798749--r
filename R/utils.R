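# Internal helpers shared across modules.

# Derive a reproducible child seed from a base seed and a stage label.
# Kept below 2^31 - 1 so it is always a valid R integer seed.
.child_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483629)
}

# Evaluate expr under a local RNG state seeded with `seed`.
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Canonicalize a loading matrix: order columns by decreasing sum of squared
# loadings, make the first non-negligible entry of each column non-negative.
.canonicalize_loadings <- function(L, Phi = NULL, tol = 1e-8) {
  ss <- colSums(L^2)
  ord <- order(ss, decreasing = TRUE)
  L <- L[, ord, drop = FALSE]
  if (!is.null(Phi)) Phi <- Phi[ord, ord, drop = FALSE]
  for (j in seq_len(ncol(L))) {
    nz <- which(abs(L[, j]) > tol)
    if (length(nz) && L[nz[1], j] < 0) {
      L[, j] <- -L[, j]
      if (!is.null(Phi)) {
        Phi[j, ] <- -Phi[j, ]
        Phi[, j] <- -Phi[, j]
      }
    }
  }
  if (is.null(Phi)) list(loadings = L) else list(loadings = L, Phi = Phi)
}

# Tucker congruence between two loading vectors.
.congruence <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))

#' Align estimated loadings to a reference matrix
#'
#' Factor solutions are identified only up to column permutation and sign.
#' Greedily matches columns of \code{L} to \code{truth} by absolute Tucker
#' congruence and flips signs to agree — the standard bookkeeping step in
#' plant-and-recover studies.
#'
#' @param L estimated loading matrix.
#' @param truth reference loading matrix with the same dimensions.
#' @param Phi optional factor correlation matrix permuted/signed alongside.
#' @return list with aligned \code{loadings} (and \code{Phi}), the
#'   \code{perm}utation and \code{sign} flips applied.
#' @export
align_loadings <- function(L, truth, Phi = NULL) {
  k <- ncol(truth)
  stopifnot(ncol(L) == k)
  cong <- abs(crossprod(truth, L) /
                outer(sqrt(colSums(truth^2)), sqrt(colSums(L^2))))
  perm <- integer(k)
  for (step in seq_len(k)) {
    best <- which(cong == max(cong), arr.ind = TRUE)[1, ]
    perm[best[1]] <- best[2]
    cong[best[1], ] <- -Inf
    cong[, best[2]] <- -Inf
  }
  La <- L[, perm, drop = FALSE]
  sgn <- sign(colSums(truth * La))
  sgn[sgn == 0] <- 1
  La <- sweep(La, 2, sgn, `*`)
  if (is.null(Phi)) return(list(loadings = La, perm = perm, sign = sgn))
  Pa <- Phi[perm, perm, drop = FALSE]
  Pa <- diag(sgn) %*% Pa %*% diag(sgn)
  dimnames(Pa) <- NULL
  list(loadings = La, Phi = Pa, perm = perm, sign = sgn)
}

# Write a numeric data frame as CSV with values rounded to 6 decimals so
# content hashes are stable across platforms.
.write_csv_rounded <- function(df, path, digits = 6) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) round(x, digits))
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}
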