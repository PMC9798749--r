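#' Specify a planted bifactor generating model
#'
#' Defines the population from which synthetic cohorts are drawn: every item
#' loads on one general factor and exactly one of \code{n_specific} orthogonal
#' specific factors; latent responses are discretized at item thresholds for
#' ordinal/binary items; latent scores share a family component inducing an
#' exchangeable intra-family correlation.
#'
#' @param n_subjects number of subjects.
#' @param n_specific number of specific (domain) factors.
#' @param loading_general numeric vector of general-factor loadings, one per
#'   item, each in \[0, 1).
#' @param loading_specific numeric vector of specific-factor loadings, one per
#'   item, each in \[0, 1).
#' @param item_factor integer vector assigning each item to a specific factor
#'   (1..n_specific).
#' @param item_levels character vector per item: \code{"continuous"},
#'   \code{"ordinal"} or \code{"binary"}.
#' @param thresholds list of strictly increasing threshold vectors for
#'   ordinal/binary items (length k-1 for a k-category item); \code{NULL}
#'   entries for continuous items.
#' @param cluster_sizes integer vector of family sizes summing to
#'   \code{n_subjects}; defaults to singleton families.
#' @param icc_family intra-family correlation of latent scores in \[0, 1).
#' @param missing_rate MCAR missingness proportion in \[0, 1).
#' @param seed integer seed.
#' @return an object of class \code{generative_spec}.
#' @export
generative_spec <- function(n_subjects,
                            n_specific,
                            loading_general,
                            loading_specific,
                            item_factor,
                            item_levels = NULL,
                            thresholds = NULL,
                            cluster_sizes = NULL,
                            icc_family = 0,
                            missing_rate = 0,
                            seed = 1L) {
  p <- length(loading_general)
  stopifnot(length(loading_specific) == p, length(item_factor) == p)
  if (is.null(item_levels)) item_levels <- rep("continuous", p)
  stopifnot(length(item_levels) == p,
            all(item_levels %in% c("continuous", "ordinal", "binary")))
  if (is.null(thresholds)) thresholds <- vector("list", p)
  stopifnot(length(thresholds) == p)
  if (any(loading_general < 0 | loading_general >= 1))
    stop("general loadings must lie in [0, 1)")
  if (any(loading_specific < 0 | loading_specific >= 1))
    stop("specific loadings must lie in [0, 1)")
  uni <- 1 - loading_general^2 - loading_specific^2
  if (any(uni <= 0))
    stop("every item needs positive uniqueness: lambda_g^2 + lambda_s^2 < 1")
  if (!all(item_factor %in% seq_len(n_specific)))
    stop("item_factor entries must reference a specific factor")
  if (icc_family < 0 || icc_family >= 1)
    stop("icc_family must lie in [0, 1)")
  if (missing_rate < 0 || missing_rate >= 1)
    stop("missing_rate must lie in [0, 1)")
  for (i in seq_len(p)) {
    lev <- item_levels[i]
    tau <- thresholds[[i]]
    if (lev == "continuous") {
      if (!is.null(tau)) stop("continuous items take no thresholds")
    } else {
      if (is.null(tau) || length(tau) < 1L)
        stop(sprintf("item %d (%s) needs at least one threshold", i, lev))
      if (lev == "binary" && length(tau) != 1L)
        stop("binary items take exactly one threshold")
      if (any(!is.finite(tau)) || any(diff(tau) <= 0))
        stop(sprintf("thresholds of item %d must be finite, strictly increasing", i))
    }
  }
  if (is.null(cluster_sizes)) cluster_sizes <- rep(1L, n_subjects)
  if (sum(cluster_sizes) != n_subjects)
    stop("cluster_sizes must sum to n_subjects")
  structure(list(n_subjects = as.integer(n_subjects),
                 n_specific = as.integer(n_specific),
                 loading_general = loading_general,
                 loading_specific = loading_specific,
                 item_factor = as.integer(item_factor),
                 item_levels = item_levels,
                 thresholds = thresholds,
                 cluster_sizes = as.integer(cluster_sizes),
                 icc_family = icc_family,
                 missing_rate = missing_rate,
                 seed = as.integer(seed)),
            class = "generative_spec")
}

#' Population correlation matrix implied by a generative spec
#'
#' \eqn{R = \Lambda \Lambda' + \mathrm{diag}(\psi)} with
#' \eqn{\Lambda = [\lambda_g | \lambda_{s,1} | ... ]}, the closed form against
#' which sampled correlation matrices converge.
#'
#' @param spec a \code{generative_spec}.
#' @return a correlation matrix.
#' @export
population_correlation <- function(spec) {
  L <- planted_loadings(spec)
  R <- tcrossprod(L)
  diag(R) <- 1
  dimnames(R) <- list(item_names(spec), item_names(spec))
  R
}

#' Planted orthogonal loading matrix (general column first)
#' @param spec a \code{generative_spec}.
#' @return items x (1 + n_specific) matrix.
#' @export
planted_loadings <- function(spec) {
  p <- length(spec$loading_general)
  L <- matrix(0, p, 1 + spec$n_specific)
  L[, 1] <- spec$loading_general
  L[cbind(seq_len(p), spec$item_factor + 1L)] <- spec$loading_specific
  colnames(L) <- c("general", paste0("specific", seq_len(spec$n_specific)))
  rownames(L) <- item_names(spec)
  L
}

item_names <- function(spec) sprintf("item%03d", seq_along(spec$loading_general))

#' Simulate latent factor scores with family clustering
#'
#' Draws subjects x (1 + n_specific) standard-normal scores, mutually
#' independent across columns in the population. Within a family each column
#' is an equicorrelated mixture \eqn{\sqrt{icc}\,u_{fam} + \sqrt{1-icc}\,e},
#' so the intra-family correlation equals \code{icc_family}.
#'
#' @param spec a \code{generative_spec}.
#' @return data frame with \code{family_id} and score columns
#'   \code{general}, \code{specific1}, ...
#' @export
simulate_latent_scores <- function(spec) {
  stopifnot(inherits(spec, "generative_spec"))
  n <- spec$n_subjects
  k <- 1 + spec$n_specific
  fam <- rep(seq_along(spec$cluster_sizes), times = spec$cluster_sizes)
  .with_seed(.child_seed(spec$seed, "latent"), {
    scores <- matrix(NA_real_, n, k)
    icc <- spec$icc_family
    for (j in seq_len(k)) {
      u <- stats::rnorm(length(spec$cluster_sizes))[fam]
      e <- stats::rnorm(n)
      scores[, j] <- sqrt(icc) * u + sqrt(1 - icc) * e
    }
    colnames(scores) <- c("general", paste0("specific", seq_len(spec$n_specific)))
    data.frame(family_id = fam, scores)
  })
}

#' Simulate item responses from latent scores
#'
#' Each item's latent response is
#' \eqn{y^* = \lambda_g g + \lambda_s s + \sqrt{\psi}\,\epsilon}; continuous
#' items return \eqn{y^*} directly, ordinal/binary items discretize it at the
#' item thresholds into categories 0..k-1. MCAR missingness is applied last.
#'
#' @param latent data frame from \code{\link{simulate_latent_scores}}.
#' @param spec the same \code{generative_spec}.
#' @return data frame of item columns (plus nothing else); ordinal columns are
#'   integer-coded 0..k-1 with NA for missing.
#' @export
simulate_item_responses <- function(latent, spec) {
  stopifnot(inherits(spec, "generative_spec"))
  scores <- as.matrix(latent[, c("general",
                                 paste0("specific", seq_len(spec$n_specific))),
                             drop = FALSE])
  n <- nrow(scores)
  p <- length(spec$loading_general)
  L <- planted_loadings(spec)
  uni <- 1 - rowSums(L^2)
  .with_seed(.child_seed(spec$seed, "items"), {
    eps <- matrix(stats::rnorm(n * p), n, p)
    ystar <- scores %*% t(L) + eps %*% diag(sqrt(uni), p)
    out <- as.data.frame(ystar)
    names(out) <- item_names(spec)
    for (i in seq_len(p)) {
      if (spec$item_levels[i] != "continuous") {
        tau <- spec$thresholds[[i]]
        out[[i]] <- as.integer(findInterval(ystar[, i], tau))
      }
    }
    if (spec$missing_rate > 0) {
      miss <- matrix(stats::runif(n * p) < spec$missing_rate, n, p)
      for (i in seq_len(p)) out[[i]][miss[, i]] <- NA
    }
    out
  })
}

#' Specify planted outcome effects
#'
#' Standardized effects of the general factor, the specific factors and the
#' covariates on a continuous outcome (variance 1 in population, so the
#' squared betas sum to the model R-squared), plus a planted odds ratio per
#' binary outcome for a one-SD increase in the general factor.
#'
#' @param beta_general standardized effect of the general factor.
#' @param beta_specific vector of specific-factor effects.
#' @param beta_covariates named vector of covariate effects (on the
#'   standardized covariate scale).
#' @param logistic_or_general odds ratio of the general factor for binary
#'   outcomes (applies to both obesity and puberty outcomes).
#' @param prevalence named vector of marginal prevalences for the binary
#'   outcomes \code{obesity} and \code{puberty}.
#' @param seed integer seed.
#' @return an object of class \code{outcome_spec}.
#' @export
outcome_spec <- function(beta_general,
                         beta_specific,
                         beta_covariates = c(age = 0.15, sex = 0.1323),
                         logistic_or_general = 1.41,
                         prevalence = c(obesity = 0.167, puberty = 0.065),
                         seed = 1L) {
  r2 <- beta_general^2 + sum(beta_specific^2) + sum(beta_covariates^2)
  if (r2 >= 1)
    stop(sprintf("implied R^2 of the continuous outcome is %.3f >= 1", r2))
  if (logistic_or_general <= 0) stop("odds ratio must be positive")
  structure(list(beta_general = beta_general,
                 beta_specific = beta_specific,
                 beta_covariates = beta_covariates,
                 r2 = r2,
                 logistic_or_general = logistic_or_general,
                 prevalence = prevalence,
                 seed = as.integer(seed)),
            class = "outcome_spec")
}

#' Simulate demographic covariates
#'
#' Standard-normal age score, 0/1 sex, and a 0/1 low-income indicator used by
#' the demographic-contrast stage. Age and sex are independent of the latent
#' factors; \code{income_low} is obtained by thresholding a normal deviate
#' correlated \code{income_cor} with the general factor, so low-income
#' subjects sit higher on the general exposome score.
#'
#' @param latent data frame from \code{\link{simulate_latent_scores}}.
#' @param p_low_income proportion in the low-income group.
#' @param income_cor correlation between the income liability and the general
#'   factor.
#' @param seed integer seed.
#' @return data frame of covariates.
#' @export
simulate_covariates <- function(latent, p_low_income = 0.3,
                                income_cor = 0.5, seed = 1L) {
  n <- nrow(latent)
  g <- latent$general
  .with_seed(.child_seed(seed, "covariates"), {
    liab <- income_cor * g + sqrt(1 - income_cor^2) * stats::rnorm(n)
    data.frame(age = stats::rnorm(n),
               sex = stats::rbinom(n, 1, 0.5),
               income_low = as.integer(liab > stats::qnorm(1 - p_low_income)))
  })
}

#' Simulate continuous and binary outcomes with planted effects
#'
#' The continuous outcome is
#' \eqn{y = \beta_g g + \sum_s \beta_s s + \beta_c' C + \sigma\epsilon}
#' with \eqn{\sigma^2 = 1 - R^2}, standardized in population. Binary outcomes
#' follow a logistic model with coefficient \eqn{\log(OR)} on the general
#' factor and intercept set to hit the requested marginal prevalence at
#' \eqn{g = 0}.
#'
#' @param latent data frame from \code{\link{simulate_latent_scores}}.
#' @param covariates aligned covariate data frame containing the columns
#'   named by \code{ospec$beta_covariates}.
#' @param ospec an \code{outcome_spec}.
#' @return data frame with columns \code{y}, \code{obesity}, \code{puberty}.
#' @export
simulate_outcomes <- function(latent, covariates, ospec) {
  stopifnot(inherits(ospec, "outcome_spec"),
            nrow(latent) == nrow(covariates))
  ns <- length(ospec$beta_specific)
  g <- latent$general
  S <- as.matrix(latent[, paste0("specific", seq_len(ns)), drop = FALSE])
  covn <- names(ospec$beta_covariates)
  stopifnot(all(covn %in% names(covariates)))
  C <- scale(as.matrix(covariates[, covn, drop = FALSE]))
  n <- length(g)
  .with_seed(.child_seed(ospec$seed, "outcomes"), {
    lin <- ospec$beta_general * g +
      drop(S %*% ospec$beta_specific) +
      drop(C %*% ospec$beta_covariates)
    y <- lin + sqrt(1 - ospec$r2) * stats::rnorm(n)
    b <- log(ospec$logistic_or_general)
    out <- data.frame(y = y)
    for (nm in names(ospec$prevalence)) {
      alpha <- stats::qlogis(ospec$prevalence[[nm]])
      out[[nm]] <- stats::rbinom(n, 1, stats::plogis(alpha + b * g))
    }
    out
  })
}

#' Default cohort design emulating a mixed-format exposure panel
#'
#' One general factor plus \code{n_specific} domain factors with
#' \code{items_per_factor} items each; item formats cycle through continuous,
#' 4-category ordinal, 3-category ordinal and binary; loadings alternate
#' moderately strong general (0.45-0.6) and specific (0.4-0.55) values.
#'
#' @param n_subjects,n_specific,items_per_factor cohort dimensions.
#' @param icc_family,missing_rate,seed passed through.
#' @param levels recycled vector of item formats.
#' @return a \code{generative_spec}.
#' @export
default_cohort_spec <- function(n_subjects = 3000,
                                n_specific = 4,
                                items_per_factor = 10,
                                icc_family = 0.3,
                                missing_rate = 0.02,
                                seed = 1L,
                                levels = c("continuous", "ordinal",
                                           "ordinal", "binary")) {
  p <- n_specific * items_per_factor
  item_factor <- rep(seq_len(n_specific), each = items_per_factor)
  lg <- rep(c(0.60, 0.45, 0.55, 0.50), length.out = p)
  ls <- rep(c(0.40, 0.55, 0.45, 0.50), length.out = p)
  lev <- rep(levels, length.out = p)
  thr <- vector("list", p)
  for (i in seq_len(p)) {
    if (lev[i] == "binary") thr[[i]] <- 0
    else if (lev[i] == "ordinal")
      thr[[i]] <- if (i %% 2 == 0) c(-0.8, 0.3, 1.0) else c(-0.5, 0.7)
  }
  fam_sizes <- rep(c(2L, 1L, 1L), length.out = ceiling(n_subjects / 1.25))
  fam_sizes <- fam_sizes[cumsum(fam_sizes) <= n_subjects]
  if (sum(fam_sizes) < n_subjects)
    fam_sizes <- c(fam_sizes, n_subjects - sum(fam_sizes))
  generative_spec(n_subjects = n_subjects,
                  n_specific = n_specific,
                  loading_general = lg,
                  loading_specific = ls,
                  item_factor = item_factor,
                  item_levels = lev,
                  thresholds = thr,
                  cluster_sizes = fam_sizes,
                  icc_family = icc_family,
                  missing_rate = missing_rate,
                  seed = seed)
}

#' Simulate a complete synthetic cohort
#'
#' Latent scores, item responses, covariates and outcomes in one call,
#' together with the variable manifest describing each item's measurement
#' level — the full substrate for the analysis pipeline.
#'
#' @param spec a \code{generative_spec}.
#' @param ospec an \code{outcome_spec} (defaults mirror a cohort where the
#'   exposome factors explain ~38\% of outcome variance against ~4\% for
#'   demographics alone).
#' @return list with \code{items}, \code{latent}, \code{covariates},
#'   \code{outcomes}, \code{manifest}, \code{spec}, \code{ospec}.
#' @export
simulate_cohort <- function(spec, ospec = NULL) {
  if (is.null(ospec)) {
    ns <- spec$n_specific
    ospec <- outcome_spec(beta_general = 0.285,
                          beta_specific = rep(sqrt(0.2588 / ns), ns),
                          seed = spec$seed)
  }
  latent <- simulate_latent_scores(spec)
  items <- simulate_item_responses(latent, spec)
  covariates <- simulate_covariates(latent, seed = spec$seed)
  outcomes <- simulate_outcomes(latent, covariates, ospec)
  list(items = items,
       latent = latent,
       covariates = covariates,
       outcomes = outcomes,
       manifest = manifest_from_spec(spec),
       spec = spec,
       ospec = ospec)
}

#' Variable manifest implied by a generative spec
#' @param spec a \code{generative_spec}.
#' @return data frame with columns \code{name}, \code{level},
#'   \code{n_categories}, \code{block}.
#' @export
manifest_from_spec <- function(spec) {
  p <- length(spec$loading_general)
  ncat <- vapply(seq_len(p), function(i) {
    if (spec$item_levels[i] == "continuous") NA_integer_
    else length(spec$thresholds[[i]]) + 1L
  }, integer(1))
  data.frame(name = item_names(spec),
             level = spec$item_levels,
             n_categories = ncat,
             block = paste0("domain", spec$item_factor),
             stringsAsFactors = FALSE)
}

#' Write a simulated cohort to CSV files
#'
#' Items, covariates, outcomes and manifest as CSV; the generative spec as
#' JSON. Missing values are written as empty fields.
#'
#' @param cohort list from \code{\link{simulate_cohort}}.
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of file paths.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(items = file.path(dir, "items.csv"),
             covariates = file.path(dir, "covariates.csv"),
             outcomes = file.path(dir, "outcomes.csv"),
             latent = file.path(dir, "latent.csv"),
             manifest = file.path(dir, "manifest.csv"),
             spec = file.path(dir, "spec.json"))
  .write_csv_rounded(cbind(family_id = cohort$latent$family_id, cohort$items),
                     paths[["items"]])
  .write_csv_rounded(cohort$covariates, paths[["covariates"]])
  .write_csv_rounded(cohort$outcomes, paths[["outcomes"]])
  .write_csv_rounded(cohort$latent, paths[["latent"]])
  utils::write.csv(cohort$manifest, paths[["manifest"]], row.names = FALSE)
  spec_json <- cohort$spec
  spec_json$thresholds <- lapply(spec_json$thresholds,
                                 function(t) if (is.null(t)) NA else t)
  jsonlite::write_json(unclass(spec_json), paths[["spec"]],
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(paths)
}
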