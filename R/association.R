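# Association models: how exposome factor scores relate to outcomes.

# z-score numeric columns with more than two distinct values; leave 0/1
# indicator columns untouched so their coefficients stay interpretable.
.standardize_design <- function(df) {
  for (nm in names(df)) {
    x <- df[[nm]]
    if (is.numeric(x) && length(unique(x[!is.na(x)])) > 2L)
      df[[nm]] <- as.numeric(scale(x))
  }
  df
}

#' Standardized linear regression with adjusted R-squared
#'
#' All continuous variables (outcome, predictors, covariates) are z-scored
#' before an OLS fit on listwise-complete rows, so coefficients are
#' standardized betas. Indicator (0/1) covariates are left on their original
#' scale.
#'
#' @param y continuous outcome.
#' @param predictors data frame of predictors of interest.
#' @param covariates optional data frame of adjustment covariates.
#' @return list with \code{coefficients} data frame (term, beta, se, p),
#'   \code{r2}, \code{adj_r2}, \code{n}.
#' @export
standardized_linear_model <- function(y, predictors, covariates = NULL) {
  dat <- data.frame(.y = y, predictors, check.names = TRUE)
  if (!is.null(covariates) && ncol(covariates))
    dat <- cbind(dat, covariates)
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  dat <- .standardize_design(dat)
  fit <- stats::lm(.y ~ ., data = dat)
  if (anyNA(stats::coef(fit))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("design matrix is rank deficient; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  sm <- summary(fit)
  co <- sm$coefficients
  co <- co[rownames(co) != "(Intercept)", , drop = FALSE]
  list(coefficients = data.frame(term = rownames(co),
                                 beta = co[, 1], se = co[, 2],
                                 p = co[, 4], row.names = NULL),
       r2 = sm$r.squared,
       adj_r2 = sm$adj.r.squared,
       n = nrow(dat))
}

#' Change in adjusted R-squared between nested models
#'
#' Fits the covariate-only base model and the full model (covariates plus
#' added predictors) on the same listwise-complete rows and reports both
#' adjusted R-squared values, their difference, and their ratio.
#'
#' @param y continuous outcome.
#' @param base_covariates data frame for the base model (may have 0 columns
#'   for an intercept-only base).
#' @param added_predictors data frame of predictors added in the full model.
#' @return list with \code{adj_r2_base}, \code{adj_r2_full}, \code{delta},
#'   \code{ratio}, \code{n}.
#' @export
delta_r2 <- function(y, base_covariates, added_predictors) {
  if (length(intersect(names(base_covariates), names(added_predictors))))
    stop("added predictors already appear in the base model")
  dat <- data.frame(.y = y, check.names = TRUE)
  if (!is.null(base_covariates) && ncol(base_covariates))
    dat <- cbind(dat, base_covariates)
  dat <- cbind(dat, added_predictors)
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  dat <- .standardize_design(dat)
  base_terms <- setdiff(names(dat), c(".y", names(added_predictors)))
  f_base <- if (length(base_terms))
    stats::reformulate(base_terms, response = ".y") else .y ~ 1
  fit_base <- stats::lm(f_base, data = dat)
  fit_full <- stats::lm(.y ~ ., data = dat)
  a_base <- summary(fit_base)$adj.r.squared
  a_full <- summary(fit_full)$adj.r.squared
  list(adj_r2_base = a_base, adj_r2_full = a_full,
       delta = a_full - a_base,
       ratio = if (a_base > 0) a_full / a_base else NA_real_,
       n = nrow(dat))
}

#' Binary logistic regression with odds ratios and Wald intervals
#'
#' Maximum-likelihood logistic fit on listwise-complete rows; continuous
#' predictors are z-scored so each OR refers to a one-SD increase.
#'
#' @param y binary outcome (0/1).
#' @param predictors data frame of predictors of interest.
#' @param covariates optional adjustment covariates.
#' @return list with \code{table} data frame (term, or, ci_lower, ci_upper,
#'   p), \code{n}.
#' @export
logistic_model <- function(y, predictors, covariates = NULL) {
  yv <- y[!is.na(y)]
  if (length(unique(yv)) < 2L) stop("outcome must contain both classes")
  dat <- data.frame(.y = y, predictors, check.names = TRUE)
  if (!is.null(covariates) && ncol(covariates))
    dat <- cbind(dat, covariates)
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  dat <- .standardize_design(dat)
  fit <- suppressWarnings(
    stats::glm(.y ~ ., family = stats::binomial(), data = dat))
  co <- summary(fit)$coefficients
  co <- co[rownames(co) != "(Intercept)", , drop = FALSE]
  if (!fit$converged || any(abs(co[, 1]) > 15))
    stop("separation suspected (diverging coefficient); ",
         "consider a penalized fit")
  or <- exp(co[, 1])
  ci_l <- exp(co[, 1] - 1.96 * co[, 2])
  ci_u <- exp(co[, 1] + 1.96 * co[, 2])
  list(table = data.frame(term = rownames(co), or = or,
                          ci_lower = ci_l, ci_upper = ci_u,
                          p = co[, 4], row.names = NULL),
       n = nrow(dat))
}

#' Two-group contrast with Welch t-test and Cohen's d
#'
#' Welch (unequal-variance) t-test between two groups, classic pooled-SD
#' Cohen's d (group1 minus group2 in the order of the group factor levels),
#' and Bonferroni adjustment over \code{m_comparisons} planned contrasts.
#'
#' @param score numeric score.
#' @param group two-level grouping vector.
#' @param m_comparisons Bonferroni family size (default 7, the number of
#'   demographic contrasts run per factor).
#' @return list with \code{means}, \code{t}, \code{df}, \code{p},
#'   \code{p_adjusted}, \code{d}, \code{n}.
#' @export
group_contrast <- function(score, group, m_comparisons = 7) {
  ok <- !is.na(score) & !is.na(group)
  score <- score[ok]
  group <- factor(group[ok])
  if (nlevels(group) != 2L) stop("exactly two groups required")
  g1 <- score[group == levels(group)[1]]
  g2 <- score[group == levels(group)[2]]
  if (length(g1) < 2L || length(g2) < 2L)
    stop("each group needs at least 2 observations")
  tt <- stats::t.test(g1, g2)
  sp <- sqrt(((length(g1) - 1) * stats::var(g1) +
                (length(g2) - 1) * stats::var(g2)) /
               (length(g1) + length(g2) - 2))
  d <- (mean(g1) - mean(g2)) / sp
  list(means = stats::setNames(c(mean(g1), mean(g2)), levels(group)),
       t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value,
       p_adjusted = min(1, m_comparisons * tt$p.value),
       d = d, n = c(length(g1), length(g2)))
}

#' Linear mixed model with site and family random intercepts
#'
#' REML fit of \code{y ~ predictors + (1|site) + (1|family)} — the
#' sensitivity analysis checking that fixed effects survive accounting for
#' clustering. Continuous variables are z-scored as in
#' \code{\link{standardized_linear_model}}.
#'
#' @param y continuous outcome.
#' @param predictors data frame of fixed-effect predictors.
#' @param site_id,family_id cluster labels covering all rows.
#' @return list with \code{fixed} data frame (term, estimate, se, t),
#'   \code{variance_components} (site, family, residual), \code{n}.
#' @export
cluster_random_intercept_model <- function(y, predictors, site_id, family_id) {
  stopifnot(length(site_id) == length(y), length(family_id) == length(y))
  dat <- data.frame(.y = y, predictors,
                    .site = factor(site_id), .family = factor(family_id),
                    check.names = TRUE)
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  dat <- .standardize_design(dat)
  preds <- setdiff(names(dat), c(".y", ".site", ".family"))
  f <- stats::as.formula(paste(".y ~", paste(preds, collapse = " + "),
                               "+ (1 | .site) + (1 | .family)"))
  fit <- tryCatch(
    lme4::lmer(f, data = dat, REML = TRUE,
               control = lme4::lmerControl(check.conv.singular = "ignore")),
    error = function(e) stop("mixed model failed to converge: ",
                             conditionMessage(e)))
  vc <- as.data.frame(lme4::VarCorr(fit))
  get_vc <- function(g) {
    v <- vc$vcov[vc$grp == g]
    if (length(v)) v else 0
  }
  co <- stats::coef(summary(fit))
  co <- co[rownames(co) != "(Intercept)", , drop = FALSE]
  list(fixed = data.frame(term = rownames(co), estimate = co[, 1],
                          se = co[, 2], t = co[, 3], row.names = NULL),
       variance_components = c(site = get_vc(".site"),
                               family = get_vc(".family"),
                               residual = get_vc("Residual")),
       n = nrow(dat))
}
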