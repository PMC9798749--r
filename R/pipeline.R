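#' Pipeline configuration
#'
#' Collects every knob of the end-to-end analysis: the synthetic cohort (or
#' input paths), stage toggles, the salience/pruning cutoff, the factor-count
#' override, and seeds. Deletion policy is fixed by design: pairwise-complete
#' observations for correlation estimation, listwise deletion for the
#' association models and scoring.
#'
#' @param synthetic list of arguments for \code{\link{default_cohort_spec}}
#'   (used when \code{input_dir} is NULL).
#' @param input_dir optional directory holding \code{items.csv},
#'   \code{covariates.csv}, \code{outcomes.csv}, \code{manifest.csv} as
#'   written by \code{\link{write_cohort}}.
#' @param out_dir output directory.
#' @param cutoff salience/pruning cutoff (default 0.30).
#' @param k optional factor-count override; parallel analysis decides when
#'   NULL.
#' @param stages character vector of stages to run after simulation/ingest.
#' @param reduction list of \code{\link{reduction_config}} arguments.
#' @param seed master seed; stage seeds derive from it.
#' @return list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(synthetic = list(), input_dir = NULL,
                            out_dir = tempfile("expofactor_run_"),
                            cutoff = 0.30, k = NULL,
                            stages = c("correlate", "reduce", "efa",
                                       "bifactor", "score", "associate"),
                            reduction = list(),
                            seed = 1L) {
  if (!is.null(input_dir) && !dir.exists(input_dir))
    stop("input_dir does not exist: ", input_dir)
  structure(list(synthetic = synthetic, input_dir = input_dir,
                 out_dir = out_dir, cutoff = cutoff, k = k,
                 stages = stages, reduction = reduction,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML or JSON
#' @param path configuration file.
#' @return \code{pipeline_config}.
#' @export
read_pipeline_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, cfg)
}

.load_cohort_csv <- function(dir) {
  items <- utils::read.csv(file.path(dir, "items.csv"))
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"))
  fam <- items$family_id
  items$family_id <- NULL
  list(items = items,
       covariates = utils::read.csv(file.path(dir, "covariates.csv")),
       outcomes = utils::read.csv(file.path(dir, "outcomes.csv")),
       manifest = manifest,
       family_id = fam)
}

#' Run the full exposome-factor pipeline
#'
#' Simulate (or ingest) a cohort, estimate the mixed correlation matrix with
#' pairwise deletion, optionally reduce redundancy, run minres EFA with
#' iterated target rotation, fit/prune the bifactor model, compute fit and
#' bifactor indices, score subjects, and fit the association models with
#' listwise deletion. Every artifact is written under \code{config$out_dir}
#' and listed with an MD5 content hash in the returned report; reruns with
#' an identical configuration reproduce identical hashes.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @return \code{pipeline_report}: nested list with per-stage parameters,
#'   warnings, output files and hashes; also written to
#'   \code{report.json} in the output directory.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  report <- list(seed = config$seed, stages = list())
  files <- character(0)
  stage_warnings <- list()
  run_stage <- function(name, expr) {
    ws <- character(0)
    t0 <- proc.time()[["elapsed"]]
    res <- withCallingHandlers(expr, warning = function(w) {
      ws <<- c(ws, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
    report$stages[[name]] <<- list(
      seconds = round(proc.time()[["elapsed"]] - t0, 2),
      warnings = ws)
    stage_warnings[[name]] <<- ws
    res
  }

  # --- simulate / ingest -------------------------------------------------
  cohort <- run_stage("data", {
    if (is.null(config$input_dir)) {
      args <- utils::modifyList(list(seed = config$seed), config$synthetic)
      spec <- do.call(default_cohort_spec, args)
      ch <- simulate_cohort(spec)
      write_cohort(ch, file.path(out, "cohort"))
      ch$family_id <- ch$latent$family_id
      ch
    } else .load_cohort_csv(config$input_dir)
  })
  report$stages$data$n_subjects <- nrow(cohort$items)
  report$stages$data$n_items <- ncol(cohort$items)
  items <- cohort$items
  manifest <- cohort$manifest

  # --- reduce ------------------------------------------------------------
  if ("reduce" %in% config$stages) {
    red <- run_stage("reduce", {
      reduce_redundancy(items, manifest,
                        do.call(reduction_config, config$reduction),
                        seed = config$seed)
    })
    items <- red$items
    manifest <- red$manifest
    p_audit <- file.path(out, "reduction_audit.csv")
    .write_csv_rounded(red$audit, p_audit)
    files <- c(files, p_audit)
    report$stages$reduce$iterations <- red$iterations
    report$stages$reduce$n_removed <- nrow(red$audit)
    report$stages$reduce$n_surviving <- length(red$surviving)
  }

  # --- correlate ---------------------------------------------------------
  mc <- run_stage("correlate", mixed_correlation_matrix(items, manifest))
  p_cor <- file.path(out, "correlation.csv")
  write_mixed_cor(mc, p_cor)
  files <- c(files, p_cor, sub("\\.csv$", ".meta.json", p_cor))
  report$stages$correlate$smoothed <- mc$smoothed
  report$stages$correlate$n_items <- ncol(mc$R)

  # --- efa + itr ---------------------------------------------------------
  efa <- run_stage("efa", {
    k <- config$k
    if (is.null(k))
      k <- retain_factors(mc, nrow(items), seed = config$seed)$k
    ex <- extract_minres(mc$R, k)
    itr <- iterated_target_rotation(ex, cutoff = config$cutoff,
                                    seed = config$seed)
    list(k = k, extraction = ex, itr = itr)
  })
  p_load <- file.path(out, "efa_loadings.csv")
  .write_csv_rounded(data.frame(item = rownames(efa$itr$loadings),
                                efa$itr$loadings), p_load)
  p_phi <- file.path(out, "efa_phi.csv")
  .write_csv_rounded(as.data.frame(efa$itr$Phi), p_phi)
  files <- c(files, p_load, p_phi)
  report$stages$efa$k <- efa$k
  report$stages$efa$itr_iterations <- efa$itr$iterations
  report$stages$efa$itr_converged <- efa$itr$converged

  # --- bifactor ----------------------------------------------------------
  bf <- run_stage("bifactor", {
    spec <- configure_bifactor(efa$itr, cutoff = config$cutoff)
    fit0 <- fit_bifactor(mc, spec, N = nrow(items), seed = config$seed)
    pr <- prune_and_refit(fit0, mc, N = nrow(items),
                          cutoff = config$cutoff, seed = config$seed)
    list(spec = pr$spec, fit = pr$fit, removed = pr$removed,
         indices = fit_indices(pr$fit),
         bindices = bifactor_indices(pr$fit),
         n_before = length(spec$items))
  })
  p_bl <- file.path(out, "bifactor_loadings.csv")
  .write_csv_rounded(data.frame(item = names(bf$fit$lambda_g),
                                specific_factor = unname(bf$fit$assignment),
                                lambda_g = unname(bf$fit$lambda_g),
                                lambda_s = unname(bf$fit$lambda_s),
                                psi = unname(bf$fit$psi)), p_bl)
  p_idx <- file.path(out, "bifactor_indices.json")
  jsonlite::write_json(
    list(fit = lapply(bf$indices, round, 6),
         ecv = round(bf$bindices$ecv, 6),
         omega_h = round(bf$bindices$omega_h, 6),
         omega_hs = round(bf$bindices$omega_hs, 6),
         fd = round(bf$bindices$fd, 6),
         items_before_pruning = bf$n_before,
         items_after_pruning = length(bf$spec$items)),
    p_idx, auto_unbox = TRUE, digits = NA, na = "null")
  files <- c(files, p_bl, p_idx)
  report$stages$bifactor$items_before <- bf$n_before
  report$stages$bifactor$items_after <- length(bf$spec$items)
  report$stages$bifactor$fit <- bf$indices
  report$stages$bifactor$ecv <- bf$bindices$ecv
  report$stages$bifactor$omega_h <- bf$bindices$omega_h

  # --- score -------------------------------------------------------------
  sc <- run_stage("score", {
    X <- standardize_items(items[, bf$spec$items, drop = FALSE],
                           manifest, mc$thresholds)
    factor_scores(X, bf$fit)
  })
  p_sc <- file.path(out, "factor_scores.csv")
  .write_csv_rounded(data.frame(subject = which(sc$rows_used), sc$scores),
                     p_sc)
  files <- c(files, p_sc)
  report$stages$score$n_scored <- nrow(sc$scores)
  report$stages$score$n_dropped <- sc$n_dropped
  report$stages$score$determinacy <- as.list(round(sc$determinacy, 4))

  # --- associate ---------------------------------------------------------
  if ("associate" %in% config$stages) {
    assoc <- run_stage("associate", {
      rows <- which(sc$rows_used)
      scores <- as.data.frame(sc$scores)
      cov <- cohort$covariates[rows, c("age", "sex"), drop = FALSE]
      outc <- cohort$outcomes[rows, , drop = FALSE]
      lin <- standardized_linear_model(outc$y, scores, cov)
      dr2 <- delta_r2(outc$y, cov, scores)
      logi <- lapply(stats::setNames(nm = setdiff(names(outc), "y")),
                     function(nm) logistic_model(outc[[nm]], scores, cov))
      contrast <- group_contrast(scores$general,
                                 cohort$covariates$income_low[rows])
      list(linear = lin, delta_r2 = dr2, logistic = logi,
           contrast = contrast)
    })
    p_lin <- file.path(out, "association_linear.csv")
    .write_csv_rounded(assoc$linear$coefficients, p_lin)
    files <- c(files, p_lin)
    for (nm in names(assoc$logistic)) {
      p_log <- file.path(out, sprintf("association_logistic_%s.csv", nm))
      .write_csv_rounded(assoc$logistic[[nm]]$table, p_log)
      files <- c(files, p_log)
    }
    report$stages$associate$adj_r2_full <- assoc$linear$adj_r2
    report$stages$associate$adj_r2_base <- assoc$delta_r2$adj_r2_base
    report$stages$associate$delta_r2 <- assoc$delta_r2$delta
    report$stages$associate$r2_ratio <- assoc$delta_r2$ratio
    report$stages$associate$contrast_d <- assoc$contrast$d
    report$stages$associate$n <- assoc$linear$n
  }

  # cohort files participate in the hash manifest too
  cohort_files <- list.files(file.path(out, "cohort"), full.names = TRUE)
  all_files <- c(cohort_files, files)
  hashes <- tools::md5sum(all_files)
  report$files <- data.frame(file = basename(names(hashes)),
                             md5 = unname(hashes), row.names = NULL)
  report$config <- list(cutoff = config$cutoff, k = config$k,
                        stages = config$stages, seed = config$seed)
  class(report) <- "pipeline_report"
  jsonlite::write_json(
    list(seed = report$seed,
         config = report$config,
         stages = lapply(report$stages, function(s) {
           s$seconds <- NULL  # wall time excluded for reproducible report files
           s
         }),
         files = report$files),
    file.path(out, "report.json"), auto_unbox = TRUE, digits = NA,
    dataframe = "rows", na = "null")
  report
}

#' @rdname run_pipeline
#' @param x a \code{pipeline_report}.
#' @param ... unused.
#' @export
#' @method print pipeline_report
print.pipeline_report <- function(x, ...) {
  cat("expofactor pipeline report (seed", x$seed, ")\n")
  for (nm in names(x$stages)) {
    s <- x$stages[[nm]]
    cat(sprintf("  %-10s %6.2fs  %s\n", nm, s$seconds,
                if (length(s$warnings)) paste(length(s$warnings), "warning(s)")
                else ""))
  }
  if (!is.null(x$stages$bifactor)) {
    cat(sprintf("  items %d -> %d after pruning; ECV %.3f, omega_h %.3f\n",
                x$stages$bifactor$items_before, x$stages$bifactor$items_after,
                x$stages$bifactor$ecv, x$stages$bifactor$omega_h))
  }
  if (!is.null(x$stages$associate)) {
    cat(sprintf("  adj R2 base %.3f -> full %.3f (ratio %.1f)\n",
                x$stages$associate$adj_r2_base,
                x$stages$associate$adj_r2_full,
                x$stages$associate$r2_ratio))
  }
  invisible(x)
}
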