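#' Configuration for the iterative redundancy-reduction loop
#'
#' @param r_merge absolute correlation at or above which variables are
#'   collapsed into one representative/composite (default 0.90).
#' @param min_communality EFA communality below which a variable is dropped
#'   (default 0.10).
#' @param max_iterations maximum reduction passes (default 9).
#' @param composite_rule \code{"representative"} keeps the highest-communality
#'   member of a redundant group (preserves measurement level);
#'   \code{"mean-of-standardized"} averages z-scored members into a new
#'   continuous composite (continuous-only groups).
#' @return list of class \code{reduction_config}.
#' @export
reduction_config <- function(r_merge = 0.90, min_communality = 0.10,
                             max_iterations = 9,
                             composite_rule = c("representative",
                                                "mean-of-standardized")) {
  composite_rule <- match.arg(composite_rule)
  stopifnot(min_communality > 0, min_communality < r_merge, r_merge <= 1)
  structure(list(r_merge = r_merge, min_communality = min_communality,
                 max_iterations = as.integer(max_iterations),
                 composite_rule = composite_rule),
            class = "reduction_config")
}

# connected components of the graph with an edge where |r| >= r_merge
.redundancy_groups <- function(R, r_merge) {
  p <- ncol(R)
  parent <- seq_len(p)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (i in seq_len(p - 1L)) for (j in (i + 1L):p)
    if (abs(R[i, j]) >= r_merge) {
      ri <- find(i)
      rj <- find(j)
      if (ri != rj) parent[rj] <- ri
    }
  roots <- vapply(seq_len(p), find, integer(1))
  split(seq_len(p), roots)
}

#' Iterative redundancy reduction of a wide variable panel
#'
#' Each pass (i) estimates the mixed-type correlation matrix, (ii) runs a
#' minres EFA with oblimin rotation at the parallel-analysis factor count to
#' obtain communalities, (iii) collapses groups of variables whose pairwise
#' absolute correlation reaches \code{r_merge}, and (iv) drops variables with
#' communality below \code{min_communality}. The loop stops when a pass takes
#' no action or \code{max_iterations} is reached. Every removal is recorded
#' in an audit table.
#'
#' @param items item data frame.
#' @param manifest variable manifest (columns \code{name}, \code{level},
#'   \code{n_categories}, \code{block}).
#' @param config a \code{\link{reduction_config}}.
#' @param n_subjects sample size for parallel analysis (defaults to
#'   \code{nrow(items)}).
#' @param seed seed for parallel analysis and rotation starts.
#' @return list with \code{items} (reduced table), \code{manifest},
#'   \code{surviving} names, \code{audit} data frame (iteration, variable,
#'   action, reason, value, kept_as), \code{iterations}.
#' @export
reduce_redundancy <- function(items, manifest, config = reduction_config(),
                              n_subjects = nrow(items), seed = 1L) {
  stopifnot(inherits(config, "reduction_config"), ncol(items) >= 3)
  audit <- list()
  it <- 0L
  repeat {
    it <- it + 1L
    acted <- FALSE
    mc <- mixed_correlation_matrix(items, manifest)
    k <- tryCatch(retain_factors(mc, n_subjects, seed = seed)$k,
                  error = function(e) 1L)
    ex <- extract_minres(mc$R, k)
    if (k >= 2) invisible(rotate_oblimin(ex, seed = seed))  # rotation leaves h2 unchanged
    h2 <- stats::setNames(ex$communalities, colnames(mc$R))

    groups <- .redundancy_groups(mc$R, config$r_merge)
    groups <- groups[vapply(groups, length, integer(1)) > 1L]
    drop_cols <- character(0)
    for (g in groups) {
      nms <- colnames(mc$R)[g]
      if (length(nms) == ncol(items))
        stop("all variables collapse into one composite; panel is degenerate")
      if (config$composite_rule == "representative" ||
          any(manifest$level[match(nms, manifest$name)] != "continuous")) {
        keep <- nms[which.max(h2[nms])]
        gone <- setdiff(nms, keep)
        for (v in gone)
          audit[[length(audit) + 1L]] <-
            data.frame(iteration = it, variable = v, action = "merged",
                       reason = sprintf("|r| >= %.2f with group", config$r_merge),
                       value = max(abs(mc$R[v, setdiff(nms, v)])),
                       kept_as = keep)
        drop_cols <- c(drop_cols, gone)
      } else {
        comp_name <- paste0("composite_", nms[1])
        items[[comp_name]] <-
          rowMeans(scale(items[, nms, drop = FALSE]), na.rm = FALSE)
        manifest <- rbind(manifest,
                          data.frame(name = comp_name, level = "continuous",
                                     n_categories = NA_integer_,
                                     block = manifest$block[match(nms[1], manifest$name)]))
        for (v in nms)
          audit[[length(audit) + 1L]] <-
            data.frame(iteration = it, variable = v, action = "merged",
                       reason = "mean-of-standardized composite",
                       value = NA_real_, kept_as = comp_name)
        drop_cols <- c(drop_cols, nms)
      }
      acted <- TRUE
    }
    items <- items[, setdiff(names(items), drop_cols), drop = FALSE]

    low <- names(h2)[h2 < config$min_communality]
    low <- intersect(low, names(items))
    if (length(low)) {
      for (v in low)
        audit[[length(audit) + 1L]] <-
          data.frame(iteration = it, variable = v, action = "dropped",
                     reason = sprintf("communality < %.2f", config$min_communality),
                     value = h2[[v]], kept_as = NA_character_)
      items <- items[, setdiff(names(items), low), drop = FALSE]
      acted <- TRUE
    }
    if (ncol(items) < 3)
      stop("fewer than 3 variables survive reduction; panel is degenerate")
    if (!acted || it >= config$max_iterations) break
  }
  manifest <- manifest[manifest$name %in% names(items), , drop = FALSE]
  audit_df <- if (length(audit)) do.call(rbind, audit)
  else data.frame(iteration = integer(0), variable = character(0),
                  action = character(0), reason = character(0),
                  value = numeric(0), kept_as = character(0))
  list(items = items, manifest = manifest, surviving = names(items),
       audit = audit_df, iterations = it)
}
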