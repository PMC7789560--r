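# Condition-comparison statistics: parametric (one-way ANOVA + paired T) or
# nonparametric (Kruskal-Wallis + Wilcoxon) routing based on Shapiro-Wilk
# normality and median-centered Levene homoscedasticity diagnostics, with
# Bonferroni-corrected post hoc thresholds; plus the paired T comparison of
# C+/C- offline RMSE and tabular report generation.

#' Compare a metric across conditions
#'
#' One value per subject and condition. Diagnostics: Shapiro-Wilk on each
#' condition's sample and median-centered Levene across conditions, both at
#' `alpha`; if all pass, the parametric path is taken (one-way ANOVA,
#' paired T post hocs), otherwise the nonparametric path (Kruskal-Wallis,
#' Wilcoxon signed-rank post hocs). Post hoc tests run only when the
#' omnibus test is significant at `alpha`, against the Bonferroni-corrected
#' threshold `alpha / n_pairs`.
#'
#' @param samples Named list of equal-length numeric vectors (subjects
#'   aligned across conditions).
#' @param paired Post hoc tests are paired (default `TRUE`).
#' @param alpha Significance threshold.
#' @return A list of class `comparison_result`: `metric` diagnostics,
#'   `parametric`, omnibus `test`/`statistic`/`p`, `posthoc` data frame
#'   (pair, statistic name, statistic, p, significant), and
#'   `corrected_alpha`.
#' @export
compare_conditions <- function(samples, paired = TRUE, alpha = 0.05) {
  stopifnot(is.list(samples), length(samples) >= 2)
  ns <- lengths(samples)
  if (any(ns < 3)) stop("need at least 3 values per condition")
  if (paired && length(unique(ns)) != 1) {
    stop("paired comparison requires equal-length samples")
  }
  conds <- names(samples)
  values <- unlist(samples, use.names = FALSE)
  gg <- factor(rep(conds, ns), levels = conds)
  shapiro_p <- vapply(samples, function(x) {
    if (stats::sd(x) == 0) 0 else stats::shapiro.test(x)$p.value
  }, numeric(1))
  levene_p <- tryCatch(
    car::leveneTest(values ~ gg, center = stats::median)[1, "Pr(>F)"],
    error = function(e) 0)
  parametric <- all(shapiro_p > alpha) && levene_p > alpha
  if (parametric) {
    fit <- stats::aov(values ~ gg)
    s <- summary(fit)[[1]]
    omni <- list(test = "anova", statistic = s[1, "F value"],
                 p = s[1, "Pr(>F)"])
  } else {
    k <- stats::kruskal.test(values, gg)
    omni <- list(test = "kruskal", statistic = unname(k$statistic),
                 p = k$p.value)
  }
  pairs <- utils::combn(conds, 2, simplify = FALSE)
  corrected <- alpha / length(pairs)
  posthoc <- NULL
  if (is.finite(omni$p) && omni$p < alpha) {
    posthoc <- do.call(rbind, lapply(pairs, function(pr) {
      x <- samples[[pr[1]]]; y <- samples[[pr[2]]]
      if (parametric) {
        tt <- paired_t_safe(x, y)
        data.frame(pair = paste(pr, collapse = " vs "), stat_name = "T",
                   statistic = tt$statistic, p = tt$p,
                   significant = tt$p < corrected)
      } else {
        w <- suppressWarnings(stats::wilcox.test(x, y, paired = paired,
                                                 exact = TRUE))
        data.frame(pair = paste(pr, collapse = " vs "), stat_name = "W",
                   statistic = unname(w$statistic), p = w$p.value,
                   significant = w$p.value < corrected)
      }
    }))
  }
  structure(list(conditions = conds,
                 shapiro_p = shapiro_p, levene_p = levene_p,
                 parametric = parametric,
                 test = omni$test, statistic = omni$statistic, p = omni$p,
                 posthoc = posthoc, corrected_alpha = corrected,
                 alpha = alpha),
            class = "comparison_result")
}

# paired T robust to degenerate zero-variance differences: identical
# samples give T = 0, p = 1; a constant non-zero difference is reported as
# p = 0 with a flag rather than NaN
paired_t_safe <- function(x, y) {
  d <- x - y
  if (stats::sd(d) < 1e-10 * max(1, abs(mean(d)))) {
    if (mean(d) == 0) {
      list(statistic = 0, p = 1, degenerate = TRUE)
    } else {
      list(statistic = sign(mean(d)) * Inf, p = 0, degenerate = TRUE)
    }
  } else {
    tt <- stats::t.test(x, y, paired = TRUE)
    list(statistic = unname(tt$statistic), p = tt$p.value,
         degenerate = FALSE)
  }
}

#' Paired comparison of C+ and C- offline RMSE
#'
#' Two-sided paired T test of per-subject RMSE values from the two
#' networks, as used for the offline assessment table.
#'
#' @param rmse_cplus,rmse_cminus Per-subject pooled RMSE (deg), aligned.
#' @return A list of class `comparison_result` (single pair).
#' @export
paired_rmse_test <- function(rmse_cplus, rmse_cminus) {
  stopifnot(length(rmse_cplus) == length(rmse_cminus),
            length(rmse_cplus) >= 3)
  tt <- paired_t_safe(rmse_cplus, rmse_cminus)
  structure(list(conditions = c("C+", "C-"),
                 parametric = TRUE, test = "paired_t",
                 statistic = tt$statistic, p = tt$p,
                 degenerate = isTRUE(tt$degenerate),
                 posthoc = NULL, corrected_alpha = 0.05, alpha = 0.05),
            class = "comparison_result")
}

comparison_to_row <- function(cr, label) {
  data.frame(metric = label, test = cr$test,
             statistic = cr$statistic, p = cr$p,
             parametric = cr$parametric)
}

#' Write the tabular report bundle
#'
#' Emits the result tables of a full experiment as CSV files plus a JSON
#' manifest: offline RMSE per subject/network/dataset (t-rmse), online
#' metrics per subject/condition (t-online), posture-variability SDs
#' (t-variability), and subspace distances (t-subspace). Missing components
#' are recorded as explicit gaps in the manifest.
#'
#' @param results The `results` element of a [run_experiment()] manifest.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest list.
#' @export
render_report <- function(results, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(tables = list(), gaps = list())
  emit <- function(df, name) {
    if (is.null(df) || !nrow(df)) {
      manifest$gaps <<- c(manifest$gaps, name)
    } else {
      path <- file.path(dir, paste0(name, ".csv"))
      utils::write.csv(df, path, row.names = FALSE)
      manifest$tables[[name]] <<- basename(path)
    }
  }
  emit(results$rmse_table, "t-rmse")
  emit(results$online_table, "t-online")
  emit(results$variability_table, "t-variability")
  emit(results$subspace_table, "t-subspace")
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
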