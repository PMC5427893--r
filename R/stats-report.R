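#' Percent reduction of a treated mean relative to control
#'
#' `100 * (control - treated) / control`, returned at full precision (reports
#' format to one decimal).
#'
#' @param control_mean,treated_mean group means; `control_mean` must be
#'   nonzero.
#' @return Percent reduction (negative when the treated mean is larger).
#' @examples
#' percent_reduction(3239.60, 2124.67)  # 34.4 (to one decimal)
#' @export
percent_reduction <- function(control_mean, treated_mean) {
  check_number(control_mean, "control_mean")
  check_number(treated_mean, "treated_mean")
  if (control_mean == 0) stop_config("control_mean must be nonzero")
  100 * (control_mean - treated_mean) / control_mean
}

#' Standard error of the mean
#' @param x numeric vector.
#' @return `sd(x) / sqrt(length(x))`.
#' @export
sem <- function(x) sd(x) / sqrt(length(x))

#' Compare groups with t-tests or ANOVA plus Bonferroni post-hoc tests
#'
#' Two-sided tests throughout. `two_group_t` runs a single t-test (Welch by
#' default; set `var_equal = TRUE` for the pooled Student variant).
#' `anova_bonferroni` runs a one-way ANOVA followed by all pairwise t-tests
#' with Bonferroni adjustment (p times the number of comparisons, capped
#' at 1).
#'
#' @param groups named list of numeric per-subject vectors (each n >= 2).
#' @param design `"two_group_t"` or `"anova_bonferroni"`.
#' @param var_equal pooled-variance t-tests if `TRUE`.
#' @return A `group_comparison`: `design`, `anova_f`, `anova_p` (NA for the
#'   two-group design) and `comparisons`, a data frame with group pair,
#'   means, `t_statistic`, `p_value`, `adjusted_p` and a `degenerate` flag
#'   (zero variance in both groups with equal means).
#' @export
group_compare <- function(groups, design = c("two_group_t", "anova_bonferroni"),
                          var_equal = FALSE) {
  design <- match.arg(design)
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    stop_config("groups must be a named list")
  if (any(vapply(groups, length, 1L) < 2L))
    stop_config("each group needs n >= 2")
  if (design == "two_group_t" && length(groups) != 2L)
    stop_config("two_group_t requires exactly 2 groups")

  pair_test <- function(a, b) {
    if (var(a) == 0 && var(b) == 0) {
      if (mean(a) == mean(b))
        return(list(t = NA_real_, p = NA_real_, degenerate = TRUE))
      return(list(t = sign(mean(a) - mean(b)) * Inf, p = 0, degenerate = FALSE))
    }
    tt <- t.test(a, b, var.equal = var_equal)
    list(t = unname(tt$statistic), p = tt$p.value, degenerate = FALSE)
  }

  nm <- names(groups)
  pairs <- utils::combn(seq_along(groups), 2L)
  m <- ncol(pairs)
  rows <- lapply(seq_len(m), function(k) {
    i <- pairs[1L, k]; j <- pairs[2L, k]
    r <- pair_test(groups[[i]], groups[[j]])
    data.frame(group_a = nm[i], group_b = nm[j],
               mean_a = mean(groups[[i]]), mean_b = mean(groups[[j]]),
               percent_reduction = if (mean(groups[[i]]) != 0)
                 percent_reduction(mean(groups[[i]]), mean(groups[[j]]))
               else NA_real_,
               t_statistic = r$t, p_value = r$p,
               adjusted_p = if (design == "anova_bonferroni")
                 min(1, r$p * m) else r$p,
               degenerate = r$degenerate)
  })
  comparisons <- do.call(rbind, rows)

  anova_f <- NA_real_; anova_p <- NA_real_
  if (design == "anova_bonferroni") {
    y <- unlist(groups, use.names = FALSE)
    g <- factor(rep(nm, vapply(groups, length, 1L)))
    if (var(y) > 0) {
      fit <- summary(aov(y ~ g))[[1L]]
      anova_f <- fit$`F value`[1L]
      anova_p <- fit$`Pr(>F)`[1L]
    }
  }
  structure(list(design = design, anova_f = anova_f, anova_p = anova_p,
                 comparisons = comparisons),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s\n", x$design))
  if (!is.na(x$anova_p))
    cat(sprintf("  ANOVA F = %.3f, p = %.4g\n", x$anova_f, x$anova_p))
  print(x$comparisons, row.names = FALSE)
  invisible(x)
}

#' Pearson correlation with r-squared
#'
#' @param x,y numeric vectors (length >= 3, non-constant).
#' @return List with `r_squared` and the two-sided `p_value`.
#' @export
correlate <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L)
    stop_config("x and y must share length >= 3")
  if (var(x) == 0 || var(y) == 0)
    stop_config("constant input: correlation undefined")
  ct <- cor.test(x, y, method = "pearson")
  list(r_squared = unname(ct$estimate)^2, p_value = ct$p.value)
}

#' Build a group/region summary report
#'
#' @param metrics long-format data frame with columns `group`, `subject`,
#'   `region`, `metric`, `value`.
#' @param control,treated group labels compared in the effect table.
#' @param alpha significance level flagged in the report.
#' @return An `analysis_report`: `summary` (per group/region/metric n, mean,
#'   SEM) and `effects` (percent reduction, Welch t, p, significance; rows
#'   are marked not computable when a group has n < 2). Regenerating from the
#'   same inputs gives identical output.
#' @export
build_report <- function(metrics, control = "sham", treated = "tbi",
                         alpha = 0.05) {
  need <- c("group", "subject", "region", "metric", "value")
  missing_cols <- setdiff(need, names(metrics))
  if (length(missing_cols))
    stop_config("metrics table lacks required columns: ",
                paste(missing_cols, collapse = ", "))

  key <- interaction(metrics$region, metrics$metric, drop = TRUE)
  summary_rows <- list()
  effect_rows <- list()
  for (k in levels(key)) {
    sub <- metrics[key == k, , drop = FALSE]
    region <- sub$region[1L]; metric <- sub$metric[1L]
    for (g in sort(unique(sub$group))) {
      v <- sub$value[sub$group == g]
      summary_rows[[length(summary_rows) + 1L]] <-
        data.frame(group = g, region = region, metric = metric,
                   n = length(v), mean = mean(v),
                   sem = if (length(v) > 1L) sem(v) else NA_real_)
    }
    a <- sub$value[sub$group == control]
    b <- sub$value[sub$group == treated]
    a <- a[is.finite(a)]
    b <- b[is.finite(b)]
    computable <- length(a) >= 2L && length(b) >= 2L && mean(a) != 0
    if (computable) {
      cmp <- group_compare(stats::setNames(list(a, b), c(control, treated)),
                           design = "two_group_t")$comparisons
      effect_rows[[length(effect_rows) + 1L]] <-
        data.frame(region = region, metric = metric,
                   control_mean = mean(a), treated_mean = mean(b),
                   percent_reduction = percent_reduction(mean(a), mean(b)),
                   t_statistic = cmp$t_statistic, p_value = cmp$p_value,
                   significant = !is.na(cmp$p_value) & cmp$p_value < alpha,
                   computable = TRUE)
    } else {
      effect_rows[[length(effect_rows) + 1L]] <-
        data.frame(region = region, metric = metric,
                   control_mean = if (length(a)) mean(a) else NA_real_,
                   treated_mean = if (length(b)) mean(b) else NA_real_,
                   percent_reduction = NA_real_, t_statistic = NA_real_,
                   p_value = NA_real_, significant = NA, computable = FALSE)
    }
  }
  summary_df <- do.call(rbind, summary_rows)
  effects_df <- do.call(rbind, effect_rows)
  ord <- order(summary_df$region, summary_df$metric, summary_df$group)
  summary_df <- summary_df[ord, , drop = FALSE]
  rownames(summary_df) <- NULL
  ord <- order(effects_df$region, effects_df$metric)
  effects_df <- effects_df[ord, , drop = FALSE]
  rownames(effects_df) <- NULL
  structure(list(summary = summary_df, effects = effects_df,
                 control = control, treated = treated, alpha = alpha),
            class = "analysis_report")
}

#' @export
print.analysis_report <- function(x, ...) {
  cat(sprintf("<analysis_report> %s vs %s, alpha = %g\n", x$control,
              x$treated, x$alpha))
  print(x$effects, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Render an analysis report as Markdown
#' @param report an `analysis_report`.
#' @return Character vector of Markdown lines.
#' @export
format_report_md <- function(report) {
  f1 <- function(x) ifelse(is.na(x), "NA", sprintf("%.1f", x))
  f4 <- function(x) ifelse(is.na(x), "NA", sprintf("%.4g", x))
  lines <- c("# Vascular metrics report", "",
             sprintf("Comparison: %s (control) vs %s (treated); alpha = %g",
                     report$control, report$treated, report$alpha), "",
             "## Group means (mean +/- SEM)", "",
             "| region | metric | group | n | mean | sem |",
             "|---|---|---|---|---|---|")
  s <- report$summary
  lines <- c(lines, sprintf("| %s | %s | %s | %d | %s | %s |", s$region,
                            s$metric, s$group, s$n, f4(s$mean), f4(s$sem)))
  e <- report$effects
  lines <- c(lines, "", "## Effects", "",
             "| region | metric | % reduction | t | p | significant |",
             "|---|---|---|---|---|---|",
             sprintf("| %s | %s | %s | %s | %s | %s |", e$region, e$metric,
                     f1(e$percent_reduction), f4(e$t_statistic),
                     f4(e$p_value),
                     ifelse(is.na(e$significant), "not computable",
                            ifelse(e$significant, "yes", "no"))))
  lines
}

#' Write a report as JSON and Markdown
#'
#' Output is deterministic (no timestamps): the same report writes the same
#' bytes.
#'
#' @param report an `analysis_report`.
#' @param json_path,md_path output paths (`NULL` skips a format).
#' @return Invisible list of written paths.
#' @export
write_report <- function(report, json_path = NULL, md_path = NULL) {
  if (!is.null(json_path)) {
    jsonlite::write_json(list(control = report$control,
                              treated = report$treated,
                              alpha = report$alpha,
                              summary = report$summary,
                              effects = report$effects),
                         json_path, auto_unbox = TRUE, digits = NA,
                         na = "null")
  }
  if (!is.null(md_path))
    writeLines(format_report_md(report), md_path)
  invisible(list(json = json_path, md = md_path))
}
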