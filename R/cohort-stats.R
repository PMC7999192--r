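# The cohort statistics layer: chi-square independence on the cohort
# composition table, and per-measurement two-group comparison routed between
# one-way ANOVA and Kruskal-Wallis by normality and variance-homogeneity
# diagnostics, at alpha = 0.05 throughout.

#' Pearson chi-square test of independence on a 2x2 table
#'
#' Pearson chi-square without continuity correction (df = 1 for a 2x2
#' table), expected counts `row * col / total`.
#'
#' @param table 2x2 matrix of non-negative counts (rows = modality,
#'   columns = category such as sex).
#' @return A list with `statistic`, `df`, `p_value` and `expected`.
#' @export
#' @examples
#' chi2_independence(matrix(c(72, 110, 60, 257), 2))
chi2_independence <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L)))
    stop_condylometry("expected a 2x2 table")
  if (any(table < 0) || sum(table) < 1)
    stop_condylometry("counts must be non-negative with positive total")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop_condylometry("zero marginal: expected counts undefined")
  ct <- suppressWarnings(chisq.test(table, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = unname(ct$p.value), expected = ct$expected)
}

#' Compare one measurement between two modality groups
#'
#' Routes the two-group comparison the way the protocol prescribes: one-way
#' ANOVA when both groups pass Shapiro-Wilk normality at 0.05 and Levene's
#' test for homogeneity of variance passes at 0.05, otherwise the
#' Kruskal-Wallis rank test (with the standard tie correction).
#' Significance is declared at p < 0.05.
#'
#' @param fbct_values,cbct_values numeric vectors (mm), each of length >= 3.
#' @param name measurement label carried into the result.
#' @param alpha significance level (default 0.05).
#' @param levene_center centring for Levene's test: `"mean"` (classic
#'   Levene, the default) or `"median"` (Brown-Forsythe).
#' @return An object of class `group_comparison`: route, diagnostics,
#'   statistic, p-value, significance flag and group summaries.
#' @export
#' @examples
#' set.seed(1)
#' compare_groups(rnorm(30, 2.15, 0.8), rnorm(30, 1.71, 0.5), "thickness")
compare_groups <- function(fbct_values, cbct_values, name = "measurement",
                           alpha = 0.05, levene_center = c("mean", "median")) {
  levene_center <- match.arg(levene_center)
  fbct_values <- fbct_values[is.finite(fbct_values)]
  cbct_values <- cbct_values[is.finite(cbct_values)]
  if (length(fbct_values) < 3 || length(cbct_values) < 3)
    stop_condylometry("each group needs at least 3 finite values")

  sw <- function(x) {
    if (length(unique(x)) == 1) return(0)   # degenerate: clearly non-normal
    shapiro.test(x)$p.value
  }
  norm_p <- c(FBCT = sw(fbct_values), CBCT = sw(cbct_values))
  values <- c(fbct_values, cbct_values)
  group <- factor(rep(c("FBCT", "CBCT"), c(length(fbct_values),
                                           length(cbct_values))),
                  levels = c("FBCT", "CBCT"))
  var_p <- if (all(norm_p > alpha)) {
    lt <- car::leveneTest(values ~ group, center = levene_center)
    lt[["Pr(>F)"]][1]
  } else NA_real_

  if (all(norm_p > alpha) && isTRUE(var_p > alpha)) {
    route <- "ANOVA"
    fit <- anova(lm(values ~ group))
    statistic <- fit[["F value"]][1]
    p_value <- fit[["Pr(>F)"]][1]
  } else {
    route <- "Kruskal-Wallis"
    kt <- kruskal.test(values, group)
    statistic <- unname(kt$statistic)
    p_value <- kt$p.value
  }
  structure(list(
    name = name, route = route, normality_p = norm_p, variance_p = var_p,
    statistic = statistic, p_value = p_value,
    significant = is.finite(p_value) && p_value < alpha, alpha = alpha,
    group_means = c(FBCT = mean(fbct_values), CBCT = mean(cbct_values)),
    group_sds = c(FBCT = sd(fbct_values), CBCT = sd(cbct_values)),
    n = c(FBCT = length(fbct_values), CBCT = length(cbct_values))),
    class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s via %s\n", x$name, x$route))
  cat(sprintf("  FBCT %.3f +/- %.3f (n=%d), CBCT %.3f +/- %.3f (n=%d)\n",
              x$group_means["FBCT"], x$group_sds["FBCT"], x$n["FBCT"],
              x$group_means["CBCT"], x$group_sds["CBCT"], x$n["CBCT"]))
  cat(sprintf("  statistic %.4g, p = %.4g (%s at %.2g)\n", x$statistic,
              x$p_value, if (x$significant) "significant" else "n.s.", x$alpha))
  invisible(x)
}

#' Assemble a study report table
#'
#' Emits the per-measurement comparison table (group mean +/- SD per
#' modality, route, p-value and "p < 0.05" / "n.s." flag), in canonical
#' measurement order where applicable, together with the cohort chi-square
#' result.
#'
#' @param comparisons list of [compare_groups()] results (>= 1).
#' @param cohort optional 2x2 cohort composition table for
#'   [chi2_independence()].
#' @return An object of class `study_report` with elements `table` (a
#'   data.frame), `chi2` and `comparisons`.
#' @export
report <- function(comparisons, cohort = NULL) {
  if (inherits(comparisons, "group_comparison")) comparisons <- list(comparisons)
  if (!length(comparisons)) stop_condylometry("need at least one comparison")
  nms <- vapply(comparisons, `[[`, "", "name")
  ord <- order(match(nms, canonical_measurements, nomatch = NA), seq_along(nms),
               na.last = TRUE)
  comparisons <- comparisons[ord]
  tab <- do.call(rbind, lapply(comparisons, function(x) {
    data.frame(
      measurement = x$name,
      fbct_mean = unname(x$group_means["FBCT"]),
      fbct_sd = unname(x$group_sds["FBCT"]),
      cbct_mean = unname(x$group_means["CBCT"]),
      cbct_sd = unname(x$group_sds["CBCT"]),
      route = x$route, statistic = x$statistic, p_value = x$p_value,
      significance = if (x$significant) "p < 0.05" else "n.s.",
      stringsAsFactors = FALSE)
  }))
  chi2 <- if (!is.null(cohort)) chi2_independence(cohort) else NULL
  structure(list(table = tab, chi2 = chi2, comparisons = comparisons),
            class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat("Condylar measurement comparison (FBCT vs CBCT)\n")
  tab <- x$table
  cat(sprintf("%-32s %-17s %-17s %s\n", "Measurement", "FBCT mean+/-SD",
              "CBCT mean+/-SD", "Significance"))
  for (i in seq_len(nrow(tab)))
    cat(sprintf("%-32s %7.2f +/- %-6.2f %7.2f +/- %-6.2f %s [%s]\n",
                tab$measurement[i], tab$fbct_mean[i], tab$fbct_sd[i],
                tab$cbct_mean[i], tab$cbct_sd[i], tab$significance[i],
                tab$route[i]))
  if (!is.null(x$chi2))
    cat(sprintf("Cohort chi-square: X2 = %.3f, df = %d, p = %.4g\n",
                x$chi2$statistic, x$chi2$df, x$chi2$p_value))
  invisible(x)
}

#' Write a study report to disk
#'
#' @param x a [report()] object.
#' @param dir output directory (created if needed); writes
#'   `report.csv` and `report.txt`.
#' @export
write_report <- function(x, dir) {
  stopifnot(inherits(x, "study_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(x$table, file.path(dir, "report.csv"), row.names = FALSE)
  con <- file(file.path(dir, "report.txt"), "w")
  sink(con); print(x); sink()
  close(con)
  invisible(file.path(dir, "report.csv"))
}

#' Boxplot of one measurement by modality
#'
#' @param x a `study_report`.
#' @param measurement measurement name to plot (default: first row).
#' @param ... passed to [graphics::boxplot()].
#' @export
plot.study_report <- function(x, measurement = NULL, ...) {
  measurement <- measurement %||% x$table$measurement[1]
  cmp <- Filter(function(c) c$name == measurement, x$comparisons)
  if (!length(cmp)) stop_condylometry("measurement not in report")
  cmp <- cmp[[1]]
  graphics::barplot(cmp$group_means, ylab = "mm",
                    main = sprintf("%s (%s, p = %.3g)", measurement,
                                   cmp$route, cmp$p_value), ...)
  invisible(x)
}
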