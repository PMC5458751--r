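# Group statistics: mean +/- SEM summaries, normality checks, two-group t
# tests, one-way ANOVA with all-pairs Bonferroni post hoc, and report
# assembly.

#' Mean and standard error of a sample
#' @param values Numeric vector (length >= 1).
#' @return List with `mean`, `sem` (SD / sqrt(n); 0 for a single value),
#'   and `n`.
#' @export
group_summary <- function(values) {
  values <- as.numeric(values)
  if (!length(values)) stop_chc("empty sample")
  n <- length(values)
  list(mean = mean(values),
       sem = if (n > 1) stats::sd(values) / sqrt(n) else 0,
       n = n)
}

#' Significance stars for a p-value
#' @param p P-value(s).
#' @return `"***"` for p < 0.001, `"**"` for p < 0.01, `"*"` for p < 0.05,
#'   `"n.s."` otherwise.
#' @export
significance_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**",
                                  ifelse(p < 0.05, "*", "n.s.")))
}

#' Compare two or more groups
#'
#' Normality is assessed per group by the Shapiro-Wilk test (reported; it
#' gates the choice of test only when `gate_on_normality = TRUE`, in which
#' case a violated assumption switches to the rank-based analogue).  Two
#' groups are compared by a two-tailed unpaired Student's t test; more
#' than two by one-way ANOVA followed by all-pairs pooled-SD t tests with
#' Bonferroni adjustment (each pairwise p multiplied by the number of
#' pairs, capped at 1).
#'
#' @param samples Named list of numeric vectors (>= 2 groups, each n >= 2).
#' @param gate_on_normality Switch to rank tests when any group fails
#'   Shapiro-Wilk at 0.05.
#' @return An object of class `chc_test`: `test_name`, `statistic`,
#'   `p_value`, `stars`, per-group `shapiro` p-values, and (for > 2
#'   groups) a `pairwise` data frame with raw and Bonferroni-adjusted
#'   p-values.
#' @export
compare_groups <- function(samples, gate_on_normality = FALSE) {
  if (length(samples) < 2L) stop_chc("need at least two groups")
  if (is.null(names(samples)) || any(names(samples) == "")) {
    names(samples) <- paste0("group", seq_along(samples))
  }
  ns <- vapply(samples, length, integer(1))
  if (any(ns < 2L)) stop_chc("every group needs n >= 2")
  shapiro <- vapply(samples, function(x) {
    if (length(x) >= 3L && length(x) <= 5000L && stats::sd(x) > 0) {
      stats::shapiro.test(x)$p.value
    } else NA_real_
  }, numeric(1))
  normal_ok <- all(is.na(shapiro) | shapiro >= 0.05)
  use_rank <- gate_on_normality && !normal_ok

  values <- unlist(samples, use.names = FALSE)
  group <- factor(rep(names(samples), ns), levels = names(samples))
  pairwise <- NULL
  if (length(samples) == 2L) {
    if (use_rank) {
      ht <- stats::wilcox.test(samples[[1]], samples[[2]], exact = FALSE)
      test_name <- "Mann-Whitney U"
    } else {
      ht <- stats::t.test(samples[[1]], samples[[2]], var.equal = TRUE)
      test_name <- "Student's t test, two tailed, unpaired"
    }
    statistic <- unname(ht$statistic)
    p_value <- ht$p.value
  } else {
    if (use_rank) {
      ht <- stats::kruskal.test(values, group)
      test_name <- "Kruskal-Wallis"
      statistic <- unname(ht$statistic)
      p_value <- ht$p.value
    } else {
      fit <- stats::aov(values ~ group)
      tab <- summary(fit)[[1]]
      test_name <- "One-way ANOVA Bonferroni post hoc"
      statistic <- tab[["F value"]][1]
      p_value <- tab[["Pr(>F)"]][1]
    }
    pt <- stats::pairwise.t.test(values, group, pool.sd = !use_rank,
                                 p.adjust.method = "none")
    pm <- pt$p.value
    pairs <- which(!is.na(pm), arr.ind = TRUE)
    raw <- pm[pairs]
    adj <- stats::p.adjust(raw, method = "bonferroni")
    pairwise <- data.frame(
      group1 = rownames(pm)[pairs[, 1]],
      group2 = colnames(pm)[pairs[, 2]],
      p_raw = raw, p_adj = adj, stars = significance_stars(adj))
  }
  structure(list(test_name = test_name, statistic = statistic,
                 p_value = p_value, stars = significance_stars(p_value),
                 shapiro = shapiro, pairwise = pairwise,
                 groups = names(samples), n = ns),
            class = "chc_test")
}

#' @export
print.chc_test <- function(x, ...) {
  cat(sprintf("%s: statistic %.4g, p = %.4g %s\n", x$test_name,
              x$statistic, x$p_value, x$stars))
  if (!is.null(x$pairwise)) {
    cat("pairwise (Bonferroni):\n")
    print(x$pairwise, row.names = FALSE)
  }
  invisible(x)
}

#' Assemble a per-metric, per-group summary report
#'
#' For each metric column, computes the group-wise mean +/- SEM and the
#' group comparison ([compare_groups()]): the layer that turns per-cell
#' tables into the per-age-group summary statements.
#'
#' @param per_cell Data frame with one row per cell.
#' @param metrics Character vector of metric column names.
#' @param group_col Name of the grouping column.
#' @param gate_on_normality Passed to [compare_groups()].
#' @return A data frame (`metric`, `group`, `n`, `mean`, `sem`) with a
#'   named list of `chc_test` results in `attr(, "tests")`.
#' @export
build_report <- function(per_cell, metrics, group_col = "group",
                         gate_on_normality = FALSE) {
  if (nrow(per_cell) == 0L) {
    out <- data.frame(metric = character(0), group = character(0),
                      n = integer(0), mean = numeric(0), sem = numeric(0))
    attr(out, "tests") <- list()
    return(out)
  }
  if (!group_col %in% names(per_cell)) {
    stop_chc("grouping column '", group_col, "' not found")
  }
  missing <- setdiff(metrics, names(per_cell))
  if (length(missing)) {
    stop_chc("metric column(s) not found: ", paste(missing, collapse = ", "))
  }
  grp <- as.character(per_cell[[group_col]])
  levels_ <- unique(grp)
  rows <- list()
  tests <- list()
  for (mt in metrics) {
    samples <- lapply(levels_, function(g) {
      v <- per_cell[[mt]][grp == g]
      v[!is.na(v)]
    })
    names(samples) <- levels_
    for (g in levels_) {
      gs <- group_summary(samples[[g]])
      rows[[length(rows) + 1L]] <- data.frame(
        metric = mt, group = g, n = gs$n, mean = gs$mean, sem = gs$sem)
    }
    if (length(levels_) >= 2L && all(vapply(samples, length, 1L) >= 2L)) {
      tests[[mt]] <- compare_groups(samples, gate_on_normality)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "tests") <- tests
  out
}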