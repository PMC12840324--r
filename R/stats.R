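#' Kruskal-Wallis comparison of groups
#'
#' Nonparametric omnibus comparison of two or more groups, the test used
#' for recall and sensitivity comparisons when normality fails. The
#' significance level defaults to 0.01.
#'
#' @param values Numeric outcome values.
#' @param groups Group labels, same length as `values`.
#' @param alpha Significance level.
#' @return One-row tibble: `test`, `statistic`, `df`, `p_value`, `alpha`,
#'   `significant`, `groups`, `n`. Returns a zero-row tibble with a warning
#'   if any group has fewer than 2 observations.
#' @export
compare_groups_kw <- function(values, groups, alpha = 0.01) {
  stopifnot(length(values) == length(groups))
  groups <- droplevels(factor(groups))
  if (nlevels(groups) < 2) stop("need at least 2 groups", call. = FALSE)
  sizes <- table(groups)
  if (any(sizes < 2)) {
    warning("group(s) with < 2 observations: ",
            paste(names(sizes)[sizes < 2], collapse = ", "),
            "; test skipped", call. = FALSE)
    return(stat_result_empty())
  }
  kw <- stats::kruskal.test(values, groups)
  stat_result("kruskal-wallis", unname(kw$statistic), unname(kw$parameter),
              kw$p.value, alpha, paste(levels(groups), collapse = " vs "),
              length(values))
}

#' Post hoc pairwise rank comparisons
#'
#' All pairwise two-group rank tests after a significant omnibus
#' comparison. Raw p-values are reported by default (no multiple-testing
#' correction), with Holm or any [stats::p.adjust()] method available.
#'
#' @inheritParams compare_groups_kw
#' @param p_adjust Correction method, default `"none"`.
#' @return Tibble with one row per pair.
#' @export
posthoc_pairwise <- function(values, groups, alpha = 0.01, p_adjust = "none") {
  groups <- droplevels(factor(groups))
  if (nlevels(groups) < 3) {
    stop("post hoc comparisons need >= 3 groups; use compare_groups_kw()",
         call. = FALSE)
  }
  pairs <- utils::combn(levels(groups), 2, simplify = FALSE)
  out <- purrr::map_dfr(pairs, function(pr) {
    sel <- groups %in% pr
    res <- compare_groups_kw(values[sel], groups[sel], alpha = alpha)
    if (nrow(res) == 0) {
      res <- stat_result("kruskal-wallis", NA_real_, NA_real_, NA_real_,
                         alpha, paste(pr, collapse = " vs "), sum(sel))
    }
    res
  })
  out$p_value <- stats::p.adjust(out$p_value, method = p_adjust)
  out$significant <- !is.na(out$p_value) & out$p_value < alpha
  out
}

#' Shapiro-Wilk normality screen
#'
#' Screens a sample for normality before choosing nonparametric tests.
#' For samples above 5000 values a deterministic evenly-spaced subsample
#' of 5000 is tested (the test statistic is defined for n <= 5000).
#' A constant sample is an error.
#'
#' @param values Numeric sample, n >= 3.
#' @param alpha Significance level.
#' @return One-row tibble as in [compare_groups_kw()].
#' @export
normality_screen <- function(values, alpha = 0.01) {
  values <- values[is.finite(values)]
  if (length(values) < 3) stop("need n >= 3 for the normality screen", call. = FALSE)
  if (max(values) == min(values)) {
    stop("normality screen undefined for a constant sample", call. = FALSE)
  }
  if (length(values) > 5000) {
    values <- values[round(seq(1, length(values), length.out = 5000))]
  }
  sw <- stats::shapiro.test(values)
  stat_result("shapiro-wilk", unname(sw$statistic), NA_real_, sw$p.value,
              alpha, "sample", length(values))
}

#' Correlation between node size and segmentation sensitivity
#'
#' Pearson correlation between per-node SAD (mm) and per-node sensitivity,
#' optionally restricted to nodes with `sad_mm > sad_min` (e.g. 10 mm to
#' focus on enlarged nodes).
#'
#' @param nodes Tibble with columns `sad_mm` and `sensitivity`.
#' @param sad_min Optional lower SAD cut (strict, mm).
#' @param alpha Significance level.
#' @return One-row tibble as in [compare_groups_kw()] with `test`
#'   `"pearson"`; the statistic is the correlation coefficient r.
#' @export
sad_sensitivity_correlation <- function(nodes, sad_min = NULL, alpha = 0.01) {
  df <- nodes[stats::complete.cases(nodes[c("sad_mm", "sensitivity")]), ]
  label <- "all nodes"
  if (!is.null(sad_min)) {
    df <- df[df$sad_mm > sad_min, ]
    label <- paste0("nodes with SAD > ", sad_min, " mm")
  }
  if (nrow(df) < 3) stop("need >= 3 nodes for the correlation", call. = FALSE)
  if (stats::sd(df$sad_mm) == 0 || stats::sd(df$sensitivity) == 0) {
    stop("zero variance in SAD or sensitivity", call. = FALSE)
  }
  ct <- stats::cor.test(df$sad_mm, df$sensitivity, method = "pearson")
  stat_result("pearson", unname(ct$estimate), unname(ct$parameter),
              ct$p.value, alpha, label, nrow(df))
}

stat_result <- function(test, statistic, df, p_value, alpha, groups, n) {
  tibble::tibble(
    test = test, statistic = statistic, df = df, p_value = p_value,
    alpha = alpha, significant = !is.na(p_value) & p_value < alpha,
    groups = groups, n = n
  )
}

stat_result_empty <- function() {
  tibble::tibble(
    test = character(), statistic = double(), df = double(),
    p_value = double(), alpha = double(), significant = logical(),
    groups = character(), n = integer()
  )
}
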