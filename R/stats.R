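#' One-way ANOVA across groups
#'
#' Classical F test with (k - 1, N - k) degrees of freedom, as used for
#' genotype comparisons of each circadian and sleep metric.
#'
#' @param groups named (or unnamed) list of numeric vectors, one per group;
#'   at least 2 groups of n >= 2 each.
#' @return a \code{"group_comparison"} list: \code{test = "ANOVA_F"},
#'   \code{statistic}, \code{dof = c(between, within)}, \code{p_value}.
#' @examples
#' one_way_anova(list(c(1, 2, 3), c(2, 3, 4), c(3, 4, 5)))$statistic  # 3
#' @export
one_way_anova <- function(groups) {
  .check_groups(groups)
  df <- .stack_groups(groups)
  fit <- stats::aov(value ~ group, data = df)
  tab <- summary(fit)[[1]]
  structure(list(test = "ANOVA_F",
                 statistic = tab[["F value"]][1],
                 dof = c(between = tab[["Df"]][1], within = tab[["Df"]][2]),
                 p_value = tab[["Pr(>F)"]][1],
                 pairwise = NULL),
            class = "group_comparison")
}

#' Kruskal-Wallis ANOVA on ranks
#'
#' Rank-based omnibus test (H statistic against chi-square with k - 1 df,
#' tie-corrected), used when a metric fails normality or equal-variance
#' checks.
#'
#' @inheritParams one_way_anova
#' @return a \code{"group_comparison"} with \code{test = "KRUSKAL_H"}.
#' @examples
#' kruskal_wallis(list(c(1, 2), c(3, 4), c(5, 6)))$statistic  # 4.571
#' @export
kruskal_wallis <- function(groups) {
  .check_groups(groups)
  df <- .stack_groups(groups)
  kt <- stats::kruskal.test(value ~ group, data = df)
  structure(list(test = "KRUSKAL_H",
                 statistic = unname(kt$statistic),
                 dof = unname(kt$parameter),
                 p_value = kt$p.value,
                 pairwise = NULL),
            class = "group_comparison")
}

#' Bonferroni-corrected pairwise t tests
#'
#' All pairwise t tests using the pooled within-group standard deviation,
#' with each p value multiplied by the number of comparisons and capped at
#' 1. Intended as the post hoc step after a significant omnibus test: by
#' default it refuses to run unless \code{omnibus_p < alpha} (pass
#' \code{force = TRUE} to override).
#'
#' @inheritParams one_way_anova
#' @param omnibus_p p value of the omnibus test already run on these groups.
#' @param alpha significance level gating the post hoc step (default 0.05).
#' @param force run even without a significant omnibus test.
#' @return data frame with \code{group1}, \code{group2}, \code{t},
#'   \code{p_raw}, \code{p_adjusted}.
#' @export
bonferroni_pairwise_t <- function(groups, omnibus_p = NA, alpha = 0.05,
                                  force = FALSE) {
  .check_groups(groups)
  if (!force) {
    if (is.na(omnibus_p))
      stop("supply omnibus_p (or force = TRUE): post hoc tests follow a significant omnibus test")
    if (omnibus_p >= alpha)
      stop("omnibus test not significant; post hoc comparisons suppressed (force = TRUE to override)")
  }
  df <- .stack_groups(groups)
  k <- nlevels(df$group)
  ns <- tapply(df$value, df$group, length)
  means <- tapply(df$value, df$group, mean)
  ss <- tapply(df$value, df$group, function(v) sum((v - mean(v))^2))
  pooled_var <- sum(ss) / (nrow(df) - k)
  df_w <- nrow(df) - k
  pairs <- utils::combn(levels(df$group), 2)
  m <- ncol(pairs)
  rows <- lapply(seq_len(m), function(i) {
    a <- pairs[1, i]; b <- pairs[2, i]
    se <- sqrt(pooled_var * (1 / ns[[a]] + 1 / ns[[b]]))
    tval <- if (se == 0) 0 else (means[[a]] - means[[b]]) / se
    p <- 2 * stats::pt(-abs(tval), df_w)
    data.frame(group1 = a, group2 = b, t = tval, p_raw = p,
               p_adjusted = min(1, m * p))
  })
  do.call(rbind, rows)
}

#' Gated group comparison
#'
#' Applies the decision rule used for the group tables: if every group
#' passes a Shapiro-Wilk normality check and the groups pass Levene's
#' equal-variance test at \code{gate_alpha}, an ordinary one-way ANOVA is
#' run and F reported; otherwise ANOVA on ranks (Kruskal-Wallis) is run and
#' H reported. When the omnibus test is significant, Bonferroni pairwise
#' t comparisons are attached.
#'
#' @inheritParams one_way_anova
#' @param gate_alpha significance level of the normality/equal-variance
#'   gates (default 0.05).
#' @param alpha omnibus significance level for the post hoc step
#'   (default 0.05).
#' @return a \code{"group_comparison"} with \code{pairwise} filled in when
#'   the omnibus test is significant, plus \code{gates} (p values of the
#'   gate tests).
#' @export
compare_groups <- function(groups, gate_alpha = 0.05, alpha = 0.05) {
  .check_groups(groups)
  df <- .stack_groups(groups)
  sw <- vapply(groups, function(v) {
    if (length(unique(v)) < 3) return(0)  # degenerate: treat as non-normal
    stats::shapiro.test(v)$p.value
  }, 0)
  lv <- car::leveneTest(value ~ group, data = df)[["Pr(>F)"]][1]
  parametric <- all(sw > gate_alpha) && lv > gate_alpha
  out <- if (parametric) one_way_anova(groups) else kruskal_wallis(groups)
  out$gates <- list(shapiro_p = sw, levene_p = lv, parametric = parametric)
  if (!is.na(out$p_value) && out$p_value < alpha)
    out$pairwise <- bonferroni_pairwise_t(groups, omnibus_p = out$p_value,
                                          alpha = alpha)
  out
}

#' @export
print.group_comparison <- function(x, ...) {
  lab <- if (x$test == "ANOVA_F") "F" else "H"
  cat(sprintf("<group_comparison> %s = %.3f, dof = %s, P = %.4g\n",
              lab, x$statistic, paste(x$dof, collapse = ","), x$p_value))
  if (!is.null(x$gates))
    cat("  route:", if (x$gates$parametric) "one-way ANOVA" else
      "ANOVA on ranks (failed normality/equal-variance gate)", "\n")
  if (!is.null(x$pairwise)) {
    cat("  Bonferroni pairwise comparisons:\n")
    print(x$pairwise, row.names = FALSE)
  }
  invisible(x)
}

.check_groups <- function(groups) {
  if (!is.list(groups) || length(groups) < 2)
    stop("need at least 2 groups")
  ns <- vapply(groups, length, 0L)
  if (any(ns < 2))
    stop("every group needs n >= 2")
  invisible(TRUE)
}

.stack_groups <- function(groups) {
  nm <- names(groups)
  if (is.null(nm) || any(!nzchar(nm)))
    nm <- paste0("g", seq_along(groups))
  data.frame(value = unlist(groups, use.names = FALSE),
             group = factor(rep(nm, vapply(groups, length, 0L)), levels = nm))
}
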