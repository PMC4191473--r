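# Group statistics: two-sample t statistics from printed summaries
# (mean, SEM, n) or raw values, and a mixed repeated-measures ANOVA with a
# linear within-subject contrast.

#' Group summary triplet
#'
#' @param mean group mean (response units).
#' @param sem standard error of the mean; must be positive.
#' @param n number of animals; must be at least 2.
#' @param label optional group label.
#' @return object of class `group_summary`.
#' @export
group_summary <- function(mean, sem, n, label = NA_character_) {
  stopifnot_scalar(mean, "mean"); stopifnot_scalar(sem, "sem")
  if (sem <= 0) stop("'sem' must be positive", call. = FALSE)
  if (n < 2) stop("'n' must be at least 2", call. = FALSE)
  structure(list(mean = mean, sem = sem, n = as.integer(n), label = label),
            class = "group_summary")
}

#' Two-sample t statistic from group summaries
#'
#' Computes the t statistic from two (mean, SEM, n) triplets. The default
#' combines the SEMs in quadrature, `t = (m1 - m2) / sqrt(sem1^2 + sem2^2)`,
#' with `df = n1 + n2 - 2`; this is the form that reproduces published t/df
#' pairs computed from per-group SEMs. `pooled = TRUE` uses the classical
#' pooled-variance statistic instead (same df).
#'
#' @param g1,g2 `group_summary` objects (see [group_summary()]).
#' @param pooled use the pooled-variance t instead of SEM quadrature.
#' @return object of class `summary_ttest`: `t`, `df`, `p` (two-sided),
#'   method and labels. The sign follows `g1 - g2`.
#' @examples
#' t_from_summary(group_summary(197.16, 19.5, 12),
#'                group_summary(120.2, 8.6, 9))
#' @export
t_from_summary <- function(g1, g2, pooled = FALSE) {
  if (!inherits(g1, "group_summary") || !inherits(g2, "group_summary"))
    stop("inputs must be group_summary objects", call. = FALSE)
  df <- g1$n + g2$n - 2L
  if (pooled) {
    s1 <- g1$sem * sqrt(g1$n); s2 <- g2$sem * sqrt(g2$n)
    sp2 <- ((g1$n - 1) * s1^2 + (g2$n - 1) * s2^2) / df
    tval <- (g1$mean - g2$mean) / sqrt(sp2 * (1 / g1$n + 1 / g2$n))
  } else {
    tval <- (g1$mean - g2$mean) / sqrt(g1$sem^2 + g2$sem^2)
  }
  structure(list(
    t = tval, df = df, p = 2 * stats::pt(-abs(tval), df),
    method = if (pooled) "pooled variance" else "SEM quadrature",
    labels = c(g1$label, g2$label)
  ), class = "summary_ttest")
}

#' Two-sample t statistic from raw values
#'
#' Computes per-group means and SEMs and delegates to [t_from_summary()];
#' the two are exactly equal by construction.
#'
#' @param values1,values2 numeric vectors of per-animal values (length >= 2).
#' @param pooled passed to [t_from_summary()].
#' @param labels optional length-2 character vector of group labels.
#' @return a `summary_ttest`.
#' @export
t_from_raw <- function(values1, values2, pooled = FALSE,
                       labels = c(NA_character_, NA_character_)) {
  if (length(values1) < 2 || length(values2) < 2)
    stop("each group needs at least 2 values", call. = FALSE)
  g <- function(v, lab) group_summary(mean(v), stats::sd(v) / sqrt(length(v)),
                                      length(v), lab)
  t_from_summary(g(values1, labels[1]), g(values2, labels[2]), pooled = pooled)
}

#' @export
print.summary_ttest <- function(x, ...) {
  lab <- if (all(is.na(x$labels))) "" else
    sprintf(" (%s vs %s)", x$labels[1], x$labels[2])
  cat(sprintf("Two-sample t%s [%s]: t = %.3f, df = %d, p = %.4g\n",
              lab, x$method, x$t, x$df, x$p))
  invisible(x)
}

#' Repeated-measures ANOVA with a linear within-subject contrast
#'
#' For a balanced group x subject x ordered-condition table, computes
#' (1) the between-group F on subject mean scores (the between-subjects
#' stratum of the split-plot ANOVA) and (2) the F of the linear
#' within-subject trend: each subject's condition profile is projected onto
#' orthonormal linear-contrast coefficients over the ordered conditions, and
#' the squared grand mean of the projections is tested against their
#' within-group variance. A df = 1 contrast needs no
#' sphericity correction.
#'
#' @param data data frame with one row per observation.
#' @param value,group,subject,condition names of the respective columns;
#'   conditions are ordered by their factor levels (or sorted unique values).
#' @return object of class `rm_anova`: `F_between`, `df_between` (numerator,
#'   denominator), `p_between`, `F_linear`, `df_linear`, `p_linear`, plus the
#'   linear x group interaction F.
#' @export
rm_anova_linear <- function(data, value = "value", group = "group",
                            subject = "subject", condition = "condition") {
  need <- c(value, group, subject, condition)
  if (!all(need %in% names(data)))
    stop("data must contain columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  y <- data[[value]]
  g <- as.factor(data[[group]])
  s <- as.factor(data[[subject]])
  cf <- data[[condition]]
  cf <- if (is.factor(cf)) droplevels(cf) else factor(cf, sort(unique(cf)))
  k <- nlevels(cf)
  if (k < 2) stop("need at least two conditions", call. = FALSE)
  # balanced wide table: subjects x conditions
  tab <- tapply(y, list(s, cf), mean)
  if (anyNA(tab))
    stop("missing cells: every subject needs every condition", call. = FALSE)
  subj_group <- tapply(as.character(g), s, function(z) unique(z)[1])
  if (any(tapply(as.character(g), s, function(z) length(unique(z))) != 1))
    stop("each subject must belong to exactly one group", call. = FALSE)
  gs <- factor(subj_group[rownames(tab)])
  n_per <- table(gs)
  if (any(n_per < 2)) stop("need at least 2 subjects per group", call. = FALSE)
  N <- nrow(tab)
  ngr <- nlevels(gs)

  # between-subjects stratum, on subject means scaled by k conditions
  sm <- rowMeans(tab)
  grand <- mean(sm)
  gm <- tapply(sm, gs, mean)
  ss_between <- k * sum(n_per * (gm - grand)^2)
  ss_subj <- k * sum((sm - gm[gs])^2)
  df_b <- c(ngr - 1, N - ngr)
  F_between <- (ss_between / df_b[1]) / (ss_subj / df_b[2])

  # within-subject linear contrast (orthonormal over equally spaced levels)
  cc <- stats::contr.poly(k)[, 1]
  L <- as.vector(tab %*% cc)
  Lg <- tapply(L, gs, mean)
  ss_lin <- N * mean(L)^2              # = (sum L)^2 / N, df 1
  ss_lin_g <- sum(n_per * (Lg - mean(L))^2)   # linear x group interaction
  ss_err <- sum((L - Lg[gs])^2)
  df_e <- N - ngr
  F_linear <- ss_lin / (ss_err / df_e)
  F_lin_group <- (ss_lin_g / (ngr - 1)) / (ss_err / df_e)

  structure(list(
    F_between = F_between, df_between = df_b,
    p_between = stats::pf(F_between, df_b[1], df_b[2], lower.tail = FALSE),
    F_linear = F_linear, df_linear = c(1, df_e),
    p_linear = stats::pf(F_linear, 1, df_e, lower.tail = FALSE),
    F_linear_by_group = F_lin_group,
    df_linear_by_group = c(ngr - 1, df_e),
    n_subjects = N, n_conditions = k, groups = levels(gs)
  ), class = "rm_anova")
}

#' @export
print.rm_anova <- function(x, ...) {
  cat(sprintf(paste0(
    "Repeated-measures ANOVA (%d subjects, %d ordered conditions)\n",
    "  between groups:        F = %8.3f, df = (%d, %d), p = %.4g\n",
    "  linear within subject: F = %8.3f, df = (%d, %d), p = %.4g\n",
    "  linear x group:        F = %8.3f, df = (%d, %d)\n"),
    x$n_subjects, x$n_conditions,
    x$F_between, x$df_between[1], x$df_between[2], x$p_between,
    x$F_linear, x$df_linear[1], x$df_linear[2], x$p_linear,
    x$F_linear_by_group, x$df_linear_by_group[1], x$df_linear_by_group[2]))
  invisible(x)
}
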