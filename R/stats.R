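#' Pearson correlation of a per-subject measure with age
#'
#' Pearson r with a two-sided p-value. When a family of p-values from the
#' parallel tests across stimuli is supplied, a Benjamini-Hochberg
#' false-discovery-rate flag is returned for this test at level `fdr_q`
#' (this test's p must be part of `family`).
#'
#' @param values per-subject numeric values (e.g. ISC).
#' @param ages per-subject ages in years, same order.
#' @param fdr_q FDR level (default 0.05).
#' @param family optional numeric vector of the p-values across the test
#'   family, including this one's.
#' @return A list with `r`, `p`, `n`, and (when `family` given) `fdr_flag`.
#' @export
correlate_with_age <- function(values, ages, fdr_q = 0.05, family = NULL) {
  ok <- is.finite(values) & is.finite(ages)
  values <- values[ok]; ages <- ages[ok]
  if (length(values) < 3L) stop("need at least 3 paired observations")
  if (stats::sd(values) == 0 || stats::sd(ages) == 0)
    stop("zero variance: correlation undefined")
  ct <- stats::cor.test(values, ages, method = "pearson")
  out <- list(r = unname(ct$estimate), p = ct$p.value, n = length(values))
  if (!is.null(family)) {
    adj <- stats::p.adjust(family, method = "BH")
    i <- which.min(abs(family - out$p))
    if (abs(family[i] - out$p) > 1e-12)
      stop("this test's p-value is not in the supplied family")
    out$fdr_flag <- adj[i] <= fdr_q
  }
  out
}

#' Median split of a subject table into young and old groups
#'
#' Subjects at or below the boundary become `"young"`, the rest `"old"`.
#' By default the boundary is the cohort median age; a fixed boundary
#' (e.g. 14, splitting 6-14 from 15-44) reproduces a predetermined split
#' across cohorts.
#'
#' @param table data.frame with columns `subject_id`, `age`.
#' @param boundary fixed age boundary; `NULL` (default) uses the median.
#' @return The table with an added `age_group` factor column.
#' @export
median_split <- function(table, boundary = NULL) {
  if (nrow(table) < 2L) stop("need at least 2 subjects")
  if (is.null(boundary)) boundary <- stats::median(table$age)
  grp <- ifelse(table$age <= boundary, "young", "old")
  if (length(unique(grp)) == 1L)
    warning("all subjects fall on one side of the split (boundary ",
            boundary, ")")
  table$age_group <- factor(grp, levels = c("young", "old"))
  table
}

#' Two-way ANOVA main effects (Type II sums of squares)
#'
#' Additive model `values ~ a + b` with main-effect F tests; Type II sums
#' of squares accommodate unbalanced groups. With `b = NULL` the reduction
#' to a one-way ANOVA is returned (its F equals the squared pooled
#' two-sample t statistic when `a` has two levels).
#'
#' @param values numeric response.
#' @param factor_a,factor_b grouping labels; `factor_b` may be `NULL`.
#' @return A list with `F_a`, `p_a`, `df_a`, (when present `F_b`, `p_b`,
#'   `df_b`) and `df_resid`.
#' @export
two_way_anova <- function(values, factor_a, factor_b = NULL) {
  a <- factor(factor_a)
  if (nlevels(a) < 2L) stop("factor_a needs at least 2 levels")
  if (is.null(factor_b)) {
    fit <- stats::lm(values ~ a)
    tab <- stats::anova(fit)
    return(list(F_a = tab$`F value`[1L], p_a = tab$`Pr(>F)`[1L],
                df_a = tab$Df[1L], df_resid = tab$Df[2L]))
  }
  b <- factor(factor_b)
  if (nlevels(b) < 2L) stop("factor_b needs at least 2 levels")
  cells <- table(a, b)
  if (any(cells == 0L)) {
    idx <- which(cells == 0L, arr.ind = TRUE)
    empty <- paste(rownames(cells)[idx[, 1]], colnames(cells)[idx[, 2]],
                   sep = ":")
    stop("empty cell(s): ", paste(empty, collapse = ", "))
  }
  fit <- stats::lm(values ~ a + b)
  tab <- car::Anova(fit, type = "II")
  list(F_a = tab$`F value`[1L], p_a = tab$`Pr(>F)`[1L], df_a = tab$Df[1L],
       F_b = tab$`F value`[2L], p_b = tab$`Pr(>F)`[2L], df_b = tab$Df[2L],
       df_resid = tab$Df[nrow(tab)])
}

#' Tukey-Kramer post hoc pairwise comparisons
#'
#' Studentized-range comparisons of all group pairs, valid for unequal
#' group sizes. Groups of size 1 are excluded with a warning.
#'
#' @param values numeric response.
#' @param labels group labels.
#' @param conf_level confidence level for the intervals (default 0.95).
#' @return data.frame with columns `comparison`, `diff`, `lwr`, `upr`,
#'   `p_adj`.
#' @export
tukey_hsd <- function(values, labels, conf_level = 0.95) {
  g <- factor(labels)
  sizes <- table(g)
  if (any(sizes < 2L)) {
    drop <- names(sizes)[sizes < 2L]
    warning("excluding size-1 group(s): ", paste(drop, collapse = ", "))
    keep <- !(g %in% drop)
    values <- values[keep]; g <- droplevels(g[keep])
  }
  if (nlevels(g) < 2L) stop("need at least 2 groups of size >= 2")
  hsd <- stats::TukeyHSD(stats::aov(values ~ g), conf.level = conf_level)$g
  data.frame(comparison = rownames(hsd), diff = hsd[, "diff"],
             lwr = hsd[, "lwr"], upr = hsd[, "upr"],
             p_adj = hsd[, "p adj"], row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Residualize ISC on SSVEP band power
#'
#' Regresses per-subject ISC on SSVEP amplitude (with intercept) by
#' ordinary least squares and returns the residuals, i.e. the portion of
#' ISC not explained by evoked-response magnitude. Subjects are paired by
#' `subject_id` (inner join).
#'
#' @param isc data.frame with `subject_id`, `isc` (or a named numeric
#'   vector).
#' @param ssvep data.frame with `subject_id`, `band_power` (or a named
#'   numeric vector).
#' @return data.frame with `subject_id`, `isc`, `band_power`,
#'   `residual` (mean zero, orthogonal to `band_power`).
#' @export
residualize_isc <- function(isc, ssvep) {
  to_df <- function(x, col) {
    if (is.data.frame(x)) return(x[, c("subject_id", col)])
    data.frame(subject_id = names(x), v = as.numeric(x),
               stringsAsFactors = FALSE) |>
      stats::setNames(c("subject_id", col))
  }
  m <- merge(to_df(isc, "isc"), to_df(ssvep, "band_power"),
             by = "subject_id")
  if (nrow(m) < 3L) stop("need at least 3 paired subjects, have ", nrow(m))
  m$residual <- stats::residuals(stats::lm(isc ~ band_power, data = m))
  m
}
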