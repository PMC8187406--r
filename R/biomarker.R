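# Serum biomarker statistics: multiple-of-the-median (MoM)
# normalization, analyte MoM ratios, percent-increase effects and the
# associated significance tests.

#' Express serum concentrations as multiples of the median (MoM)
#'
#' Divides each subject's concentration by the median concentration of
#' the reference group at the same gestational week and analyte, the
#' standard prenatal-screening normalization. By construction the
#' reference-group MoM median is exactly 1 in every (week, analyte)
#' stratum, and MoM values are invariant to per-analyte unit rescaling.
#'
#' @param table long-format data.frame with columns `subject`, `group`,
#'   `week`, `analyte`, `concentration` (one positive value per
#'   (subject, week, analyte)).
#' @param reference group label used as the reference population
#'   (default "healthy"); the alternative is to reference against all
#'   subjects with `reference = NULL`.
#' @return The input with an added `mom` column.
#' @export
compute_mom <- function(table, reference = "healthy") {
  req <- c("subject", "group", "week", "analyte", "concentration")
  if (!all(req %in% names(table)))
    stopf("biomarker table must have columns %s", paste(req, collapse = ", "))
  if (any(table$concentration <= 0))
    stopf("concentrations must be > 0")
  strata <- interaction(table$week, table$analyte, drop = TRUE)
  ref_rows <- if (is.null(reference)) rep(TRUE, nrow(table)) else
    table$group == reference
  med <- vapply(levels(strata), function(s) {
    v <- table$concentration[ref_rows & strata == s]
    if (length(v) == 0L)
      stopf("empty reference stratum (week.analyte = %s)", s)
    stats::median(v)
  }, numeric(1))
  table$mom <- table$concentration / med[as.character(strata)]
  table
}

#' Per-subject ratio of two analytes' MoM values
#'
#' Composite biomarkers such as sFLT1/MIF are evaluated as the quotient
#' of the two analytes' MoM values within each subject and week.
#' Subjects missing either analyte at a week are excluded and counted.
#'
#' @param moms MoM table from [compute_mom()].
#' @param numerator,denominator analyte names.
#' @return data.frame `subject`, `group`, `week`, `ratio`; attribute
#'   `n_excluded` counts subject-weeks missing an analyte.
#' @export
mom_ratio <- function(moms, numerator, denominator) {
  num <- moms[moms$analyte == numerator, c("subject", "group", "week", "mom")]
  den <- moms[moms$analyte == denominator, c("subject", "week", "mom")]
  if (nrow(num) == 0L || nrow(den) == 0L)
    stopf("analyte not present in MoM table")
  merged <- merge(num, den, by = c("subject", "week"),
                  suffixes = c("_num", "_den"))
  n_excluded <- nrow(num) + nrow(den) - 2L * nrow(merged)
  out <- data.frame(subject = merged$subject, group = merged$group,
                    week = merged$week,
                    ratio = merged$mom_num / merged$mom_den,
                    stringsAsFactors = FALSE)
  structure(out[order(out$week, out$subject), , drop = FALSE],
            n_excluded = n_excluded)
}

#' Percent increase of a case group over a reference group
#'
#' `100 * (mean(case) - mean(ref)) / mean(ref)`; e.g. a case/reference
#' mean ratio of 3.1 is a 210 percent increase.
#'
#' @param values_case,values_ref numeric vectors.
#' @return Percent increase (scalar).
#' @export
percent_increase <- function(values_case, values_ref) {
  if (length(values_case) == 0L || length(values_ref) == 0L)
    stopf("both groups must be non-empty")
  m_ref <- mean(values_ref)
  if (m_ref <= 0)
    stopf("reference mean must be > 0")
  100 * (mean(values_case) - m_ref) / m_ref
}

#' Two-sample t test (Student or Welch)
#'
#' @param a,b numeric vectors of length >= 2.
#' @param variant "student" (pooled variance, the default) or "welch".
#' @return List with `t`, `df`, `p` (two-sided).
#' @export
two_sample_ttest <- function(a, b, variant = c("student", "welch")) {
  variant <- match.arg(variant)
  if (length(a) < 2L || length(b) < 2L)
    stopf("each sample needs at least 2 observations")
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    if (isTRUE(all.equal(mean(a), mean(b)))) {
      warnf("degenerate zero-variance samples with equal means: p = 1")
      df <- if (variant == "student") length(a) + length(b) - 2L else NA_real_
      return(list(t = 0, df = df, p = 1))
    }
    stopf("zero-variance samples with unequal means: t undefined")
  }
  res <- stats::t.test(a, b, var.equal = variant == "student")
  list(t = unname(res$statistic), df = unname(res$parameter),
       p = res$p.value)
}

#' Two-way fixed-effects ANOVA with interaction
#'
#' Fits `value ~ group * week` and reports F and p for the group effect,
#' the week effect and their interaction, using Type II sums of squares
#' so unbalanced designs are handled sensibly. When the week factor has
#' a single level the model reduces to a one-way ANOVA on group (whose F
#' equals the squared pooled t statistic).
#'
#' @param values numeric response.
#' @param group,week factors (coerced); every group x week cell must be
#'   non-empty.
#' @return data.frame with rows `group`, `week`, `group:week` (as
#'   applicable) and columns `F`, `df`, `p`.
#' @export
two_way_anova <- function(values, group, week) {
  group <- factor(group)
  week <- factor(week)
  if (nlevels(group) < 2L)
    stopf("group factor needs at least 2 levels")
  tab <- table(group, week)
  if (any(tab == 0L)) {
    empty <- which(tab == 0L, arr.ind = TRUE)[1L, ]
    stopf("empty cell: group = %s, week = %s",
          rownames(tab)[empty[1]], colnames(tab)[empty[2]])
  }
  if (nlevels(week) < 2L) {
    fit <- stats::lm(values ~ group)
    a <- stats::anova(fit)
    return(data.frame(effect = "group", F = a$`F value`[1L],
                      df = a$Df[1L], p = a$`Pr(>F)`[1L],
                      stringsAsFactors = FALSE))
  }
  fit <- stats::lm(values ~ group * week)
  a <- car::Anova(fit, type = 2)
  rows <- c("group", "week", "group:week")
  data.frame(effect = rows,
             F = a[rows, "F value"],
             df = a[rows, "Df"],
             p = a[rows, "Pr(>F)"],
             row.names = NULL,
             stringsAsFactors = FALSE)
}

#' t test from summary statistics (mean, SEM, n)
#'
#' Clinical tables often report only mean +/- SEM and n per group; the t
#' statistic is recovered from these (SD = SEM * sqrt(n)) under the
#' pooled (Student) or Welch variance assumption.
#'
#' @param mean1,sem1,n1 summary of group 1.
#' @param mean2,sem2,n2 summary of group 2.
#' @param variant "student" (default) or "welch".
#' @return List with `t`, `df`, `p` (two-sided).
#' @export
summary_ttest <- function(mean1, sem1, n1, mean2, sem2, n2,
                          variant = c("student", "welch")) {
  variant <- match.arg(variant)
  if (n1 < 2L || n2 < 2L) stopf("n1 and n2 must be >= 2")
  if (sem1 < 0 || sem2 < 0) stopf("SEMs must be >= 0")
  if (sem1 == 0 && sem2 == 0) {
    if (isTRUE(all.equal(mean1, mean2))) {
      warnf("degenerate zero-SEM summaries with equal means: p = 1")
      return(list(t = 0, df = n1 + n2 - 2, p = 1))
    }
    stopf("zero-SEM summaries with unequal means: t undefined")
  }
  s1sq <- (sem1 * sqrt(n1))^2
  s2sq <- (sem2 * sqrt(n2))^2
  if (variant == "student") {
    sp2 <- ((n1 - 1) * s1sq + (n2 - 1) * s2sq) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    se <- sqrt(s1sq / n1 + s2sq / n2)
    df <- (s1sq / n1 + s2sq / n2)^2 /
      ((s1sq / n1)^2 / (n1 - 1) + (s2sq / n2)^2 / (n2 - 1))
  }
  t <- (mean1 - mean2) / se
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}
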