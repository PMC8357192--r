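#' Compare per-sample ROI means across treatment groups
#'
#' One-way ANOVA with Tukey HSD post-hoc pairwise comparisons (family
#' level 0.05), delegating to [stats::aov()] and [stats::TukeyHSD()]. With
#' exactly two groups the ANOVA F test is equivalent to the two-sample
#' t test with pooled variance.
#'
#' @param samples Named list of numeric vectors: one per group, each
#'   element a per-sample summary (e.g. ROI mean depletion thickness).
#' @return A [GroupComparison-class]. When all observations are identical
#'   the F statistic is undefined and flagged `degenerate`.
#' @examples
#' compareGroups(list(control = c(1, 2, 3), treated = c(11, 12, 13)))
#' @export
compareGroups <- function(samples) {
  if (!is.list(samples) || length(samples) < 2L)
    stop("need >= 2 groups")
  if (any(lengths(samples) < 2L))
    stop("need >= 2 samples per group")
  if (is.null(names(samples)))
    names(samples) <- paste0("group", seq_along(samples))
  df <- data.frame(
    value = unlist(samples, use.names = FALSE),
    group = factor(rep(names(samples), lengths(samples)),
                   levels = names(samples))
  )
  stats <- data.frame(
    group = names(samples),
    n = lengths(samples),
    mean = vapply(samples, mean, numeric(1)),
    sd = vapply(samples, stats::sd, numeric(1)),
    row.names = NULL
  )
  degenerate <- sum(tapply(df$value, df$group,
                           function(v) sum((v - mean(v))^2))) < 1e-300
  if (degenerate) {
    pw <- data.frame(comparison = character(0), diff = numeric(0),
                     pAdj = numeric(0))
    return(new("GroupComparison", groupStats = stats,
               fStatistic = NA_real_, pValue = NA_real_,
               pairwise = pw, degenerate = TRUE))
  }
  fit <- stats::aov(value ~ group, data = df)
  an <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit, conf.level = 0.95)$group
  pw <- data.frame(comparison = rownames(tk),
                   diff = tk[, "diff"],
                   pAdj = tk[, "p adj"],
                   row.names = NULL)
  new("GroupComparison", groupStats = stats,
      fStatistic = an[["F value"]][1], pValue = an[["Pr(>F)"]][1],
      pairwise = pw, degenerate = FALSE)
}
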