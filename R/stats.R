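# Group-level statistics used in the results tables: mean +/- SEM
# summaries, paired t, balanced two-factor ANOVA, and one-way ANOVA
# with Bonferroni-corrected pairwise post hoc tests.

#' Mean +/- SEM summary table
#'
#' @param values Numeric vector of observations.
#' @param group Grouping vector (condition/measure labels).
#' @return Data frame with `group`, `mean`, `sem` (sd/sqrt(n)), `n`.
#' @export
summary_table <- function(values, group) {
  stopifnot(length(values) == length(group), length(values) >= 1)
  aggregate_mean_sem(values, group)
}

#' Paired t-test between matched per-unit values
#'
#' @param a,b Equal-length numeric vectors paired by experimental unit
#'   (typically per-rat means).
#' @return List with `t`, `df`, `p_value`, `mean_difference`.
#' @export
paired_compare <- function(a, b) {
  if (length(a) != length(b)) stop("a and b must have equal length", call. = FALSE)
  if (length(a) < 2L) stop("need at least 2 pairs", call. = FALSE)
  d <- a - b
  if (stats::sd(d) == 0) {
    if (all(d == 0)) return(list(t = 0, df = length(d) - 1L, p_value = 1,
                                 mean_difference = 0))
    stop("paired differences have zero variance; t is undefined", call. = FALSE)
  }
  ht <- stats::t.test(a, b, paired = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value, mean_difference = mean(d))
}

#' Balanced two-factor fixed-effects ANOVA
#'
#' Used for the data-type x dimension comparisons (e.g. real vs
#' optimised routes crossed with layer vs column OD).
#'
#' @param values Numeric observations.
#' @param factor_a,factor_b Factor levels per observation.
#' @return Data frame with one row per effect (`A`, `B`, `A:B`):
#'   `effect`, `df1`, `df2`, `F`, `p_value`.
#' @export
two_factor_anova <- function(values, factor_a, factor_b) {
  fa <- factor(factor_a)
  fb <- factor(factor_b)
  stopifnot(length(values) == length(fa), length(values) == length(fb),
            nlevels(fa) >= 2, nlevels(fb) >= 2)
  cell_n <- table(fa, fb)
  if (any(cell_n < 2)) stop("need >= 2 observations per cell", call. = FALSE)
  if (length(unique(as.vector(cell_n))) != 1) {
    stop("design must be balanced (equal cell sizes)", call. = FALSE)
  }
  fit <- stats::aov(values ~ fa * fb)
  tab <- summary(fit)[[1]]  # rows: fa, fb, fa:fb, Residuals
  df2 <- tab[4, "Df"]
  data.frame(effect = c("A", "B", "A:B"),
             df1 = tab[1:3, "Df"],
             df2 = df2,
             F = tab[1:3, "F value"],
             p_value = tab[1:3, "Pr(>F)"],
             row.names = NULL)
}

#' One-way ANOVA with Bonferroni pairwise post hoc tests
#'
#' @param values Numeric observations.
#' @param group Group labels (>= 2 groups, each with >= 2 observations).
#' @return List with `F`, `df1`, `df2`, `p_value`, and `pairwise`
#'   (data frame of group pairs with raw and Bonferroni-adjusted
#'   p-values, adjusted = min(1, m x raw) over the m pairs).
#' @export
oneway_anova_bonferroni <- function(values, group) {
  g <- factor(group)
  stopifnot(length(values) == length(g), nlevels(g) >= 2)
  if (any(table(g) < 2)) stop("every group needs >= 2 observations", call. = FALSE)
  fit <- stats::aov(values ~ g)
  tab <- summary(fit)[[1]]
  lv <- levels(g)
  pairs <- utils::combn(lv, 2)
  m <- ncol(pairs)
  pw <- do.call(rbind, lapply(seq_len(m), function(i) {
    a <- values[g == pairs[1, i]]
    b <- values[g == pairs[2, i]]
    p_raw <- stats::t.test(a, b, var.equal = TRUE)$p.value
    data.frame(group1 = pairs[1, i], group2 = pairs[2, i],
               p_raw = p_raw, p_bonferroni = min(1, m * p_raw))
  }))
  list(F = tab[1, "F value"], df1 = tab[1, "Df"], df2 = tab["Residuals", "Df"],
       p_value = tab[1, "Pr(>F)"], pairwise = pw)
}
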