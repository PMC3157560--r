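# Detour route-choice analysis: tallies of horizontal-first vs
# vertical-first choices around a barrier, with exact binomial
# confidence intervals per condition, and the per-rat one-sample t-test
# on proportions used for the pooled inference.

#' Tally detour choices by condition
#'
#' Counts horizontal-first choices and completed trials per group.
#' Records whose `choice` is `"none"` or `NA` (incomplete trials) are
#' excluded from the denominators; groups with no completed trial are
#' dropped with a warning.
#'
#' @param records Data frame with at least `choice`
#'   (`"horizontal_first"` / `"vertical_first"` / `"none"`) and the
#'   grouping columns.
#' @param by Character vector of grouping column names (default
#'   `"direction"`).
#' @param conf_level Confidence level of the exact binomial interval.
#' @return Data frame: grouping columns, `k` (horizontal-first), `n`
#'   (completed), `proportion`, `ci_lo`, `ci_hi`.
#' @examples
#' d <- simulate_detours(c(up = 0.95, down = 0.4), seed = 1)
#' tally_choices(d)
#' @export
tally_choices <- function(records, by = "direction", conf_level = 0.95) {
  stopifnot(nrow(records) > 0, all(by %in% names(records)),
            "choice" %in% names(records))
  completed <- !is.na(records$choice) & records$choice != "none"
  g <- interaction(records[by], drop = TRUE, sep = "\r")
  out <- lapply(levels(g), function(lv) {
    sel <- g == lv & completed
    n <- sum(sel)
    keys <- strsplit(lv, "\r", fixed = TRUE)[[1]]
    row <- as.data.frame(as.list(stats::setNames(keys, by)),
                         stringsAsFactors = FALSE)
    if (n == 0L) {
      warning(sprintf("group '%s' has no completed trials; omitted",
                      paste(keys, collapse = "/")), call. = FALSE)
      return(NULL)
    }
    k <- sum(records$choice[sel] == "horizontal_first")
    ci <- stats::binom.test(k, n, conf.level = conf_level)$conf.int
    cbind(row, data.frame(k = k, n = n, proportion = k / n,
                          ci_lo = ci[1], ci_hi = ci[2]))
  })
  do.call(rbind, out)
}

#' One-sample t-test on per-rat choice proportions
#'
#' Each rat's proportion of horizontal-first choices among its completed
#' trials is one observation; the test compares these proportions
#' against `null_p` with df = n_rats - 1.
#'
#' @param records Data frame with `rat` and `choice` columns (optionally
#'   pre-filtered to one condition).
#' @param null_p Null proportion (default 0.5, indifference).
#' @return List with `t`, `df`, `p_value`, `mean_proportion`,
#'   `per_rat` (named vector of proportions).
#' @export
per_rat_proportion_test <- function(records, null_p = 0.5) {
  stopifnot("rat" %in% names(records), "choice" %in% names(records))
  completed <- records[!is.na(records$choice) & records$choice != "none", ]
  props <- tapply(completed$choice == "horizontal_first", completed$rat, mean)
  props <- props[!is.na(props)]
  if (length(props) < 2L) {
    stop("need at least 2 rats with completed trials", call. = FALSE)
  }
  if (stats::sd(props) == 0) {
    # degenerate: all rats identical; t is 0 at the null, infinite otherwise
    t_stat <- if (props[1] == null_p) 0 else sign(props[1] - null_p) * Inf
    return(list(t = t_stat, df = length(props) - 1L,
                p_value = if (props[1] == null_p) 1 else 0,
                mean_proportion = unname(props[1]),
                per_rat = props))
  }
  ht <- stats::t.test(props, mu = null_p)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value, mean_proportion = mean(props),
       per_rat = props)
}
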