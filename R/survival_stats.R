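# Survival curves, log-rank comparison, median splits, and the shared
# statistical utilities (normality-gated test selection, ANOVA + Tukey,
# Benjamini-Hochberg correction).

#' Kaplan-Meier product-limit estimate
#'
#' @param times Follow-up times (days), non-negative.
#' @param events Logical event indicators (TRUE = progression observed);
#'   defaults to all observed, matching cohorts where every progression
#'   time is known.
#' @return List with `table` (tibble: time, n_risk, n_event, survival), the
#'   underlying `survival::survfit` object (`fit`), and `surv_fn`, a step
#'   function t -> S(t) with S(0) = 1.
#' @export
km_estimate <- function(times, events = rep(TRUE, length(times))) {
  if (length(times) < 1) stop("need at least one subject")
  if (any(times < 0)) stop("times must be non-negative")
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  tab <- tibble::tibble(time = fit$time, n_risk = fit$n.risk,
                        n_event = fit$n.event, survival = fit$surv)
  ev <- tab[tab$n_event > 0, ]
  surv_fn <- if (nrow(ev) == 0) {
    function(t) rep(1, length(t))
  } else {
    stats::stepfun(ev$time, c(1, ev$survival), right = FALSE)
  }
  list(table = tab, fit = fit, surv_fn = surv_fn)
}

#' Two-group log-rank test
#'
#' Standard chi-square log-rank statistic with 1 degree of freedom,
#' symmetric in the group labels. With no events in either group the test
#' is undefined and `NA` is returned with a warning.
#'
#' @param times Follow-up times for all subjects.
#' @param events Event indicators.
#' @param group Two-level group labels.
#' @return List: statistic, df, p, n per group.
#' @export
logrank_test <- function(times, events, group) {
  group <- as.factor(group)
  if (nlevels(droplevels(group)) != 2) stop("need exactly two non-empty groups")
  if (!any(events)) {
    warning("no events in either group: log-rank undefined")
    return(list(statistic = NA_real_, df = 1L, p = NA_real_,
                n = table(group)))
  }
  fit <- survival::survdiff(survival::Surv(times, events) ~ group)
  stat <- fit$chisq
  list(statistic = stat, df = 1L, p = pchisq(stat, df = 1, lower.tail = FALSE),
       n = table(group))
}

#' Split subjects at the median of a scalar
#'
#' `"low"` holds values strictly below the median, `"high"` values strictly
#' above; values equal to the median go to `"low"` by default (the tie
#' policy is explicit and configurable since the split of the median
#' subject is a convention).
#'
#' @param values Named numeric vector (names = subject ids) or plain vector.
#' @param ties `"low"` (default) or `"high"`: the side receiving values
#'   equal to the median.
#' @return Tibble: id, value, group (factor low/high).
#' @export
median_split <- function(values, ties = c("low", "high")) {
  ties <- match.arg(ties)
  if (length(values) < 2) stop("need at least two subjects")
  med <- median(values)
  group <- ifelse(values < med, "low",
                  ifelse(values > med, "high", ties))
  if (length(unique(group)) < 2) {
    stop("median split degenerate: one group is empty")
  }
  ids <- if (!is.null(names(values))) names(values) else
    as.character(seq_along(values))
  tibble::tibble(id = ids, value = unname(values),
                 group = factor(group, levels = c("low", "high")))
}

#' Normality-gated two-sample test
#'
#' Dispatches between parametric and rank-based two-sample tests using a
#' Shapiro-Wilk gate at `alpha_normality`: for paired samples the gate is
#' applied to the differences and the test is a paired t-test or Wilcoxon
#' signed-rank test; for independent samples the gate is applied to each
#' sample and the test is an independent t-test or Mann-Whitney U test
#' (parametric only when both samples pass).
#'
#' @param a,b Numeric samples (equal length when `paired`).
#' @param paired Paired design.
#' @param tail `"two.sided"`, `"greater"` (a > b), or `"less"`.
#' @param alpha_normality Gate level for the Shapiro-Wilk tests.
#' @return List: method ("t" or "rank"), paired, normal (gate outcome),
#'   statistic, p.
#' @export
choose_and_run_test <- function(a, b, paired = FALSE,
                                tail = c("two.sided", "greater", "less"),
                                alpha_normality = 0.05) {
  tail <- match.arg(tail)
  if (length(a) < 3 || length(b) < 3) {
    stop("need at least three observations per sample for the normality gate")
  }
  shapiro_ok <- function(v) {
    if (length(unique(v)) == 1) return(FALSE) # degenerate: no evidence of normality
    shapiro.test(v)$p.value >= alpha_normality
  }
  normal <- if (paired) shapiro_ok(a - b) else shapiro_ok(a) && shapiro_ok(b)
  tst <- if (normal) {
    t.test(a, b, paired = paired, alternative = tail)
  } else {
    suppressWarnings(wilcox.test(a, b, paired = paired, alternative = tail,
                                 exact = FALSE))
  }
  list(method = if (normal) "t" else "rank", paired = paired,
       normal = normal, statistic = unname(tst$statistic), p = tst$p.value)
}

#' One-way ANOVA with Tukey HSD post-hoc
#'
#' Omnibus one-way ANOVA across groups; the Tukey honestly-significant-
#' difference table is computed only when the omnibus p-value is below
#' `alpha`.
#'
#' @param values Numeric observations.
#' @param groups Group labels (>= 2 groups, >= 2 observations each).
#' @param alpha Omnibus gate for running the post-hoc (default 0.05).
#' @return List: f, p, tukey (tibble comparison, diff, lwr, upr, p_adj, or
#'   `NULL` when the omnibus is not significant).
#' @export
anova_tukey <- function(values, groups, alpha = 0.05) {
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) < 2) stop("need at least two groups")
  if (any(table(groups) < 2)) stop("each group needs at least two observations")
  dat <- data.frame(values = values, groups = groups)
  fit <- aov(values ~ groups, data = dat)
  s <- summary(fit)[[1]]
  f <- s$`F value`[1]
  p <- s$`Pr(>F)`[1]
  if (var(values) == 0) {
    # identical observations everywhere: no between-group signal
    f <- 0
    p <- 1
  }
  tukey <- NULL
  if (!is.na(p) && p < alpha) {
    tk <- TukeyHSD(fit)$groups
    tukey <- tibble::tibble(comparison = rownames(tk), diff = tk[, "diff"],
                            lwr = tk[, "lwr"], upr = tk[, "upr"],
                            p_adj = tk[, "p adj"])
  }
  list(f = f, p = p, tukey = tukey)
}

#' Benjamini-Hochberg false-discovery-rate correction
#'
#' Step-up adjusted p-values (`p.adjust` method `"BH"`): monotone, never
#' below the raw p, never above 1, invariant to input order.
#'
#' @param p Raw p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order as the input.
#' @export
bh_correct <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  p.adjust(p, method = "BH")
}
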