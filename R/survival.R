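# Survival and association statistics used to characterize the subgroups.
# Estimators are delegated to the survival package and base R tests; the
# functions here fix the contracts (Breslow ties, Wald CIs, no continuity
# correction, half-away-from-zero percentages) used throughout.

#' Kaplan-Meier curve
#'
#' Product-limit estimator over distinct event times; censored-only times
#' reduce the risk set without an estimator step. The step function starts
#' at S(0) = 1.
#'
#' @param times Follow-up times (months, >= 0).
#' @param events Event indicators (1 = distant relapse, 0 = censored).
#' @return A data.frame with `time`, `n_risk`, `n_event`, `n_censor`,
#'   `survival`, beginning with the t = 0 row.
#' @export
km_curve <- function(times, events) {
  stopifnot(length(times) == length(events), all(times >= 0),
            all(events %in% c(0, 1)))
  sf <- survival::survfit(survival::Surv(times, events) ~ 1)
  data.frame(time = c(0, sf$time),
             n_risk = c(length(times), sf$n.risk),
             n_event = c(0, sf$n.event),
             n_censor = c(0, sf$n.censor),
             survival = c(1, sf$surv))
}

#' Log-rank (Mantel-Cox) test
#'
#' @param times,events Follow-up times and event indicators.
#' @param group Group labels (2 or more groups).
#' @return List with `chi2`, `df` (groups - 1) and `p`.
#' @export
logrank_test <- function(times, events, group) {
  group <- as.factor(group)
  if (nlevels(group) < 2L) stop("need at least 2 groups")
  sd <- survival::survdiff(survival::Surv(times, events) ~ group)
  df <- nlevels(group) - 1L
  list(chi2 = unname(sd$chisq), df = df,
       p = stats::pchisq(sd$chisq, df, lower.tail = FALSE))
}

#' Hazard ratio for a binary group from a Cox model
#'
#' Cox partial-likelihood fit with a single binary covariate, Breslow tie
#' handling by default (Efron via `ties`), Wald 95% CI
#' `exp(beta +/- 1.96 se)`. Groups with no events make the partial
#' likelihood monotone (the estimate diverges); this is reported as
#' `converged = FALSE` rather than a spuriously finite HR.
#'
#' @param times,events Follow-up times and event indicators.
#' @param group01 Binary covariate: 0 for the reference group, 1 otherwise
#'   (any two-level vector is accepted; the first sorted level is the
#'   reference).
#' @param ties `"breslow"` (default) or `"efron"`.
#' @return List with `hr`, `ci` (length-2), `p`, `beta`, `se`, `reference`,
#'   `n`, `events_per_group`, `converged`.
#' @export
cox_binary_hr <- function(times, events, group01, ties = c("breslow",
                                                           "efron")) {
  ties <- match.arg(ties)
  lv <- sort(unique(as.character(group01)))
  if (length(lv) != 2L) stop("group01 must have exactly 2 levels")
  x <- as.integer(as.character(group01) == lv[2L])
  ev_by <- tapply(events, x, sum)
  converged <- all(ev_by > 0) && length(ev_by) == 2L
  fit <- suppressWarnings(
    survival::coxph(survival::Surv(times, events) ~ x, ties = ties))
  beta <- unname(stats::coef(fit))
  se <- sqrt(unname(fit$var[1L, 1L]))
  if (!converged)
    warning("a group has no events: Cox estimate did not converge")
  list(hr = exp(beta), ci = exp(beta + c(-1.96, 1.96) * se),
       p = unname(summary(fit)$coefficients[1L, "Pr(>|z|)"]),
       beta = beta, se = se, reference = lv[1L],
       n = length(times), events_per_group = ev_by,
       converged = converged)
}

#' Compare survival between groups
#'
#' The bundle reported for every subgroup comparison: per-group KM step
#' functions, the log-rank test, and (for two groups) the Cox hazard ratio
#' with its Wald CI.
#'
#' @param times,events Follow-up times and event indicators.
#' @param group Group labels.
#' @return An object of class `survival_result`.
#' @export
compare_survival <- function(times, events, group) {
  group <- as.character(group)
  keep <- !is.na(times) & !is.na(events) & !is.na(group)
  times <- times[keep]; events <- events[keep]; group <- group[keep]
  lv <- sort(unique(group))
  km <- lapply(stats::setNames(lv, lv), function(g)
    km_curve(times[group == g], events[group == g]))
  lr <- logrank_test(times, events, group)
  hr <- if (length(lv) == 2L) cox_binary_hr(times, events, group) else NULL
  structure(list(km = km, logrank = lr, hr = hr,
                 n = table(group), n_used = sum(keep)),
            class = "survival_result")
}

#' @export
print.survival_result <- function(x, ...) {
  cat("survival_result:",
      paste(names(x$n), as.integer(x$n), sep = "=", collapse = ", "), "\n")
  cat(sprintf("  log-rank chi2 = %.3f (df = %d), p = %.4g\n",
              x$logrank$chi2, x$logrank$df, x$logrank$p))
  if (!is.null(x$hr))
    cat(sprintf("  HR = %.4f (95%% CI %.4f-%.4f), reference = %s\n",
                x$hr$hr, x$hr$ci[1L], x$hr$ci[2L], x$hr$reference))
  invisible(x)
}

#' Kruskal-Wallis test across groups
#'
#' Rank-based H statistic with tie correction, via [stats::kruskal.test()].
#'
#' @param values Numeric response.
#' @param group Group labels.
#' @return List with `H`, `df`, `p`.
#' @export
kruskal_wallis <- function(values, group) {
  kt <- stats::kruskal.test(values, as.factor(group))
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p = kt$p.value)
}

#' Dunn's post-hoc pairwise comparisons
#'
#' Pairwise z statistics on the joint-ranking mean ranks with the standard
#' tie correction, two-sided p-values, multiplicity-adjusted (Bonferroni by
#' default, any [stats::p.adjust()] method accepted).
#'
#' @param values Numeric response.
#' @param group Group labels.
#' @param method Multiplicity adjustment (default `"bonferroni"`).
#' @return A data.frame with `group_a`, `group_b`, `z`, `p`, `p_adjusted`.
#' @export
dunn_posthoc <- function(values, group, method = "bonferroni") {
  group <- as.factor(group)
  if (nlevels(group) < 2L) stop("need at least 2 groups")
  N <- length(values)
  rk <- rank(values)
  ties <- table(rk)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  mean_rank <- tapply(rk, group, mean)
  n <- tapply(rk, group, length)
  lv <- levels(group)
  pairs <- utils::combn(lv, 2L)
  z <- apply(pairs, 2L, function(pr) {
    i <- pr[1L]; j <- pr[2L]
    (mean_rank[i] - mean_rank[j]) /
      sqrt((N * (N + 1) / 12 - tie_term) * (1 / n[i] + 1 / n[j]))
  })
  p <- 2 * stats::pnorm(-abs(z))
  data.frame(group_a = pairs[1L, ], group_b = pairs[2L, ], z = unname(z),
             p = unname(p),
             p_adjusted = stats::p.adjust(p, method = method),
             stringsAsFactors = FALSE)
}

#' Two-sided Fisher exact test on a 2x2 table
#'
#' Exact hypergeometric p: the sum over tables with probability no larger
#' than the observed one, via [stats::fisher.test()].
#'
#' @param table A 2x2 integer matrix.
#' @return Two-sided p-value.
#' @export
fisher_2x2 <- function(table) {
  stopifnot(all(dim(table) == c(2L, 2L)))
  stats::fisher.test(table)$p.value
}

#' Pearson chi-squared test on a contingency table
#'
#' No continuity correction; df = (r - 1)(c - 1).
#'
#' @param table An r x c contingency matrix.
#' @return List with `chi2`, `df`, `p`.
#' @export
chi2_contingency <- function(table) {
  ct <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  list(chi2 = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value)
}
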