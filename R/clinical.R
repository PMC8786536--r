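#' Dichotomize marker scores or continuous values
#'
#' Two rules are supported. `"ihc"`: immunohistochemistry staining-intensity
#' scores 1-4, with 1-2 labelled `low` and 3-4 labelled `high`. `"quantile"`:
#' a continuous marker is split at the given quantile (default the median);
#' values at or below the cut are `low` (ties at the cut go to low).
#'
#' @param x integer IHC scores or a continuous marker.
#' @param rule `"ihc"` or `"quantile"`.
#' @param probs cut quantile for the quantile rule (default 0.5).
#' @return factor with levels `low`, `high`.
#' @export
dichotomize <- function(x, rule = c("ihc", "quantile"), probs = 0.5) {
  rule <- match.arg(rule)
  if (rule == "ihc") {
    if (!all(x %in% 1:4)) stop("IHC scores must be integers 1-4")
    lab <- ifelse(x <= 2, "low", "high")
  } else {
    cut <- stats::quantile(x, probs, na.rm = TRUE, names = FALSE)
    lab <- ifelse(x <= cut, "low", "high")
    if (all(lab == "low", na.rm = TRUE))
      warning("all values at or below the cut; single 'low' group")
  }
  factor(lab, levels = c("low", "high"))
}

#' Chi-squared test of association for a 2x2 table
#'
#' Pearson chi-squared statistic `sum((O - E)^2 / E)` with one degree of
#' freedom, optionally with the Yates continuity correction
#' `sum((|O - E| - 0.5)^2 / E)`.
#'
#' @param table 2x2 matrix of non-negative counts.
#' @param correction `"none"` (default) or `"yates"`.
#' @return list with `statistic`, `p_value`, `expected` counts.
#' @examples
#' chi_square_2x2(matrix(c(20, 12, 20, 28), 2))            # p = 0.068
#' chi_square_2x2(matrix(c(30, 2, 29, 19), 2), "yates")    # p = 0.002
#' @export
chi_square_2x2 <- function(table, correction = c("none", "yates")) {
  correction <- match.arg(correction)
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2)) || any(table < 0))
    stop("need a 2x2 table of non-negative counts")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("zero marginal row or column")
  res <- suppressWarnings(
    stats::chisq.test(table, correct = correction == "yates"))
  list(statistic = unname(res$statistic), p_value = res$p.value,
       expected = res$expected)
}

#' Kaplan-Meier survival curve
#'
#' Product-limit estimator of the survival function. The curve starts at 1,
#' is non-increasing, and drops only at event times; fully censored data give
#' a flat curve at 1.
#'
#' @param times non-negative follow-up times.
#' @param events event indicators (1 = event, 0 = censored).
#' @return data.frame with `time`, `n_risk`, `n_event`, `survival`.
#' @export
kaplan_meier <- function(times, events) {
  stopifnot(length(times) >= 1, all(times >= 0), all(events %in% c(0, 1)))
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  data.frame(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
             survival = fit$surv)
}

#' Two-group log-rank test
#'
#' Standard log-rank chi-squared comparison of survival between groups
#' (df = number of groups - 1).
#'
#' @param times,events as in [kaplan_meier()].
#' @param group group labels; at least two non-empty groups.
#' @return list with `statistic`, `df`, `p_value`.
#' @export
logrank_test <- function(times, events, group) {
  group <- as.factor(droplevels(as.factor(group)))
  if (nlevels(group) < 2)
    stop("log-rank test needs at least two non-empty groups")
  fit <- survival::survdiff(survival::Surv(times, events) ~ group)
  df <- length(fit$n) - 1
  list(statistic = unname(fit$chisq), df = df,
       p_value = stats::pchisq(fit$chisq, df, lower.tail = FALSE))
}

#' Univariate and multivariate Cox proportional-hazards regression
#'
#' Univariate models fit each covariate alone against `Surv(follow_up,
#' event)`; the multivariate model jointly includes the covariates whose
#' univariate Wald p-value is below `select_p` (mirroring the usual
#' carry-forward from univariate screening). Ties are handled with the Efron
#' approximation. Hazard ratios, 95% Wald confidence intervals and p-values
#' are reported per covariate.
#'
#' @param data data.frame with columns `follow_up`, `event` and the
#'   covariates.
#' @param covariates character vector of covariate column names.
#' @param type `"univariate"`, `"multivariate"` or `"both"` (default).
#' @param select_p univariate p threshold for inclusion in the multivariate
#'   model (default 0.05).
#' @return data.frame with `model`, `term`, `hr`, `ci_lower`, `ci_upper`,
#'   `p_value`.
#' @export
cox_fit <- function(data, covariates,
                    type = c("both", "univariate", "multivariate"),
                    select_p = 0.05) {
  type <- match.arg(type)
  stopifnot(all(c("follow_up", "event") %in% names(data)),
            all(covariates %in% names(data)))
  if (sum(data$event) < 1) stop("no events in the data")
  tidy_cox <- function(fit, model) {
    s <- summary(fit)
    co <- s$coefficients
    ci <- s$conf.int
    data.frame(model = model, term = rownames(co),
               hr = unname(co[, "exp(coef)"]),
               ci_lower = unname(ci[, 3]), ci_upper = unname(ci[, 4]),
               p_value = unname(co[, "Pr(>|z|)"]),
               stringsAsFactors = FALSE)
  }
  uni <- do.call(rbind, lapply(covariates, function(v) {
    f <- stats::as.formula(paste("survival::Surv(follow_up, event) ~", v))
    tidy_cox(survival::coxph(f, data = data, ties = "efron"), "univariate")
  }))
  uni$covariate <- rep(covariates, vapply(covariates, function(v)
    sum(startsWith(uni$term, v)), integer(1)))
  if (type == "univariate") {
    rownames(uni) <- NULL
    return(uni)
  }
  min_p <- vapply(covariates, function(v)
    min(uni$p_value[uni$covariate == v]), numeric(1))
  chosen <- covariates[min_p < select_p]
  multi <- NULL
  if (length(chosen) >= 1) {
    f <- stats::as.formula(paste("survival::Surv(follow_up, event) ~",
                                 paste(chosen, collapse = " + ")))
    fit <- survival::coxph(f, data = data, ties = "efron")
    if (!fit$iter || any(!is.finite(stats::coef(fit))))
      warning("multivariate Cox fit did not converge cleanly")
    multi <- tidy_cox(fit, "multivariate")
    multi$covariate <- multi$term
    for (v in chosen) multi$covariate[startsWith(multi$term, v)] <- v
  }
  out <- if (type == "multivariate") multi else rbind(uni, multi)
  rownames(out) <- NULL
  out
}

#' Area under the ROC curve
#'
#' AUC via the rank (Mann-Whitney) identity: the probability that a random
#' positive scores higher than a random negative, with ties counted 1/2.
#'
#' @param scores numeric marker values.
#' @param labels binary class labels (1 = positive, 0 = negative), both
#'   classes present.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
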