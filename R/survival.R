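# Survival validation of module genes: product-limit curves, log-rank
# tests, Cox proportional-hazards fits (Efron ties), and expression
# dichotomization. The survival package provides the estimators; the
# functions here define the pipeline's record contract and checks.

.checkRecords <- function(records) {
  .stopIf(!all(c("time", "event") %in% names(records)),
          "records need 'time' and 'event' columns")
  .stopIf(any(records$time <= 0) || any(!is.finite(records$time)),
          "times must be finite and positive")
  .stopIf(!all(records$event %in% c(0, 1)), "event flags must be 0/1")
  records
}

#' Kaplan-Meier product-limit estimate
#'
#' \eqn{\hat S(t) = \prod_{t_i \le t} (1 - d_i/n_i)}; times with only
#' censoring shrink the risk set without a step. With no censoring the curve
#' equals the empirical survival function.
#'
#' @param records data.frame with `time` (> 0) and `event` (0/1)
#' @return data.frame: `time`, `n_risk`, `n_event`, `survival`
#' @export
kmEstimator <- function(records) {
  .stopIf(nrow(records) < 1, "need at least one record")
  .checkRecords(records)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = records)
  data.frame(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
             survival = fit$surv)
}

#' Two-group log-rank test
#'
#' \eqn{U = \sum_j (O_{1j} - E_{1j})} over event times with the
#' hypergeometric variance; the statistic \eqn{U^2/V} is chi-square with one
#' degree of freedom.
#'
#' @param records data.frame with `time`, `event`
#' @param group two-level factor/character of the same length
#' @return list: `chisq`, `df`, `p`, `observed`, `expected` (per group)
#' @export
logrankTest <- function(records, group) {
  .checkRecords(records)
  group <- factor(group)
  .stopIf(nlevels(group) != 2, "log-rank test requires exactly 2 groups")
  .stopIf(any(table(group) == 0), "both groups must be non-empty")
  .stopIf(sum(records$event) == 0, "no events observed")
  sd <- survival::survdiff(
    survival::Surv(records$time, records$event) ~ group)
  chisq <- sd$chisq
  p <- stats::pchisq(chisq, df = 1, lower.tail = FALSE)
  list(chisq = chisq, df = 1L, p = p,
       observed = stats::setNames(sd$obs, levels(group)),
       expected = stats::setNames(sd$exp, levels(group)))
}

#' Cox proportional-hazards fit
#'
#' Partial-likelihood Newton-Raphson with Efron tie handling; optional
#' stratification gives each stratum its own risk sets. The Wald 95%
#' confidence interval is `beta +/- 1.96 SE`.
#'
#' @param records data.frame with `time`, `event`
#' @param covariate numeric (or 0/1) vector; must vary
#' @param strata optional stratification factor (e.g. tumor stage)
#' @param ties tie-handling method (default `"efron"`)
#' @return list: `beta`, `hr`, `ci` (length 2), `se`, `p`, `ties`
#' @export
coxFit <- function(records, covariate, strata = NULL, ties = "efron") {
  .checkRecords(records)
  .stopIf(length(unique(covariate)) < 2, "no variation in the covariate")
  .stopIf(sum(records$event) == 0, "no events observed")
  df <- data.frame(time = records$time, event = records$event,
                   x = covariate)
  fm <- if (is.null(strata)) survival::Surv(time, event) ~ x
        else { df$s <- strata; survival::Surv(time, event) ~ x + survival::strata(s) }
  fit <- survival::coxph(fm, data = df, ties = ties,
                         control = survival::coxph.control(iter.max = 100))
  .stopIf(!is.null(fit$info) && grepl("did not converge", paste(fit$info)),
          "Cox fit did not converge")
  beta <- unname(fit$coefficients["x"])
  se <- sqrt(fit$var[1, 1])
  list(beta = beta, hr = exp(beta),
       ci = exp(beta + c(-1.96, 1.96) * se), se = se,
       p = 2 * stats::pnorm(-abs(beta / se)), ties = ties)
}

#' Dichotomize expression for survival contrast
#'
#' `method = "scan"` (default): candidate cutoffs are the observed
#' expression values inside the interquartile range; the cutoff minimizing
#' the log-rank p-value is chosen. That minimum p is optimistic (selected
#' over multiple cutoffs) and is flagged as such. `method = "roc"`:
#' dichotomizes at the cutoff maximizing Youden's J for classifying
#' event-by-horizon status, with the horizon at the median follow-up time
#' (subjects censored before the horizon are excluded from the ROC).
#'
#' @param records data.frame with `time`, `event`
#' @param expression numeric vector, one value per record; must vary
#' @param method `"scan"` or `"roc"`
#' @return list: `labels` (factor `low`/`high`), `cutoff`, `method`,
#'   `logrank_p`, `optimistic` (TRUE for scan)
#' @export
dichotomizeExpression <- function(records, expression,
                                  method = c("scan", "roc")) {
  method <- match.arg(method)
  .checkRecords(records)
  .stopIf(length(unique(expression)) < 2, "expression does not vary")
  labelsOf <- function(cut) factor(ifelse(expression <= cut, "low", "high"),
                                   levels = c("low", "high"))
  if (method == "scan") {
    qs <- stats::quantile(expression, c(0.25, 0.75), type = 7)
    cand <- sort(unique(expression[expression >= qs[1] & expression <= qs[2]]))
    if (!length(cand)) cand <- stats::median(expression)
    best <- NULL
    for (cut in cand) {
      lab <- labelsOf(cut)
      if (length(unique(lab)) < 2) next
      p <- logrankTest(records, lab)$p
      if (is.null(best) || p < best$p) best <- list(cutoff = cut, p = p)
    }
    .stopIf(is.null(best), "no cutoff splits the samples into two groups")
    return(list(labels = labelsOf(best$cutoff), cutoff = best$cutoff,
                method = "scan", logrank_p = best$p, optimistic = TRUE))
  }
  horizon <- stats::median(records$time)
  case <- records$event == 1 & records$time <= horizon
  ctrl <- records$time > horizon
  use <- case | ctrl
  .stopIf(sum(case) == 0 || sum(ctrl) == 0,
          "no events (or no survivors) by the horizon")
  cand <- sort(unique(expression))
  youden <- vapply(cand, function(cut) {
    lowrisk <- expression > cut
    sens <- mean(!lowrisk[use][case[use]])
    spec <- mean(lowrisk[use][ctrl[use]])
    sens2 <- mean(lowrisk[use][case[use]])
    spec2 <- mean(!lowrisk[use][ctrl[use]])
    max(sens + spec, sens2 + spec2) - 1   # direction-free Youden J
  }, numeric(1))
  cut <- cand[which.max(youden)]
  lab <- labelsOf(cut)
  if (length(unique(lab)) < 2) {
    cut <- stats::median(expression)
    lab <- labelsOf(cut)
  }
  p <- if (length(unique(lab)) == 2) logrankTest(records, lab)$p else NA_real_
  list(labels = lab, cutoff = cut, method = "roc", logrank_p = p,
       optimistic = FALSE)
}

#' Per-gene survival validation summary
#'
#' For each gene, dichotomizes its expression, runs the log-rank test on the
#' resulting low/high groups, and fits a Cox model on the continuous
#' expression.
#'
#' @param records survival data.frame with `sample_id`, `time`, `event`
#' @param expression gene x sample matrix (columns matched by `sample_id`)
#' @param genes genes to validate (default: all rows)
#' @param method dichotomization method, see [dichotomizeExpression()]
#' @return data.frame: `gene`, `cutoff`, `hr`, `ci_lo`, `ci_hi`, `cox_p`,
#'   `logrank_p`, `optimistic`
#' @export
survivalValidation <- function(records, expression, genes = NULL,
                               method = "scan") {
  .stopIf(!"sample_id" %in% names(records), "records need sample_id")
  idx <- match(records$sample_id, colnames(expression))
  .stopIf(anyNA(idx), "records contain samples missing from the expression")
  if (is.null(genes)) genes <- rownames(expression)
  rows <- lapply(genes, function(g) {
    x <- expression[g, idx]
    di <- dichotomizeExpression(records, x, method = method)
    cx <- coxFit(records, x)
    data.frame(gene = g, cutoff = di$cutoff, hr = cx$hr,
               ci_lo = cx$ci[1], ci_hi = cx$ci[2], cox_p = cx$p,
               logrank_p = di$logrank_p, optimistic = di$optimistic,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
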