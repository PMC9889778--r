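# Survival stratification: two-group log-rank test, maximally selected
# cutpoint sweep for dichotomising a continuous abundance score, and Cox
# proportional-hazards estimation with covariates.

#' Two-group log-rank test
#'
#' At each distinct event time the observed number of events in group 1 is
#' compared with its hypergeometric expectation; U = sum(O - E),
#' Var = sum of hypergeometric variances, chi2 = U^2 / Var, p from a
#' chi-square with 1 df. The signed standardized statistic U / sqrt(Var) is
#' also returned (positive when group 1 has more events than expected,
#' i.e. worse survival).
#'
#' @param records data.frame with \code{time_months} and \code{event}.
#' @param group logical or 0/1 vector; TRUE/1 marks group 1.
#' @return List with \code{chi2}, \code{p}, \code{statistic} (signed
#'   U/sqrt(Var)), \code{U}, \code{var}.
#' @export
logrank_test <- function(records, group) {
  time <- records$time_months; event <- records$event
  group <- as.logical(group)
  if (length(group) != length(time)) stopf("group length mismatch")
  if (!any(group) || all(group)) stopf("both groups must be non-empty")
  if (sum(event) < 1) stopf("no events observed")
  ord <- order(time)
  time <- time[ord]; event <- event[ord]; group <- group[ord]
  ev_times <- unique(time[event == 1])
  n <- length(time)
  U <- 0; V <- 0
  # counts at risk just before each event time
  for (t in ev_times) {
    at_risk <- time >= t
    n_tot <- sum(at_risk)
    n1 <- sum(at_risk & group)
    d <- sum(event == 1 & time == t)
    d1 <- sum(event == 1 & time == t & group)
    e1 <- d * n1 / n_tot
    U <- U + d1 - e1
    if (n_tot > 1) {
      V <- V + d * (n1 / n_tot) * (1 - n1 / n_tot) * (n_tot - d) / (n_tot - 1)
    }
  }
  if (V <= 0) {
    return(list(chi2 = 0, p = 1, statistic = 0, U = U, var = V))
  }
  chi2 <- U^2 / V
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
       statistic = U / sqrt(V), U = U, var = V)
}

#' Maximally selected log-rank cutpoint sweep
#'
#' Every distinct score value whose induced split (score > cutpoint = high)
#' keeps both groups at least \code{min_prop} of subjects is a candidate;
#' the signed standardized log-rank statistic is computed at each, and the
#' optimal cutpoint maximizes its absolute value. The uncorrected sweep is
#' returned in full for plotting; significance of the selected cutpoint
#' should be assessed on independent validation cohorts.
#'
#' @param records data.frame with \code{time_months}, \code{event}.
#' @param score per-subject continuous score (e.g. subpopulation
#'   percentage); must be non-constant.
#' @param min_prop minimum group share on each side (default 0.1).
#' @return An object of class \code{cutpoint_result}: \code{table}
#'   (cutpoint, statistic, n_high), \code{optimal_cutpoint},
#'   \code{optimal_statistic}, \code{min_prop}.
#' @export
cutpoint_sweep <- function(records, score, min_prop = 0.1) {
  n <- nrow(records)
  if (n < 20) stopf("need at least 20 subjects (got %d)", n)
  if (length(score) != n) stopf("score length mismatch")
  if (stats::var(score) == 0) stopf("score is constant")
  cand <- sort(unique(score))
  keep <- vapply(cand, function(cp) {
    nh <- sum(score > cp)
    nh >= min_prop * n && (n - nh) >= min_prop * n
  }, logical(1))
  cand <- cand[keep]
  if (!length(cand)) stopf("no candidate cutpoint satisfies min_prop = %.2f", min_prop)
  stat <- vapply(cand, function(cp) {
    logrank_test(records, score > cp)$statistic
  }, numeric(1))
  best <- which.max(abs(stat))
  structure(list(table = data.frame(cutpoint = cand, statistic = stat,
                                    n_high = vapply(cand, function(cp)
                                      sum(score > cp), numeric(1))),
                 optimal_cutpoint = cand[best],
                 optimal_statistic = stat[best],
                 min_prop = min_prop),
            class = "cutpoint_result")
}

#' @export
print.cutpoint_result <- function(x, ...) {
  cat(sprintf("<cutpoint_result> %d candidates; optimal cutpoint %.4g (|z| = %.3f)\n",
              nrow(x$table), x$optimal_cutpoint, abs(x$optimal_statistic)))
  invisible(x)
}

#' Plot a cutpoint sweep
#'
#' Standardized log-rank statistic against candidate cutpoint, with the
#' optimum marked.
#'
#' @param x a \code{cutpoint_result}.
#' @param ... passed to \code{plot}.
#' @export
plot.cutpoint_result <- function(x, ...) {
  graphics::plot(x$table$cutpoint, x$table$statistic, type = "l",
                 xlab = "cutpoint", ylab = "standardized log-rank statistic",
                 ...)
  graphics::abline(v = x$optimal_cutpoint, lty = 2)
  invisible(x)
}

#' Cox proportional-hazards regression with covariates
#'
#' Wraps the partial-likelihood fit of \code{survival::coxph} with the
#' chosen ties correction, optional administrative censoring at a horizon
#' (e.g. 48 months for four-year survival), and Wald confidence intervals.
#'
#' @param records data.frame with \code{time_months}, \code{event} and the
#'   covariate columns.
#' @param covariates character vector of covariate column names (entered
#'   linearly; stage as ordinal by default).
#' @param ties \code{"efron"} (default) or \code{"breslow"}.
#' @param horizon_months optional administrative censoring horizon.
#' @return An object of class \code{cox_result}: \code{table} (covariate,
#'   coef, hr, lower95, upper95, p), \code{ties}, \code{horizon_months},
#'   \code{n}, \code{n_events}, and the underlying \code{fit}.
#' @export
cox_ph <- function(records, covariates, ties = c("efron", "breslow"),
                   horizon_months = NULL) {
  ties <- match.arg(ties)
  missing_cov <- setdiff(covariates, colnames(records))
  if (length(missing_cov)) stopf("covariate '%s' not found", missing_cov[1])
  df <- records
  if (!is.null(horizon_months)) {
    over <- df$time_months > horizon_months
    df$event[over] <- 0
    df$time_months[over] <- horizon_months
  }
  for (cv in covariates) {
    if (stats::var(as.numeric(df[[cv]])) == 0) stopf("covariate '%s' is constant", cv)
  }
  n_events <- sum(df$event)
  if (n_events < 5 * length(covariates)) {
    warnf("only %d events for %d covariates; estimates may be unstable",
          n_events, length(covariates))
  }
  fml <- stats::as.formula(paste("survival::Surv(time_months, event) ~",
                                 paste(covariates, collapse = " + ")))
  fit <- tryCatch(
    survival::coxph(fml, data = df, ties = ties,
                    control = survival::coxph.control(iter.max = 100)),
    warning = function(w) {
      if (grepl("infinite|did not converge|beta may be infinite", conditionMessage(w))) {
        stopf("partial likelihood is monotone (perfect separation or non-convergence): %s",
              conditionMessage(w))
      }
      suppressWarnings(survival::coxph(fml, data = df, ties = ties,
                                       control = survival::coxph.control(iter.max = 100)))
    })
  sm <- summary(fit)
  coefs <- sm$coefficients
  tab <- data.frame(covariate = rownames(coefs),
                    coef = coefs[, "coef"],
                    hr = exp(coefs[, "coef"]),
                    lower95 = exp(coefs[, "coef"] - 1.96 * coefs[, "se(coef)"]),
                    upper95 = exp(coefs[, "coef"] + 1.96 * coefs[, "se(coef)"]),
                    p = coefs[, "Pr(>|z|)"],
                    stringsAsFactors = FALSE, row.names = NULL)
  structure(list(table = tab, ties = ties, horizon_months = horizon_months,
                 n = nrow(df), n_events = n_events, fit = fit),
            class = "cox_result")
}

#' @export
print.cox_result <- function(x, ...) {
  cat(sprintf("<cox_result> n = %d, events = %d, ties = %s%s\n",
              x$n, x$n_events, x$ties,
              if (!is.null(x$horizon_months))
                sprintf(", horizon = %g months", x$horizon_months) else ""))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Read a survival table from CSV
#'
#' @param path CSV with header time_months,event,score,age,stage.
#' @return data.frame of survival records.
#' @export
read_survival_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("time_months", "event")
  miss <- setdiff(needed, colnames(df))
  if (length(miss)) stopf("survival CSV lacks column '%s'", miss[1])
  df
}
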