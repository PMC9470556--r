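#' Kaplan-Meier product-limit estimate
#'
#' Right-censored product-limit survival curve for one group. Steps occur
#' at observed event times; censoring only reduces the risk set.
#'
#' @param time event/censoring times (days), strictly positive.
#' @param event 1/TRUE for an observed death, 0/FALSE for censoring.
#' @return data.frame with one row per distinct time: `time`, `n_risk`,
#'   `n_event`, `n_censor`, `surv` (the estimate just after `time`).
#' @examples
#' kmEstimate(c(1, 2, 3, 4), c(1, 1, 0, 0))
#' @export
kmEstimate <- function(time, event) {
  if (!length(time)) stop("no survival records")
  stopifnot(length(time) == length(event), all(time > 0))
  event <- as.integer(as.logical(event))
  ts <- sort(unique(time))
  n <- length(time)
  surv <- 1
  rows <- lapply(ts, function(t) {
    nRisk <- sum(time >= t)
    d <- sum(time == t & event == 1L)
    cns <- sum(time == t & event == 0L)
    if (d > 0) surv <<- surv * (1 - d / nRisk)
    data.frame(time = t, n_risk = nRisk, n_event = d, n_censor = cns,
               surv = surv)
  })
  do.call(rbind, rows)
}

#' Log-rank test and observed/expected hazard ratio
#'
#' Compares control and tumor survival with the standard log-rank
#' procedure: at every distinct event time the expected number of events
#' per group is allocated in proportion to the group's share of the risk
#' set (tied events contribute in aggregate). The hazard ratio is the
#' observed-over-expected ratio
#' `HR = (O_C / E_C) / (O_T / E_T)`,
#' with a 95% confidence interval from the usual log-scale standard error
#' `sqrt(1/E_C + 1/E_T)`, and the two-sided log-rank p-value comes from
#' the chi-squared statistic `(O_C - E_C)^2 / V` with one degree of
#' freedom. `HR = 1` means no survival difference; animals alive at study
#' end should enter as censored.
#'
#' A group with zero observed events yields a degenerate hazard ratio
#' (0 or Inf) with an infinite confidence bound and a warning rather than
#' an error.
#'
#' @param control,tumor data.frames with columns `time` and `event`
#'   (1 = death observed, 0 = censored).
#' @return a [SurvivalResult-class].
#' @export
logrankAndHr <- function(control, tumor) {
  for (df in list(control, tumor)) {
    stopifnot(all(c("time", "event") %in% names(df)), nrow(df) >= 1L)
  }
  tAll <- c(control$time, tumor$time)
  eAll <- c(as.integer(as.logical(control$event)),
            as.integer(as.logical(tumor$event)))
  grp <- rep(c("control", "tumor"), c(nrow(control), nrow(tumor)))
  if (sum(eAll) == 0L) stop("no events in either group")

  evTimes <- sort(unique(tAll[eAll == 1L]))
  oC <- 0; oT <- 0; eC <- 0; eT <- 0; v <- 0
  for (t in evTimes) {
    atRisk <- tAll >= t
    nC <- sum(atRisk & grp == "control")
    nT <- sum(atRisk & grp == "tumor")
    n <- nC + nT
    dC <- sum(tAll == t & eAll == 1L & grp == "control")
    dT <- sum(tAll == t & eAll == 1L & grp == "tumor")
    d <- dC + dT
    oC <- oC + dC; oT <- oT + dT
    eC <- eC + d * nC / n
    eT <- eT + d * nT / n
    if (n > 1) v <- v + d * (nC / n) * (nT / n) * (n - d) / (n - 1)
  }

  hr <- (oC / eC) / (oT / eT)
  if (oC == 0L || oT == 0L) {
    warning("zero observed events in one group: hazard ratio degenerate")
    ci <- if (oT == 0L) c(NA_real_, Inf) else c(0, NA_real_)
  } else {
    se <- sqrt(1 / eC + 1 / eT)
    z <- stats::qnorm(0.975)
    ci <- hr * exp(c(-1, 1) * z * se)
  }
  chisq <- if (v > 0) (oC - eC)^2 / v else 0
  p <- stats::pchisq(chisq, df = 1, lower.tail = FALSE)

  new("SurvivalResult",
      kmControl = kmEstimate(control$time, control$event),
      kmTumor = kmEstimate(tumor$time, tumor$event),
      observed = c(control = oC, tumor = oT),
      expected = c(control = eC, tumor = eT),
      hr = hr, hrCi = ci, chisq = chisq, p = p)
}

setMethod("show", "SurvivalResult", function(object) {
  cat("Two-group survival analysis\n")
  cat(sprintf("  observed events: control %g, tumor %g\n",
              object@observed[["control"]], object@observed[["tumor"]]))
  cat(sprintf("  expected events: control %.2f, tumor %.2f\n",
              object@expected[["control"]], object@expected[["tumor"]]))
  cat(sprintf("  HR = %.3f (95%% CI %.3f-%.3f)\n", object@hr,
              object@hrCi[1], object@hrCi[2]))
  cat(sprintf("  log-rank chi-squared = %.3f, p = %.3g\n",
              object@chisq, object@p))
})

#' Survival result as a plain list
#'
#' Flattens a [SurvivalResult-class] for JSON serialization.
#'
#' @param x a [SurvivalResult-class].
#' @return named list of scalars and curve data.frames.
#' @export
survivalResultAsList <- function(x) {
  stopifnot(is(x, "SurvivalResult"))
  list(
    observed = as.list(x@observed), expected = as.list(x@expected),
    hazard_ratio = x@hr, hr_ci_95 = x@hrCi,
    logrank_chisq = x@chisq, logrank_p = x@p,
    km_control = x@kmControl, km_tumor = x@kmTumor
  )
}
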