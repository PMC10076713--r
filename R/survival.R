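# Survival evaluation of biomarker groups: Kaplan-Meier estimates,
# log-rank tests, two-group Cox hazard ratios and combination ranking.
# Estimators are backed by the survival package; the test suite checks
# them against independent hand-computed and brute-force oracles.

#' Kaplan-Meier estimate
#'
#' Product-limit estimator of the survival function for one group.
#' Subjects censored at an event time are counted at risk at that time
#' (the standard convention).
#'
#' @param time positive event/censoring times.
#' @param event logical or 0/1 event indicators (TRUE = event observed).
#' @return a data frame of class `icb_km` with columns `time`, `n_risk`,
#'   `n_event`, `n_censor`, `surv` (one row per distinct observed time).
#' @export
km_estimate <- function(time, event) {
  stopifnot(length(time) == length(event), length(time) >= 1L)
  if (any(time <= 0)) {
    stop_icb("survival times must be positive", "icbcombo_validation_error")
  }
  fit <- survival::survfit(survival::Surv(time, as.integer(event)) ~ 1,
                           conf.type = "none")
  out <- data.frame(time = fit$time, n_risk = fit$n.risk,
                    n_event = fit$n.event, n_censor = fit$n.censor,
                    surv = fit$surv)
  class(out) <- c("icb_km", "data.frame")
  out
}

#' Evaluate a Kaplan-Meier step function
#'
#' @param km an [km_estimate()] result.
#' @param t times at which to evaluate S(t).
#' @return survival probabilities; S(t) = 1 for t before the first
#'   observed time.
#' @export
km_surv_at <- function(km, t) {
  vapply(t, function(tt) {
    idx <- which(km$time <= tt)
    if (length(idx) == 0L) 1 else km$surv[max(idx)]
  }, numeric(1))
}

#' Two-group log-rank test
#'
#' Standard (unweighted) log-rank test comparing the survival of the high
#' and low groups; 1-df chi-square p-value. With zero events overall the
#' test is degenerate: chi-square 0, p = 1, with a warning.
#'
#' @param time positive times for all patients.
#' @param event event indicators.
#' @param group character/factor with exactly two levels (e.g. high/low).
#' @return list with `chi_square`, `p_value`, `n` (per-group sizes),
#'   `observed` and `expected` event counts per group.
#' @export
logrank_test <- function(time, event, group) {
  group <- as.factor(as.character(group))
  if (nlevels(group) != 2L) {
    stop_icb("log-rank test requires exactly two non-empty groups",
             "icbcombo_validation_error")
  }
  event <- as.integer(event)
  if (sum(event) == 0L) {
    warning("no events in either group; log-rank test is degenerate")
    n <- table(group)
    return(list(chi_square = 0, p_value = 1,
                n = as.vector(n), observed = c(0, 0),
                expected = c(0, 0)))
  }
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  list(chi_square = unname(sd$chisq),
       p_value = unname(pchisq(sd$chisq, df = 1L, lower.tail = FALSE)),
       n = as.vector(sd$n), observed = as.vector(sd$obs),
       expected = as.vector(sd$exp))
}

#' Two-group Cox proportional-hazards ratio
#'
#' Fits a Cox model with a single binary covariate (`high` = 1, `low` = 0)
#' by partial likelihood with Efron tie handling (Breslow available).
#' Returns the hazard ratio `exp(beta)` with a Wald 95% CI
#' `exp(beta +/- 1.96 se)`. HR < 1 means the high group has the lower
#' hazard. A monotone likelihood (e.g. zero events in one group, or
#' complete separation of event times) cannot be estimated and is
#' reported as a flagged result with an infinite-bound CI, never as a
#' spurious finite number.
#'
#' @param time positive times.
#' @param event event indicators.
#' @param group character/factor with levels including "high" and "low"
#'   (low is the reference).
#' @param ties `"efron"` (default) or `"breslow"`.
#' @return a list of class `icb_cox` with `hr`, `ci95` (length-2), `beta`,
#'   `log_hr_se`, `n_high`, `n_low`, `events`, `converged` (FALSE when the
#'   estimate is flagged) and `note`.
#' @export
cox_hr <- function(time, event, group, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  group <- as.character(group)
  keep <- !is.na(group) & !is.na(time) & !is.na(event)
  time <- time[keep]; event <- as.integer(event[keep]); group <- group[keep]
  if (!all(group %in% c("high", "low"))) {
    stop_icb("group labels must be 'high' or 'low'",
             "icbcombo_validation_error")
  }
  n_high <- sum(group == "high"); n_low <- sum(group == "low")
  res <- list(hr = NA_real_, ci95 = c(NA_real_, NA_real_),
              beta = NA_real_, log_hr_se = NA_real_,
              n_high = n_high, n_low = n_low, events = sum(event),
              converged = FALSE, note = "")
  class(res) <- "icb_cox"
  if (n_high == 0L || n_low == 0L) {
    res$note <- "one group is empty; HR not estimable"
    return(res)
  }
  if (sum(event) == 0L) {
    res$note <- "no events; HR not estimable"
    return(res)
  }
  ev_high <- sum(event[group == "high"])
  ev_low <- sum(event[group == "low"])
  if (ev_high == 0L || ev_low == 0L) {
    # monotone partial likelihood: beta diverges
    res$note <- sprintf("zero events in the %s group; monotone likelihood",
                        if (ev_high == 0L) "high" else "low")
    res$hr <- if (ev_high == 0L) 0 else Inf
    res$ci95 <- if (ev_high == 0L) c(0, Inf) else c(0, Inf)
    return(res)
  }
  x <- as.integer(group == "high")
  fit <- tryCatch(
    suppressWarnings(survival::coxph(
      survival::Surv(time, event) ~ x, ties = ties,
      control = survival::coxph.control(iter.max = 50))),
    error = function(e) NULL
  )
  if (is.null(fit) || is.na(fit$coefficients[1])) {
    res$note <- "Cox fit failed"
    return(res)
  }
  beta <- unname(fit$coefficients[1])
  se <- unname(sqrt(fit$var[1, 1]))
  if (!is.finite(beta) || !is.finite(se) || se > 1e3) {
    res$note <- "estimate did not converge (likely separation)"
    res$beta <- beta
    return(res)
  }
  res$beta <- beta
  res$log_hr_se <- se
  res$hr <- exp(beta)
  res$ci95 <- exp(beta + c(-1, 1) * 1.96 * se)
  res$converged <- TRUE
  res
}

#' @export
print.icb_cox <- function(x, ...) {
  if (x$converged) {
    cat(sprintf("HR %.3g (95%% CI %.3g-%.3g), %d high / %d low, %d events\n",
                x$hr, x$ci95[1], x$ci95[2], x$n_high, x$n_low, x$events))
  } else {
    cat(sprintf("HR not estimated (%s); %d high / %d low, %d events\n",
                x$note, x$n_high, x$n_low, x$events))
  }
  invisible(x)
}

#' Rank biomarker combinations by hazard ratio
#'
#' Evaluates every combination spec against each requested survival
#' endpoint: group assignment by [assign_groups()], log-rank test and
#' two-group Cox HR with 95% CI. One row per (spec, endpoint); within an
#' endpoint rows are sorted by HR ascending (unestimable HRs last but
#' retained with their flag).
#'
#' @param panel biomarker panel data frame (`patient_id`, `neoload`,
#'   `pdl2`, `cyt`, `tdiv`).
#' @param specs list of [combination_spec()]; default
#'   [enumerate_combinations()].
#' @param survival_df data frame with `patient_id` and, per requested
#'   endpoint, `<endpoint>_time` and `<endpoint>_event` columns.
#' @param endpoints character subset of `c("pfs", "os")`.
#' @param ties tie handling for the Cox fits.
#' @return data frame with columns `spec`, `mode`, `endpoint`, `n_high`,
#'   `n_low`, `events`, `hr`, `ci_low`, `ci_high`, `logrank_chisq`,
#'   `logrank_p`, `estimable`, `note`.
#' @export
rank_combinations <- function(panel, specs = enumerate_combinations(),
                              survival_df, endpoints = c("pfs", "os"),
                              ties = "efron") {
  endpoints <- match.arg(endpoints, c("pfs", "os"), several.ok = TRUE)
  assert_columns(survival_df, c("patient_id",
                                paste0(rep(endpoints, each = 2),
                                       c("_time", "_event"))),
                 "survival table")
  survival_df <- survival_df[order(survival_df$patient_id), , drop = FALSE]
  rows <- list()
  for (spec in specs) {
    ga <- assign_groups(panel, spec)
    grp <- ga$labels[survival_df$patient_id]
    for (ep in endpoints) {
      tm <- survival_df[[paste0(ep, "_time")]]
      ev <- survival_df[[paste0(ep, "_event")]]
      ok <- !is.na(grp) & !is.na(tm) & !is.na(ev)
      cx <- cox_hr(tm[ok], ev[ok], grp[ok], ties = ties)
      lr <- if (length(unique(grp[ok])) == 2L && sum(ev[ok]) > 0) {
        logrank_test(tm[ok], ev[ok], grp[ok])
      } else {
        list(chi_square = NA_real_, p_value = NA_real_)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        spec = spec$label, mode = spec$mode, endpoint = ep,
        n_high = cx$n_high, n_low = cx$n_low, events = cx$events,
        hr = cx$hr, ci_low = cx$ci95[1], ci_high = cx$ci95[2],
        logrank_chisq = lr$chi_square, logrank_p = lr$p_value,
        estimable = cx$converged, note = cx$note,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  # sort within endpoint by HR ascending, unestimable last
  out <- out[order(match(out$endpoint, endpoints),
                   is.na(out$hr) | !is.finite(out$hr), out$hr), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}
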