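#' Fit a Cox proportional-hazards benchmark model
#'
#' Partial-likelihood fit (delegated to [survival::coxph()]) with adjusted
#' hazard ratios, 95% confidence intervals and Wald p-values per covariate,
#' Harrell's concordance from the linear predictor, and a scaled
#' Schoenfeld-residual test of the proportional-hazards assumption.
#'
#' @param covariates Data.frame of predictors (one column per covariate).
#' @param time Numeric event/censoring times.
#' @param event 0/1 event indicators (at least one event).
#' @return An object of class `pira_cox`: the underlying fit, a coefficient
#'   `table` (hr, lo, hi, p), `concordance`, `ph_test` (per-covariate
#'   Schoenfeld p-values plus GLOBAL), `data`, `time`, `event`.
#' @export
fit_cox <- function(covariates, time, event) {
  covariates <- as.data.frame(covariates)
  stopifnot(nrow(covariates) == length(time), length(time) == length(event))
  if (sum(event) < 1)
    stop_pirasurv("at least one event is required", "pirasurv_degenerate")
  if (nrow(covariates) <= ncol(covariates))
    stop_pirasurv("more covariates than patients", "pirasurv_degenerate")
  const <- vapply(covariates, function(x) length(unique(x)) < 2L, logical(1))
  if (any(const))
    stop_pirasurv(sprintf("degenerate design: constant covariate(s) %s",
                          paste(names(covariates)[const], collapse = ", ")),
                  "pirasurv_degenerate")
  df <- cbind(data.frame(.time = time, .event = event), covariates)
  fit <- tryCatch(
    coxph(stats::as.formula(paste(
      "Surv(.time, .event) ~",
      paste(sprintf("`%s`", names(covariates)), collapse = " + "))),
      data = df, x = TRUE),
    error = function(e) stop_pirasurv(
      paste("Cox fit failed:", conditionMessage(e)), "pirasurv_fit_failed"))
  if (any(is.na(coef(fit))))
    stop_pirasurv("Cox fit produced undefined coefficients (separation or collinearity)",
                  "pirasurv_fit_failed")
  s <- summary(fit)
  tab <- data.frame(covariate = rownames(s$conf.int),
                    hr = s$conf.int[, "exp(coef)"],
                    lo = s$conf.int[, "lower .95"],
                    hi = s$conf.int[, "upper .95"],
                    p = s$coefficients[, "Pr(>|z|)"],
                    row.names = NULL)
  ph <- tryCatch(cox.zph(fit)$table[, "p"], error = function(e) NULL)
  structure(list(fit = fit, table = tab,
                 concordance = unname(fit$concordance["concordance"]),
                 ph_test = ph, data = covariates, time = time,
                 event = event),
            class = "pira_cox")
}

#' @export
print.pira_cox <- function(x, ...) {
  if (isTRUE(x$empty)) {
    cat("Empty Cox model: no covariate met the retention threshold\n")
    return(invisible(x))
  }
  cat(sprintf("Cox PH model (%d patients, %d events), Harrell's C = %.3f\n",
              length(x$time), sum(x$event), x$concordance))
  tab <- x$table
  tab$hr <- sprintf("%.3f (%.3f-%.3f)", tab$hr, tab$lo, tab$hi)
  print(tab[, c("covariate", "hr", "p")], row.names = FALSE)
  invisible(x)
}

#' @export
summary.pira_cox <- function(object, ...) {
  print(object)
  if (!is.null(object$ph_test)) {
    cat("Proportional-hazards (scaled Schoenfeld) test p-values:\n")
    print(round(object$ph_test, 4))
  }
  invisible(object)
}

#' Backward covariate elimination at a retention threshold
#'
#' Starting from the full candidate set, repeatedly drops the covariate
#' with the largest Wald p-value at or above `p_keep` and refits, until
#' every retained covariate has `p < p_keep` (default 0.10, the retention
#' rule for baseline predictors such as age, sex, lesion counts and CSF
#' oligoclonal bands).
#'
#' @param covariates Data.frame of candidate predictors.
#' @param time,event Survival outcome.
#' @param p_keep Retention threshold (default 0.10).
#' @return A `pira_cox` fit on the retained covariates, or, when all are
#'   dropped, an object of class `pira_cox` with `empty = TRUE` and no
#'   coefficients.
#' @export
backward_select <- function(covariates, time, event, p_keep = 0.10) {
  covariates <- as.data.frame(covariates)
  keep <- names(covariates)
  while (length(keep) > 0L) {
    fit <- fit_cox(covariates[, keep, drop = FALSE], time, event)
    worst <- which.max(fit$table$p)
    if (fit$table$p[worst] < p_keep) return(fit)
    keep <- setdiff(keep, fit$table$covariate[worst])
  }
  structure(list(empty = TRUE, table = NULL, concordance = NA_real_,
                 data = covariates[, 0, drop = FALSE], time = time,
                 event = event),
            class = "pira_cox")
}

#' Min–max scaling to the unit interval
#'
#' @param x Numeric vector with `max(x) > min(x)`.
#' @return `(x - min) / (max - min)`.
#' @examples
#' minmax_scale(c(0.01, 0.11, 0.21)) # 0, 0.5, 1
#' @export
minmax_scale <- function(x) {
  rng <- range(x)
  if (diff(rng) == 0)
    stop_pirasurv("cannot min-max scale a constant vector",
                  "pirasurv_degenerate")
  (x - rng[1]) / diff(rng)
}

#' Augment a Cox benchmark with the network's cumulative risk
#'
#' Adds the (min–max scaled) first-interval cumulative probability of PIRA
#' from the survival network as an extra covariate, refits, and reports the
#' added covariate's hazard ratio, its significance at the 0.05 gate (the
#' criterion for providing independent information) and the change in
#' Harrell's C.
#'
#' @param base A `pira_cox` from [fit_cox()] or [backward_select()]
#'   (possibly empty).
#' @param dl_risk Numeric vector of per-patient cumulative risks (usually
#'   the first grid interval).
#' @param scale Min–max scale `dl_risk` first (default `TRUE`).
#' @param name Covariate name in the refit.
#' @return A list of class `pira_cox_augmented`: `fit` (the refit
#'   `pira_cox`), `dl_hr`, `dl_ci`, `dl_p`, `significant`, `base_c`,
#'   `new_c`, `delta_c`.
#' @export
augment_with_dl <- function(base, dl_risk, scale = TRUE, name = "dl_risk") {
  stopifnot(inherits(base, "pira_cox"))
  x <- if (scale) minmax_scale(dl_risk) else dl_risk
  covs <- base$data
  if (ncol(covs) > 0) {
    dup <- vapply(covs, function(c0)
      isTRUE(all.equal(as.numeric(c0), as.numeric(x))), logical(1))
    if (any(dup))
      warning("added covariate is identical to an existing one; collinear design",
              call. = FALSE)
  }
  covs[[name]] <- x
  fit <- fit_cox(covs, base$time, base$event)
  row <- fit$table[fit$table$covariate == name, ]
  base_c <- base$concordance
  structure(list(fit = fit, dl_hr = row$hr, dl_ci = c(row$lo, row$hi),
                 dl_p = row$p, significant = row$p < 0.05,
                 base_c = base_c, new_c = fit$concordance,
                 delta_c = fit$concordance -
                   ifelse(is.na(base_c), 0.5, base_c)),
            class = "pira_cox_augmented")
}

#' @export
print.pira_cox_augmented <- function(x, ...) {
  cat(sprintf(paste0("DL-augmented Cox model: HR %.3f (%.3f-%.3f), p = %.3g",
                     " [%ssignificant at 0.05]\n"),
              x$dl_hr, x$dl_ci[1], x$dl_ci[2], x$dl_p,
              if (x$significant) "" else "not "))
  cat(sprintf("Harrell's C: %.3f -> %.3f (delta %+.3f)\n",
              ifelse(is.na(x$base_c), 0.5, x$base_c), x$new_c, x$delta_c))
  invisible(x)
}
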