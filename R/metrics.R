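#' Kaplan–Meier product-limit estimator
#'
#' Product-limit estimate of the survivor function with ties grouped at
#' identical times. A small hand-rolled estimator is used so the censoring
#' distribution can be evaluated "just before" event times for the
#' censoring weights; it is cross-checked against `survival::survfit` in
#' the test suite.
#'
#' @param times Numeric vector of observed times (event or censoring).
#' @param events 0/1 vector of event indicators.
#' @return An object of class `km_curve` with `time` (unique ordered times),
#'   `n_risk`, `n_event`, `n_censor` and `surv`.
#' @export
kaplan_meier <- function(times, events) {
  stopifnot(length(times) == length(events), length(times) >= 1L)
  events <- as.integer(events)
  ut <- sort(unique(times))
  n_event <- vapply(ut, function(t) sum(times == t & events == 1L), numeric(1))
  n_cens <- vapply(ut, function(t) sum(times == t & events == 0L), numeric(1))
  n_risk <- vapply(ut, function(t) sum(times >= t), numeric(1))
  surv <- cumprod(1 - n_event / n_risk)
  structure(list(time = ut, n_risk = n_risk, n_event = n_event,
                 n_censor = n_cens, surv = surv),
            class = "km_curve")
}

#' Evaluate a Kaplan–Meier curve at arbitrary times
#'
#' @param km A [kaplan_meier()] fit.
#' @param t Numeric vector; the right-continuous step function value
#'   `S(t)`, with `S(t) = 1` before the first observed time.
#' @return Numeric vector of survival probabilities.
#' @export
km_surv_at <- function(km, t) {
  idx <- findInterval(t, km$time)
  c(1, km$surv)[idx + 1L]
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("Kaplan-Meier curve: %d distinct times, %d events\n",
              length(x$time), sum(x$n_event)))
  invisible(x)
}

#' @export
plot.km_curve <- function(x, ...) {
  graphics::plot(stats::stepfun(x$time, c(1, x$surv)), do.points = FALSE,
                 xlab = "time", ylab = "S(t)", ylim = c(0, 1), ...)
  invisible(x)
}

#' Time-dependent concordance index
#'
#' The extension of Harrell's concordance to time-varying predicted risks:
#' over all comparable pairs (`i`,`j`) with an observed event for `i` and
#' `T_i < T_j`, the pair is concordant when the predicted cumulative risk
#' of `i` at its own event time exceeds that of `j` evaluated at the same
#' time, `F_i(T_i) > F_j(T_i)`. Prediction ties count 1/2; pairs tied on
#' time are not comparable.
#'
#' @param cumrisk Patients x intervals matrix of predicted cumulative risks.
#' @param interval Integer vector of observed event/censoring intervals.
#' @param event 0/1 event indicators.
#' @return Concordance in `[0, 1]`, or `NA` (with a warning) when no pair
#'   is comparable.
#' @export
td_cindex <- function(cumrisk, interval, event) {
  stopifnot(nrow(cumrisk) == length(interval), length(event) == length(interval))
  num <- 0; den <- 0
  for (i in which(event == 1L)) {
    js <- which(interval > interval[i])
    if (!length(js)) next
    fi <- cumrisk[i, interval[i]]
    fj <- cumrisk[js, interval[i]]
    num <- num + sum(fi > fj) + 0.5 * sum(fi == fj)
    den <- den + length(js)
  }
  if (den == 0) {
    warning("no comparable pairs; time-dependent concordance undefined",
            call. = FALSE)
    return(NA_real_)
  }
  num / den
}

#' Brier score at one grid interval with censoring weights
#'
#' Graf-style inverse-probability-of-censoring weighting (IPCW): patients
#' with an event by interval `k` contribute their squared predicted
#' survival weighted by `1/G(T_i-)`; patients event-free past `k`
#' contribute the squared complement weighted by `1/G(k)`; patients
#' censored by `k` contribute nothing. `G` is the Kaplan–Meier estimate of
#' the censoring distribution (flipped indicators), evaluated just before
#' event times.
#'
#' @param k Grid interval at which to score.
#' @param survivor Patients x intervals matrix of predicted survival.
#' @param interval,event Observed discrete labels.
#' @param censor_km Optional precomputed censoring [kaplan_meier()] fit.
#' @return The Brier score at `k`, or `NA` (with a warning) when the weight
#'   mass is zero.
#' @export
brier_at <- function(k, survivor, interval, event, censor_km = NULL) {
  stopifnot(k >= 1, k <= ncol(survivor))
  if (is.null(censor_km)) censor_km <- kaplan_meier(interval, 1L - event)
  n <- length(interval)
  contrib <- numeric(n)
  used <- FALSE
  for (i in seq_len(n)) {
    if (event[i] == 1L && interval[i] <= k) {
      g <- km_surv_at(censor_km, interval[i] - 1L)
      if (g <= 0) {
        warning("zero censoring weight mass; Brier score undefined",
                call. = FALSE)
        return(NA_real_)
      }
      contrib[i] <- survivor[i, k]^2 / g
      used <- TRUE
    } else if (interval[i] > k) {
      g <- km_surv_at(censor_km, k)
      if (g <= 0) {
        warning("zero censoring weight mass; Brier score undefined",
                call. = FALSE)
        return(NA_real_)
      }
      contrib[i] <- (1 - survivor[i, k])^2 / g
      used <- TRUE
    } # censored by k: weight 0
  }
  if (!used) {
    warning("no patient contributes at this interval; Brier score undefined",
            call. = FALSE)
    return(NA_real_)
  }
  mean(contrib)
}

#' Integrated Brier score over the interval grid
#'
#' Computes the censoring-weighted Brier score at every grid interval and
#' summarises it as the mean and standard deviation across intervals (the
#' default reporting), optionally also as a trapezoidal time integral
#' normalised by the grid span.
#'
#' @param survivor Patients x intervals matrix of predicted survival.
#' @param interval,event Observed discrete labels.
#' @param type `"mean"` (default) or `"trapezoid"`.
#' @return A list with `scores` (per-interval BS), `mean`, `sd`, and for
#'   `"trapezoid"` the normalised `integral`.
#' @export
integrated_brier <- function(survivor, interval, event,
                             type = c("mean", "trapezoid")) {
  type <- match.arg(type)
  K <- ncol(survivor)
  ckm <- kaplan_meier(interval, 1L - event)
  scores <- vapply(seq_len(K), function(k)
    suppressWarnings(brier_at(k, survivor, interval, event, ckm)),
    numeric(1))
  out <- list(scores = scores, mean = mean(scores, na.rm = TRUE),
              sd = sd(scores, na.rm = TRUE))
  if (type == "trapezoid") {
    ok <- which(!is.na(scores))
    xs <- ok; ys <- scores[ok]
    out$integral <- if (length(ok) >= 2L)
      sum(diff(xs) * (head(ys, -1) + tail(ys, -1)) / 2) / diff(range(xs))
    else NA_real_
  }
  out
}

#' Non-informative Brier score bound for a given incidence
#'
#' For outcome incidence `p` the score of an uninformative constant
#' prediction is `p (1-p)^2 + (1-p) p^2 = p (1-p)`: 0.25 at 50% incidence
#' and ~0.17 at 22%, the acceptability ceiling used when judging the
#' integrated Brier score.
#'
#' @param p Incidence in `[0, 1]`.
#' @return The bound `p * (1 - p)`.
#' @examples
#' noninformative_brier_bound(0.5)  # 0.25
#' noninformative_brier_bound(0.22) # 0.1716
#' @export
noninformative_brier_bound <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  p * (1 - p)^2 + (1 - p) * p^2
}

#' ROC curve and area under the curve
#'
#' Thin wrapper over [pROC::roc()] (trapezoidal AUC, equal to the
#' Mann–Whitney statistic with tie correction).
#'
#' @param scores Numeric predictor (higher = more likely positive).
#' @param labels 0/1 outcome vector; both classes must be present.
#' @return A list with `auc`, `curve` (data.frame of thresholds,
#'   sensitivity, specificity) and the underlying `roc` object.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L)
    stop_pirasurv("both outcome classes must be present for a ROC curve",
                  "pirasurv_degenerate")
  r <- pROC::roc(labels, scores, levels = c(0, 1), direction = "<",
                 quiet = TRUE)
  list(auc = as.numeric(pROC::auc(r)),
       curve = data.frame(threshold = r$thresholds,
                          sensitivity = r$sensitivities,
                          specificity = r$specificities),
       roc = r)
}

#' Šidák correction for multiple comparisons
#'
#' @param p Unadjusted p-value(s).
#' @param n_comparisons Number of comparisons.
#' @return Adjusted p-values `1 - (1 - p)^n`.
#' @examples
#' sidak_adjust(0.01, 10) # 0.0956
#' @export
sidak_adjust <- function(p, n_comparisons) {
  stopifnot(all(p >= 0 & p <= 1), n_comparisons >= 1)
  1 - (1 - p)^n_comparisons
}

#' Joint comparison of correlated AUCs
#'
#' Tests equality of the AUCs of `m` score columns measured on the same
#' subjects via the covariance of their placement values (a DeLong-type
#' construction): the contrast of AUC differences is referred to a
#' chi-square distribution with rank(covariance) degrees of freedom.
#' Identical columns give a zero statistic with p = 1. A Šidák-adjusted
#' p-value for `n_comparisons` parallel tests is also reported.
#'
#' @param scores Numeric matrix, subjects x score sets (`m >= 2` columns).
#' @param labels 0/1 outcomes.
#' @param n_comparisons Number of comparisons for the Šidák adjustment
#'   (default 1, i.e. no adjustment).
#' @return A list with `statistic`, `df`, `p_value`, `p_sidak` and `auc`
#'   (per-column AUCs).
#' @export
compare_aucs <- function(scores, labels, n_comparisons = 1L) {
  scores <- as.matrix(scores)
  m <- ncol(scores)
  stopifnot(m >= 2L)
  labels <- as.integer(labels)
  pos <- scores[labels == 1L, , drop = FALSE]
  neg <- scores[labels == 0L, , drop = FALSE]
  n1 <- nrow(pos); n0 <- nrow(neg)
  if (n1 == 0L || n0 == 0L)
    stop_pirasurv("both outcome classes must be present",
                  "pirasurv_degenerate")
  psi <- function(x, y) (x > y) + 0.5 * (x == y)
  V10 <- matrix(0, n1, m); V01 <- matrix(0, n0, m)
  for (c in seq_len(m)) {
    P <- outer(pos[, c], neg[, c], psi)
    V10[, c] <- rowMeans(P)
    V01[, c] <- colMeans(P)
  }
  theta <- colMeans(V10)
  S <- cov(V10) / n1 + cov(V01) / n0
  L <- diff(diag(m)) # (m-1) x m contrasts of adjacent columns
  d <- drop(L %*% theta)
  V <- L %*% S %*% t(L)
  rk <- qr(V, tol = 1e-12)$rank
  if (rk == 0L) {
    stat <- 0; p <- 1; df <- 0L
  } else {
    stat <- drop(t(d) %*% MASS::ginv(V) %*% d)
    df <- rk
    p <- pchisq(stat, df, lower.tail = FALSE)
  }
  list(statistic = stat, df = df, p_value = p,
       p_sidak = sidak_adjust(p, n_comparisons), auc = theta)
}

#' Binary classification report with exact binomial confidence intervals
#'
#' Standard metrics from a 2x2 confusion matrix with exact
#' (Clopper–Pearson) 95% intervals for each proportion.
#'
#' @param tp,fp,fn,tn Non-negative counts.
#' @return An object of class `classification_report`: counts, point
#'   estimates (`sensitivity`, `specificity`, `ppv`, `npv`, `accuracy`, as
#'   proportions) and `ci95`, a named list of `(lo, hi)` pairs. Metrics
#'   with a zero denominator are `NA`.
#' @examples
#' classification_report(tp = 15, fp = 13, fn = 43, tn = 188)
#' @export
classification_report <- function(tp, fp, fn, tn) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(counts < 0) || any(!is_wholeish(counts)))
    stop_pirasurv("counts must be non-negative integers",
                  "pirasurv_bad_input")
  prop_ci <- function(x, n) {
    if (n == 0) return(list(est = NA_real_, ci = c(NA_real_, NA_real_)))
    list(est = x / n, ci = as.numeric(binom.test(x, n)$conf.int))
  }
  parts <- list(sensitivity = prop_ci(tp, tp + fn),
                specificity = prop_ci(tn, tn + fp),
                ppv = prop_ci(tp, tp + fp),
                npv = prop_ci(tn, tn + fn),
                accuracy = prop_ci(tp + tn, sum(counts)))
  structure(list(counts = counts,
                 sensitivity = parts$sensitivity$est,
                 specificity = parts$specificity$est,
                 ppv = parts$ppv$est, npv = parts$npv$est,
                 accuracy = parts$accuracy$est,
                 ci95 = lapply(parts, `[[`, "ci")),
            class = "classification_report")
}

# half-up rounding of percentages, matching how clinical tables are printed
round_half_up <- function(x, digits = 2) {
  floor(x * 10^digits + 0.5) / 10^digits
}

#' @export
print.classification_report <- function(x, ...) {
  fmt <- function(v, ci) sprintf("%6.2f%% (%.2f%% to %.2f%%)",
                                 round_half_up(100 * v),
                                 round_half_up(100 * ci[1]),
                                 round_half_up(100 * ci[2]))
  cat(sprintf("Confusion counts: tp=%d fp=%d fn=%d tn=%d\n",
              x$counts["tp"], x$counts["fp"], x$counts["fn"],
              x$counts["tn"]))
  for (m in c("sensitivity", "specificity", "ppv", "npv", "accuracy"))
    cat(sprintf("  %-11s %s\n", m, fmt(x[[m]], x$ci95[[m]])))
  invisible(x)
}

#' Best-accuracy threshold for a risk score
#'
#' Exhaustively scans candidate thresholds (all unique score values plus
#' `+Inf`), classifying positive when `score >= threshold`, and returns the
#' threshold maximising accuracy. Ties are broken towards higher
#' specificity, then towards the smaller threshold. Because the
#' all-positive and all-negative classifiers are among the candidates, the
#' selected accuracy is never below the majority-class rate.
#'
#' @param scores Numeric risk scores.
#' @param labels 0/1 outcomes.
#' @param interval Optional interval index the scores came from (recorded
#'   in the report).
#' @return An object of class `threshold_report`: `threshold`,
#'   `interval_used`, `accuracy` and `report` (a
#'   [classification_report()]).
#' @examples
#' best_accuracy_threshold(c(.1, .2, .8, .9), c(0, 0, 1, 1))$threshold # 0.8
#' @export
best_accuracy_threshold <- function(scores, labels, interval = NA_integer_) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels))
  cands <- c(sort(unique(scores)), Inf)
  n <- length(labels)
  best <- NULL
  for (thr in cands) {
    pred <- as.integer(scores >= thr)
    tp <- sum(pred == 1L & labels == 1L)
    fp <- sum(pred == 1L & labels == 0L)
    fn <- sum(pred == 0L & labels == 1L)
    tn <- sum(pred == 0L & labels == 0L)
    acc <- (tp + tn) / n
    spec <- if (tn + fp > 0) tn / (tn + fp) else 1
    cand <- list(thr = thr, acc = acc, spec = spec,
                 counts = c(tp, fp, fn, tn))
    if (is.null(best) || acc > best$acc + 1e-12 ||
        (abs(acc - best$acc) <= 1e-12 &&
         (spec > best$spec + 1e-12 ||
          (abs(spec - best$spec) <= 1e-12 && thr < best$thr))))
      best <- cand
  }
  structure(list(threshold = best$thr, interval_used = interval,
                 accuracy = best$acc,
                 report = classification_report(best$counts[1],
                                                best$counts[2],
                                                best$counts[3],
                                                best$counts[4])),
            class = "threshold_report")
}

#' @export
print.threshold_report <- function(x, ...) {
  cat(sprintf("Best-accuracy threshold: score >= %.5g (accuracy %.2f%%)\n",
              x$threshold, 100 * x$accuracy))
  if (!is.na(x$interval_used))
    cat(sprintf("  cumulative risk at interval %d\n", x$interval_used))
  print(x$report)
  invisible(x)
}
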