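#' Convert discrete-time hazards to a survivor curve
#'
#' With conditional hazards \eqn{h_j} (probability of the event in interval
#' \eqn{j} given survival to its start), the survivor function on the grid
#' is the product-limit identity \eqn{S_k = \prod_{j \le k} (1 - h_j)},
#' i.e. \eqn{\hat S(t) = pr(T > t)} evaluated at interval ends.
#'
#' @param h Numeric vector of hazards in `[0, 1]`, or a matrix with one row
#'   per patient and one column per interval.
#' @return Survivor values, same shape as `h`; non-increasing along the
#'   grid, in `(0, 1]` when hazards are strictly inside `(0, 1)`.
#' @examples
#' hazard_to_survivor(c(0.1, 0.2)) # 0.9, 0.72
#' @export
hazard_to_survivor <- function(h) {
  if (any(h < 0 | h > 1))
    stop_pirasurv("hazards must lie in [0, 1]", "pirasurv_bad_input")
  if (is.matrix(h)) {
    out <- t(apply(1 - h, 1L, cumprod))
    dimnames(out) <- dimnames(h)
    out
  } else cumprod(1 - h)
}

#' Convert a survivor curve to cumulative risk
#'
#' The cumulative risk (distribution function of the event time) is
#' \eqn{\hat F(t) = 1 - \hat S(t) = pr(T \le t)}.
#'
#' @param S Survivor values (vector or matrix) in `[0, 1]`.
#' @return `1 - S`, elementwise.
#' @export
survivor_to_cumrisk <- function(S) {
  if (any(S < 0 | S > 1))
    stop_pirasurv("survivor values must lie in [0, 1]", "pirasurv_bad_input")
  1 - S
}

#' Alias used by the synthetic-data module
#' @rdname hazard_to_survivor
#' @export
true_survivor <- hazard_to_survivor

#' Negative log-likelihood of discrete survival labels under hazards
#'
#' For a patient with event in interval `k` the contribution is
#' \eqn{-\log h_k - \sum_{j<k} \log(1-h_j)}; for a censoring in interval `k`
#' it is \eqn{-\sum_{j \le k} \log(1-h_j)}. Each interval's term only
#' involves patients whose event or censoring falls no earlier than that
#' interval. Hazards are clamped to `[eps, 1-eps]` for numerical safety.
#'
#' @param h Matrix of hazards (patients x intervals) or a vector for a
#'   single patient.
#' @param interval Integer vector of interval indices.
#' @param event 0/1 vector of event indicators.
#' @param reduce `"mean"` (default, the batch loss) or `"none"` (per-patient
#'   losses).
#' @param eps Clamping constant (default `1e-7`).
#' @return Non-negative loss value(s).
#' @examples
#' discrete_nll(matrix(0.5, 1, 2), 2, 1) # -log(.5) - log(.5) = 1.386
#' @export
discrete_nll <- function(h, interval, event, reduce = c("mean", "none"),
                         eps = 1e-7) {
  reduce <- match.arg(reduce)
  if (!is.matrix(h)) h <- matrix(h, nrow = 1L)
  n <- nrow(h); K <- ncol(h)
  stopifnot(length(interval) == n, length(event) == n,
            all(interval >= 1 & interval <= K))
  hc <- pmin(pmax(h, eps), 1 - eps)
  loss <- numeric(n)
  lg1m <- log(1 - hc)
  for (i in seq_len(n)) {
    k <- interval[i]
    loss[i] <- if (event[i] == 1) {
      -log(hc[i, k]) - if (k > 1L) sum(lg1m[i, seq_len(k - 1L)]) else 0
    } else {
      -sum(lg1m[i, seq_len(k)])
    }
  }
  if (reduce == "mean") mean(loss) else loss
}

#' Average cumulative-risk curves across an ensemble of models
#'
#' The external-validation protocol applies every fold model to each
#' patient and averages the per-model interval-specific cumulative
#' probabilities into one curve per patient.
#'
#' @param risks A list of numeric vectors or matrices (patients x
#'   intervals), all of identical shape.
#' @return The elementwise arithmetic mean.
#' @export
ensemble_average <- function(risks) {
  stopifnot(is.list(risks), length(risks) >= 1L)
  d1 <- dim(risks[[1L]]) %||% length(risks[[1L]])
  for (r in risks)
    if (!identical(dim(r) %||% length(r), d1))
      stop_pirasurv("ensemble members must share the same grid/shape",
                    "pirasurv_bad_input")
  Reduce(`+`, risks) / length(risks)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
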