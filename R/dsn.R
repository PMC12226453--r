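#' Training configuration for the discrete-time survival network
#'
#' Defaults follow the training protocol of the survival network: at most
#' 150 epochs, batches of 64 slices, early stopping after 7 epochs without
#' validation improvement, Adam with a cosine-annealed learning rate. The
#' default initial rate of `1e-5` is a fine-tuning rate appropriate for a
#' pretrained backbone; when training the `"tiny"` backbone from scratch a
#' rate around `1e-3` is the sensible choice (see the package vignette).
#'
#' @param max_epochs Maximum epochs (default 150).
#' @param batch_size Slices per batch (default 64).
#' @param patience Early-stopping patience in epochs (default 7).
#' @param initial_lr Initial learning rate (default `1e-5`).
#' @param lr_schedule `"cosine"` (annealing to 0 at `max_epochs`) or
#'   `"constant"`.
#' @param backbone `"tiny"` (3 convolution blocks + global average pooling,
#'   the default) or `"mbconv-se"` (a mobile-inverted-bottleneck block with
#'   squeeze-and-excitation and Swish activations). No pretrained weights
#'   are shipped for either.
#' @param fine_tune_from_block Accepted for interface compatibility with
#'   pretrained backbones; a no-op for the randomly initialised backbones
#'   shipped here.
#' @param seed Integer seed for weight initialisation and batch shuffling.
#' @return An object of class `dsn_config`.
#' @export
dsn_config <- function(max_epochs = 150L, batch_size = 64L, patience = 7L,
                       initial_lr = 1e-5,
                       lr_schedule = c("cosine", "constant"),
                       backbone = c("tiny", "mbconv-se"),
                       fine_tune_from_block = NULL, seed = 1L) {
  lr_schedule <- match.arg(lr_schedule)
  backbone <- match.arg(backbone)
  stopifnot(max_epochs >= 1, batch_size >= 1, patience >= 1, initial_lr > 0)
  structure(list(max_epochs = as.integer(max_epochs),
                 batch_size = as.integer(batch_size),
                 patience = as.integer(patience),
                 initial_lr = initial_lr, lr_schedule = lr_schedule,
                 backbone = backbone,
                 fine_tune_from_block = fine_tune_from_block,
                 seed = as.integer(seed)),
            class = "dsn_config")
}

#' Cross-validation folds with similar event-time distributions
#'
#' Patients are stratified by event indicator crossed with a tercile bin of
#' their (event or censoring) interval; each stratum is shuffled under the
#' seed and dealt round-robin over folds, so per-fold event counts are
#' within one patient of exact proportionality.
#'
#' @param labels Data.frame with columns `interval`, `event`.
#' @param k_folds Number of folds (default 5).
#' @param seed Integer seed.
#' @return Integer vector of fold assignments in `1..k_folds`.
#' @export
stratified_event_time_folds <- function(labels, k_folds = 5L, seed = NULL) {
  n <- nrow(labels)
  stopifnot(n >= k_folds)
  if (!is.null(seed)) set.seed(seed)
  bin3 <- function(x) {
    if (length(unique(x)) < 3L) return(rep(1L, length(x)))
    q <- quantile(x, c(1, 2) / 3, type = 7)
    findInterval(x, unique(q)) + 1L
  }
  strata <- integer(n)
  for (e in unique(labels$event)) {
    idx <- which(labels$event == e)
    strata[idx] <- 10L * e + bin3(labels$interval[idx])
  }
  fold <- integer(n)
  offset <- 0L
  for (s in sort(unique(strata))) {
    idx <- which(strata == s)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- ((offset + seq_along(idx) - 1L) %% k_folds) + 1L
    offset <- offset + length(idx)
  }
  fold
}

# flatten a list of (H, W, 2, s) slice stacks into a slice-level batch array
# plus a patient index per slice
.flatten_stacks <- function(stacks) {
  stopifnot(length(stacks) >= 1L)
  d <- dim(stacks[[1L]])
  ns <- vapply(stacks, function(s) dim(s)[4], integer(1))
  N <- sum(ns)
  X <- array(0, c(N, d[1], d[2], d[3]))
  pat <- integer(N)
  at <- 0L
  for (i in seq_along(stacks)) {
    s <- stacks[[i]]
    if (!identical(dim(s)[1:3], d[1:3]))
      stop_pirasurv("all slice stacks must share height/width/channels",
                    "pirasurv_bad_input")
    for (j in seq_len(dim(s)[4])) X[at + j, , , ] <- s[, , , j]
    pat[at + seq_len(dim(s)[4])] <- i
    at <- at + dim(s)[4]
  }
  list(X = X, patient = pat)
}

.batch_loss <- function(net, X, interval, event, batch = 256L) {
  n <- dim(X)[1]
  tot <- 0
  for (b in split(seq_len(n), ceiling(seq_len(n) / batch))) {
    fw <- net_forward(net, X[b, , , , drop = FALSE])
    tot <- tot + discrete_nll(fw$h, interval[b], event[b]) * length(b)
  }
  tot / n
}

#' Fit the discrete-time survival network
#'
#' Trains a 2D CNN with an 11-unit sigmoid head on 2-channel axial slices.
#' The sigmoid outputs are interpreted as per-interval conditional hazards;
#' the survivor curve is their cumulative product (see the vignette for why
#' this reading is used). Every slice of a patient carries that patient's
#' discrete survival label; training minimises the mean discrete-time
#' negative log-likelihood with Adam, a cosine-annealed learning rate and
#' early stopping on the validation loss. The weights from the best
#' validation epoch are kept.
#'
#' @param x List of slice stacks (`(H, W, 2, s)` arrays from
#'   [central_slices()]), one per training patient. `H` and `W` must be
#'   multiples of 4.
#' @param labels Data.frame with columns `interval`, `event`, one row per
#'   element of `x`.
#' @param x_val,labels_val Validation patients, same formats. If omitted, a
#'   20% event-stratified split of the training patients is held out.
#' @param config A [dsn_config()].
#' @param grid The [time_grid()]; its length fixes the output dimension.
#' @param verbose Print per-epoch losses.
#' @return An object of class `pira_dsn` with the fitted weights, the
#'   training log (one row per epoch), the best epoch and configuration.
#' @seealso [predict.pira_dsn()], [cv_pira_dsn()]
#' @export
pira_dsn <- function(x, labels, x_val = NULL, labels_val = NULL,
                     config = dsn_config(), grid = time_grid(),
                     verbose = FALSE) {
  stopifnot(length(x) == nrow(labels))
  if (is.null(x_val)) {
    set.seed(config$seed)
    hold <- unlist(lapply(split(seq_along(x), labels$event), function(idx)
      idx[sample.int(length(idx), max(1L, round(0.2 * length(idx))))]))
    x_val <- x[hold]; labels_val <- labels[hold, , drop = FALSE]
    x <- x[-hold]; labels <- labels[-hold, , drop = FALSE]
  }
  if (length(x) == 0L || length(x_val) == 0L)
    stop_pirasurv("training and validation sets must be non-empty",
                  "pirasurv_bad_input")

  tr <- .flatten_stacks(x)
  va <- .flatten_stacks(x_val)
  d <- dim(tr$X)
  if (d[2] %% 4 != 0 || d[3] %% 4 != 0)
    stop_pirasurv("slice height/width must be multiples of 4",
                  "pirasurv_bad_input")
  k_tr <- labels$interval[tr$patient]; d_tr <- labels$event[tr$patient]
  k_va <- labels_val$interval[va$patient]; d_va <- labels_val$event[va$patient]

  set.seed(config$seed)
  net <- net_init(config$backbone, in_channels = d[4],
                  n_out = grid$n_intervals)
  opt <- adam_init(net$params)

  best <- list(val = Inf, params = net$params, epoch = 0L)
  log <- data.frame(epoch = integer(), lr = numeric(),
                    train_loss = numeric(), val_loss = numeric())
  n_slice <- d[1]

  for (epoch in seq_len(config$max_epochs)) {
    lr <- if (config$lr_schedule == "cosine")
      cosine_lr(config$initial_lr, epoch, config$max_epochs)
    else config$initial_lr
    ord <- sample.int(n_slice)
    ep_loss <- 0
    for (b in split(ord, ceiling(seq_along(ord) / config$batch_size))) {
      Xb <- tr$X[b, , , , drop = FALSE]
      fw <- net_forward(net, Xb, keep_cache = TRUE)
      loss <- discrete_nll(fw$h, k_tr[b], d_tr[b])
      if (!is.finite(loss))
        stop_pirasurv(sprintf(
          "non-finite training loss at epoch %d (lr %.2g); diverged",
          epoch, lr), "pirasurv_diverged")
      ep_loss <- ep_loss + loss * length(b)
      dz <- nll_grad_z(fw$h, k_tr[b], d_tr[b])
      bw <- net_backward(net, fw$cache, dz)
      upd <- adam_step(net$params, bw$grads, opt, lr)
      net$params <- upd$params; opt <- upd$state
    }
    val_loss <- .batch_loss(net, va$X, k_va, d_va)
    log <- rbind(log, data.frame(epoch = epoch, lr = lr,
                                 train_loss = ep_loss / n_slice,
                                 val_loss = val_loss))
    if (verbose)
      message(sprintf("epoch %3d  lr %.2g  train %.4f  val %.4f",
                      epoch, lr, ep_loss / n_slice, val_loss))
    if (val_loss < best$val - 1e-9) {
      best <- list(val = val_loss, params = net$params, epoch = epoch)
    } else if (epoch - best$epoch >= config$patience) break
  }
  net$params <- best$params
  structure(list(net = net, config = config, grid = grid, log = log,
                 best_epoch = best$epoch, val_loss = best$val,
                 input_dim = d[2:4],
                 train_labels = labels, val_labels = labels_val),
            class = "pira_dsn")
}

#' Predict survivor and cumulative-risk curves for patients
#'
#' Each slice is passed through the network; the patient-level survivor
#' curve is the elementwise median over the slice survivor curves (order
#' statistics preserve monotonicity), and the cumulative risk is its
#' complement.
#'
#' @param object A fitted [pira_dsn()].
#' @param newdata List of slice stacks, one per patient.
#' @param type `"cumrisk"` (default), `"survivor"`, or `"hazard"` (hazards
#'   are slice-level medians and reported for diagnostics).
#' @param aggregate `"median"` over slices (default) or `"none"` to get
#'   slice-level curves (a list of matrices).
#' @param ... Unused.
#' @return A patients x intervals matrix (or a list when
#'   `aggregate = "none"`).
#' @export
predict.pira_dsn <- function(object, newdata,
                             type = c("cumrisk", "survivor", "hazard"),
                             aggregate = c("median", "none"), ...) {
  type <- match.arg(type)
  aggregate <- match.arg(aggregate)
  stopifnot(is.list(newdata), length(newdata) >= 1L)
  out <- vector("list", length(newdata))
  for (i in seq_along(newdata)) {
    s <- newdata[[i]]
    ns <- dim(s)[4]
    if (is.null(ns) || ns == 0L)
      stop_pirasurv("empty slice stack", "pirasurv_bad_input")
    X <- aperm(array(s, c(dim(s)[1], dim(s)[2], dim(s)[3], ns)),
               c(4, 1, 2, 3))
    h <- net_forward(object$net, X)$h
    h <- pmin(pmax(h, 1e-7), 1 - 1e-7)
    val <- switch(type,
                  hazard = h,
                  survivor = hazard_to_survivor(h),
                  cumrisk = survivor_to_cumrisk(hazard_to_survivor(h)))
    out[[i]] <- val
  }
  if (aggregate == "none") return(out)
  res <- t(vapply(out, function(m) apply(m, 2L, median),
                  numeric(object$grid$n_intervals)))
  colnames(res) <- paste0("interval", seq_len(object$grid$n_intervals))
  res
}

#' @export
print.pira_dsn <- function(x, ...) {
  cat(sprintf(paste0("Discrete-time survival network (backbone '%s')\n",
                     "  input %d x %d x %d, %d output intervals\n",
                     "  trained %d epochs (best %d), val NLL %.4f\n"),
              x$config$backbone, x$input_dim[1], x$input_dim[2],
              x$input_dim[3], x$grid$n_intervals, nrow(x$log),
              x$best_epoch, x$val_loss))
  invisible(x)
}

#' @export
summary.pira_dsn <- function(object, ...) {
  npar <- sum(vapply(object$net$params, length, numeric(1)))
  cat(sprintf("pira_dsn: %s backbone, %d parameters\n",
              object$config$backbone, npar))
  cat(sprintf("best epoch %d of %d run; validation NLL %.4f\n",
              object$best_epoch, nrow(object$log), object$val_loss))
  print(tail(object$log, 3L), row.names = FALSE)
  invisible(object)
}

#' @export
coef.pira_dsn <- function(object, ...) {
  list(weights = object$net$params$fc_W, bias = object$net$params$fc_b)
}

#' @export
plot.pira_dsn <- function(x, ...) {
  graphics::plot(x$log$epoch, x$log$val_loss, type = "l",
                 xlab = "epoch", ylab = "loss", col = "firebrick", ...)
  graphics::lines(x$log$epoch, x$log$train_loss, col = "grey40")
  graphics::legend("topright", c("validation", "training"),
                   col = c("firebrick", "grey40"), lty = 1, bty = "n")
  invisible(x)
}

#' Cross-validated training of the survival network
#'
#' Splits patients into `k_folds` folds with similar event-time
#' distributions; each iteration uses one fold for testing, the next for
#' validation (early stopping) and the rest for training, and the held-out
#' cumulative risks are assembled into an out-of-fold prediction matrix.
#'
#' @param x List of slice stacks, one per patient.
#' @param labels Data.frame with `interval`, `event`.
#' @param k_folds Number of folds (default 5).
#' @param config A [dsn_config()].
#' @param grid A [time_grid()].
#' @return A list with `models` (per-fold `pira_dsn` fits), `fold`
#'   (assignments), and `cumrisk` (out-of-fold patients x intervals
#'   matrix).
#' @export
cv_pira_dsn <- function(x, labels, k_folds = 5L, config = dsn_config(),
                        grid = time_grid()) {
  fold <- stratified_event_time_folds(labels, k_folds, seed = config$seed)
  models <- vector("list", k_folds)
  F_oof <- matrix(NA_real_, length(x), grid$n_intervals)
  for (f in seq_len(k_folds)) {
    vfold <- (f %% k_folds) + 1L
    te <- which(fold == f); va <- which(fold == vfold)
    tr <- which(!(fold %in% c(f, vfold)))
    cfg <- config; cfg$seed <- config$seed + f
    models[[f]] <- pira_dsn(x[tr], labels[tr, , drop = FALSE],
                            x[va], labels[va, , drop = FALSE],
                            config = cfg, grid = grid)
    F_oof[te, ] <- predict(models[[f]], x[te], type = "cumrisk")
  }
  list(models = models, fold = fold, cumrisk = F_oof)
}
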