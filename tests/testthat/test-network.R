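test_that("network gradients match finite differences for both backbones", {
  set.seed(100)
  for (bb in c("tiny", "mbconv-se")) {
    net <- pirasurv:::net_init(bb, in_channels = 2, n_out = 4, seed = 3)
    X <- array(rnorm(2 * 8 * 8 * 2), c(2, 8, 8, 2))
    k <- c(2L, 4L); d <- c(1L, 0L)
    fw <- pirasurv:::net_forward(net, X, keep_cache = TRUE)
    dz <- pirasurv:::nll_grad_z(fw$h, k, d)
    bw <- pirasurv:::net_backward(net, fw$cache, dz)
    lossfn <- function(nn) discrete_nll(pirasurv:::net_forward(nn, X)$h, k, d)
    eps <- 1e-5
    for (nm in names(net$params)) {
      p <- net$params[[nm]]
      for (i in sample(length(p), min(3, length(p)))) {
        n2 <- net
        n2$params[[nm]][i] <- p[i] + eps; up <- lossfn(n2)
        n2$params[[nm]][i] <- p[i] - eps; dn <- lossfn(n2)
        fd <- (up - dn) / (2 * eps)
        expect_equal(bw$grads[[nm]][i], fd, tolerance = 1e-4)
      }
    }
    # input gradient (used by the attribution backend)
    for (i in sample(length(X), 3)) {
      X2 <- X; X2[i] <- X[i] + eps
      up <- discrete_nll(pirasurv:::net_forward(net, X2)$h, k, d)
      X2[i] <- X[i] - eps
      dn <- discrete_nll(pirasurv:::net_forward(net, X2)$h, k, d)
      expect_equal(bw$dX[i], (up - dn) / (2 * eps), tolerance = 1e-4)
    }
  }
})

test_that("stratified folds balance events and are seed-reproducible", {
  labels <- data.frame(interval = c(rep(1:5, 2), sample(1:11, 40, TRUE)),
                       event = c(rep(1L, 10), rep(0L, 40)))
  f <- stratified_event_time_folds(labels, 5, seed = 2)
  expect_equal(sort(unique(f)), 1:5)
  ev_per_fold <- tapply(labels$event, f, sum)
  expect_true(all(ev_per_fold == 2)) # 10 events over 5 folds
  expect_identical(f, stratified_event_time_folds(labels, 5, seed = 2))
  # all-censored cohorts still stratify on time bins alone
  lab0 <- data.frame(interval = sample(1:11, 30, TRUE), event = 0L)
  f0 <- stratified_event_time_folds(lab0, 3, seed = 1)
  expect_equal(as.vector(table(f0)), rep(10, 3))
})

test_that("training reduces validation loss below the constant-hazard baseline", {
  # under strong image-hazard coupling, the fitted network's validation NLL
  # must undercut the best covariate-free model: constant per-interval
  # hazards estimated analytically from the cohort's event frequencies
  fit <- strong_fit()
  trn <- fit$train_labels
  val <- fit$val_labels
  K <- 11
  atr <- vapply(1:K, function(k) sum(trn$interval >= k), numeric(1))
  evk <- vapply(1:K, function(k) sum(trn$interval == k & trn$event == 1),
                numeric(1))
  hconst <- ifelse(atr > 0, evk / atr, 0)
  base <- discrete_nll(matrix(pmin(pmax(hconst, 1e-7), 1 - 1e-7),
                              nrow(val), K, byrow = TRUE),
                       val$interval, val$event)
  expect_lt(fit$val_loss, base)
  # training log is complete and the early-stopping bookkeeping holds
  expect_true(all(c("epoch", "lr", "train_loss", "val_loss") %in%
                    names(fit$log)))
  expect_lte(nrow(fit$log), fit$best_epoch + fit$config$patience)
})

test_that("patience halts training within 7 epochs of the best one", {
  set.seed(9)
  hp <- hazard_model_params(alpha = -2, beta_lesion = 0, beta_ventricle = 0)
  coh <- tiny_imaging_cohort(20, hp, hw = 16, Z = 6, n_slices = 2L, seed = 3)
  fit <- pira_dsn(coh$stacks[1:14], coh$labels[1:14, ],
                  coh$stacks[15:20], coh$labels[15:20, ],
                  config = dsn_config(initial_lr = 1e-3, max_epochs = 60L,
                                      patience = 7L, seed = 1))
  expect_lte(nrow(fit$log), fit$best_epoch + 7L)
})

test_that("patient curves are slice-order invariant, monotone medians", {
  set.seed(23)
  hp <- hazard_model_params(alpha = -2)
  coh <- tiny_imaging_cohort(12, hp, hw = 16, Z = 8, n_slices = 4L, seed = 2)
  fit <- pira_dsn(coh$stacks[1:9], coh$labels[1:9, ],
                  coh$stacks[10:12], coh$labels[10:12, ],
                  config = dsn_config(initial_lr = 1e-3, max_epochs = 2L,
                                      seed = 6))
  st <- coh$stacks[[10]]
  S1 <- predict(fit, list(st), type = "survivor")
  perm <- st[, , , c(3, 1, 4, 2)]
  S2 <- predict(fit, list(perm), type = "survivor")
  expect_equal(S1, S2)
  expect_true(all(diff(S1[1, ]) <= 1e-12))
  # identical slices: the patient curve equals the slice curve
  same <- st[, , , c(1, 1, 1)]
  S3 <- predict(fit, list(same), type = "survivor", aggregate = "none")[[1]]
  S4 <- predict(fit, list(same), type = "survivor")
  expect_equal(S4[1, ], S3[1, ], ignore_attr = TRUE)
  # median definition on a known triple
  sl <- predict(fit, list(st), type = "survivor", aggregate = "none")[[1]]
  expect_equal(predict(fit, list(st), type = "survivor")[1, 1],
               median(sl[, 1]), ignore_attr = TRUE)
  expect_error(predict(fit, list(st[, , , 0, drop = FALSE])),
               class = "pirasurv_bad_input")
})

test_that("hazard/survivor/cumrisk predictions are mutually consistent", {
  set.seed(33)
  hp <- hazard_model_params(alpha = -2)
  coh <- tiny_imaging_cohort(8, hp, hw = 16, Z = 6, n_slices = 2L, seed = 14)
  fit <- pira_dsn(coh$stacks[1:6], coh$labels[1:6, ],
                  coh$stacks[7:8], coh$labels[7:8, ],
                  config = dsn_config(initial_lr = 1e-3, max_epochs = 2L,
                                      seed = 8))
  S <- predict(fit, coh$stacks[7:8], type = "survivor")
  F <- predict(fit, coh$stacks[7:8], type = "cumrisk")
  expect_equal(F, 1 - S, ignore_attr = TRUE)
})

test_that("cross-validated training returns complete out-of-fold predictions", {
  set.seed(44)
  hp <- hazard_model_params(alpha = -2)
  coh <- tiny_imaging_cohort(18, hp, hw = 16, Z = 6, n_slices = 2L, seed = 9)
  cv <- cv_pira_dsn(coh$stacks, coh$labels, k_folds = 3,
                    config = dsn_config(initial_lr = 1e-3, max_epochs = 2L,
                                        seed = 2))
  expect_equal(length(cv$models), 3)
  expect_false(any(is.na(cv$cumrisk)))
  expect_true(all(cv$cumrisk >= 0 & cv$cumrisk <= 1))
  # fold-ensemble averaging over the models reproduces per-model means
  F_each <- lapply(cv$models, function(m) predict(m, coh$stacks[1:2]))
  avg <- ensemble_average(F_each)
  expect_equal(avg, (F_each[[1]] + F_each[[2]] + F_each[[3]]) / 3)
})

test_that("training is reproducible under a fixed seed and config", {
  set.seed(66)
  hp <- hazard_model_params(alpha = -2)
  coh <- tiny_imaging_cohort(10, hp, hw = 16, Z = 6, n_slices = 2L, seed = 4)
  cfg <- dsn_config(initial_lr = 1e-3, max_epochs = 3L, seed = 12)
  f1 <- pira_dsn(coh$stacks[1:8], coh$labels[1:8, ],
                 coh$stacks[9:10], coh$labels[9:10, ], config = cfg)
  f2 <- pira_dsn(coh$stacks[1:8], coh$labels[1:8, ],
                 coh$stacks[9:10], coh$labels[9:10, ], config = cfg)
  expect_identical(f1$net$params, f2$net$params)
  expect_identical(f1$log, f2$log)
})
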