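test_that("Kaplan-Meier handles ties and reduces to 1-ECDF without censoring", {
  # hand product-limit: censor at 1, events at 2 (x2), event at 3
  km <- kaplan_meier(c(1, 2, 2, 3), c(0, 1, 1, 1))
  expect_equal(km_surv_at(km, 2), 1 / 3)
  expect_equal(km_surv_at(km, 3), 0)
  expect_equal(km_surv_at(km, 0.5), 1)

  # no events: flat at 1
  km <- kaplan_meier(c(1, 2, 3), c(0, 0, 0))
  expect_equal(km$surv, rep(1, 3))

  # no censoring: equals the empirical survival fraction at every time
  set.seed(5)
  t <- sample(1:8, 40, TRUE)
  km <- kaplan_meier(t, rep(1, 40))
  for (u in 1:8) expect_equal(km_surv_at(km, u), mean(t > u))

  # cross-check against the survival package on censored data
  set.seed(6)
  t <- sample(1:6, 30, TRUE); d <- rbinom(30, 1, 0.6)
  km <- kaplan_meier(t, d)
  sf <- survival::survfit(survival::Surv(t, d) ~ 1)
  expect_equal(km_surv_at(km, sf$time), sf$surv, tolerance = 1e-12)
})

test_that("time-dependent concordance matches brute-force pair enumeration", {
  # fully consistent ordering scores 1, reversal scores 0, ties 0.5
  F <- matrix(rep(c(0.9, 0.5, 0.1), 11), 3)
  expect_equal(td_cindex(F, c(2, 4, 5), c(1, 1, 0)), 1)
  expect_equal(td_cindex(1 - F, c(2, 4, 5), c(1, 1, 0)), 0)
  expect_equal(td_cindex(matrix(0.3, 3, 11), c(2, 4, 5), c(1, 1, 0)), 0.5)
  expect_warning(out <- td_cindex(F, c(3, 3, 3), c(1, 1, 1)),
                 "comparable")
  expect_true(is.na(out))

  set.seed(77)
  for (rep in 1:200) {
    n <- sample(5:30, 1)
    K <- 6
    F <- t(apply(matrix(runif(n * K), n), 1, function(x) cumsum(x) / (sum(x) + 1)))
    if (rep %% 3 == 0) F[sample(n, 2), ] <- F[1, ] # inject prediction ties
    k <- sample.int(K, n, TRUE)
    d <- rbinom(n, 1, 0.5)
    got <- suppressWarnings(td_cindex(F, k, d))
    want <- bf_td_cindex(F, k, d)
    expect_equal(got, want)
  }
})

test_that("Brier scores use Graf censoring weights and reduce cleanly", {
  # perfect predictions, no censoring -> 0
  k <- c(1L, 2L, 4L); d <- c(1L, 1L, 0L)
  S <- matrix(1, 3, 4)
  S[1, 1:4] <- 0; S[2, 2:4] <- 0
  expect_equal(brier_at(2, S, k, d), 0)
  # constant 0.5 prediction, no censoring -> 0.25 everywhere
  S5 <- matrix(0.5, 3, 4)
  expect_equal(brier_at(1, S5, k, d), 0.25)
  expect_equal(brier_at(3, S5, k, d), 0.25)

  # hand IPCW computation on a 4-patient set with one censored patient:
  # k = (1,2,2,3), d = (1,0,1,0); censor KM: G(1)=1, G(2)=G(3)=2/3.
  # BS(2): patient1 S^2/G(0)=.49; patient3 S^2/G(1)=.04; patient4 (1-S)^2/G(2)
  k <- c(1L, 2L, 2L, 3L); d <- c(1L, 0L, 1L, 0L)
  S <- matrix(c(0.7, 0.9, 0.2, 0.8,
                0.7, 0.8, 0.2, 0.6,
                0.6, 0.7, 0.1, 0.5), 4, 3)
  ckm <- kaplan_meier(k, 1L - d)
  expect_equal(km_surv_at(ckm, 1), 1)
  expect_equal(km_surv_at(ckm, 2), 2 / 3)
  hand <- (0.7^2 / 1 + 0.2^2 / 1 + (1 - 0.6)^2 / (2 / 3) + 0) / 4
  expect_equal(brier_at(2, S, k, d), hand)

  # all censored before k: undefined
  expect_warning(out <- brier_at(2, matrix(0.5, 2, 3), c(1L, 1L), c(0L, 0L)),
                 "undefined")
  expect_true(is.na(out))
})

test_that("integrated Brier score equals the per-interval average", {
  set.seed(12)
  for (rep in 1:20) {
    n <- sample(8:25, 1); K <- 5
    S <- t(apply(matrix(runif(n * K, 0.2, 1), n), 1, function(x) cumprod(x)))
    k <- sample.int(K, n, TRUE); d <- rbinom(n, 1, 0.6)
    ib <- integrated_brier(S, k, d)
    per <- vapply(1:K, function(j)
      suppressWarnings(brier_at(j, S, k, d)), numeric(1))
    expect_equal(ib$scores, per)
    expect_equal(ib$mean, mean(per, na.rm = TRUE))
    expect_equal(ib$sd, sd(per, na.rm = TRUE))
  }
  # perfect predictions, no censoring: mean 0, sd 0
  k <- c(1L, 3L); d <- c(1L, 1L)
  S <- rbind(c(0, 0, 0), c(1, 1, 0))
  ib <- integrated_brier(S, k, d)
  expect_equal(ib$mean, 0)
  expect_equal(ib$sd, 0)
})

test_that("non-informative Brier bound is p(1-p)", {
  expect_equal(noninformative_brier_bound(0.5), 0.25)
  expect_equal(noninformative_brier_bound(0.22), 0.1716)
  expect_equal(round(noninformative_brier_bound(0.22), 2), 0.17)
  expect_equal(noninformative_brier_bound(0), 0)
  p <- runif(10)
  expect_equal(noninformative_brier_bound(p), p * (1 - p))
})

test_that("ROC AUC equals the Mann-Whitney rank statistic", {
  r <- roc_auc(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1))
  expect_equal(r$auc, 1)
  expect_equal(roc_auc(rep(0.5, 6), c(0, 1, 0, 1, 0, 1))$auc, 0.5)
  expect_error(roc_auc(1:4, rep(1, 4)), class = "pirasurv_degenerate")

  mw_auc <- function(s, y) {
    pos <- s[y == 1]; neg <- s[y == 0]
    mean(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
  }
  set.seed(3)
  for (rep in 1:200) {
    n <- sample(6:40, 1)
    y <- c(0, 1, rbinom(n - 2, 1, 0.4))
    s <- round(runif(n), 2) # rounded scores produce ties
    expect_equal(roc_auc(s, y)$auc, mw_auc(s, y))
  }
})

test_that("joint AUC comparison behaves on identical, shifted and null scores", {
  set.seed(9)
  y <- rbinom(60, 1, 0.4)
  s <- runif(60)
  # identical columns: zero statistic, p = 1
  out <- compare_aucs(cbind(s, s, s), y)
  expect_equal(out$statistic, 0)
  expect_equal(out$p_value, 1)

  # strongly different columns: significant
  s2 <- ifelse(y == 1, s + 2, s)
  out2 <- compare_aucs(cbind(s, s2), y)
  expect_lt(out2$p_value, 0.01)
  expect_equal(out2$df, 1)

  # under the null (independent noise columns) p is not degenerate
  out3 <- compare_aucs(cbind(runif(60), runif(60)), y)
  expect_true(out3$p_value > 0 && out3$p_value <= 1)
  expect_error(compare_aucs(cbind(s, s2), rep(1, 60)),
               class = "pirasurv_degenerate")
})

test_that("Sidak correction matches its closed form", {
  expect_equal(sidak_adjust(0.05, 1), 0.05)
  expect_equal(sidak_adjust(0.01, 10), 1 - 0.99^10)
})

test_that("best-accuracy threshold equals an exhaustive scan", {
  out <- best_accuracy_threshold(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1))
  expect_equal(out$threshold, 0.8)
  expect_equal(out$accuracy, 1)

  # all positive: the minimum score classifies everything positive
  out <- best_accuracy_threshold(c(0.3, 0.5, 0.9), c(1, 1, 1))
  expect_equal(out$threshold, 0.3)
  expect_equal(out$accuracy, 1)

  # permutation invariance
  set.seed(14)
  s <- runif(30); y <- rbinom(30, 1, 0.3)
  a <- best_accuracy_threshold(s, y)
  p <- sample.int(30)
  b <- best_accuracy_threshold(s[p], y[p])
  expect_equal(a$threshold, b$threshold)
  expect_equal(a$accuracy, b$accuracy)

  # never below the majority classifier; matches exhaustive scan
  for (rep in 1:200) {
    n <- sample(4:25, 1)
    s <- round(runif(n), 1)
    y <- rbinom(n, 1, runif(1, 0.2, 0.8))
    if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
    out <- best_accuracy_threshold(s, y)
    accs <- vapply(c(sort(unique(s)), Inf), function(thr)
      mean((s >= thr) == y), numeric(1))
    expect_equal(out$accuracy, max(accs))
    expect_gte(out$accuracy, max(mean(y), 1 - mean(y)) - 1e-9)
  }
})

test_that("classification reports carry exact binomial intervals", {
  rep1 <- classification_report(tp = 15, fp = 13, fn = 43, tn = 188)
  expect_equal(rep1$sensitivity, 15 / 58)
  expect_equal(rep1$specificity, 188 / 201)
  expect_equal(rep1$accuracy, 203 / 259)
  # metrics are consistent with counts and CIs contain the estimates
  for (m in c("sensitivity", "specificity", "ppv", "npv", "accuracy")) {
    ci <- rep1$ci95[[m]]
    expect_true(ci[1] <= rep1[[m]] && rep1[[m]] <= ci[2])
  }
  # Clopper-Pearson closed form for 1 success out of 4
  rep2 <- classification_report(tp = 1, fp = 6, fn = 3, tn = 22)
  expect_equal(rep2$ci95$sensitivity[1], qbeta(0.025, 1, 4))
  expect_equal(rep2$ci95$sensitivity,
               as.numeric(binom.test(1, 4)$conf.int))
  # degenerate margins give NA metrics, perfect ones give 1
  rep3 <- classification_report(tp = 5, fp = 0, fn = 0, tn = 0)
  expect_equal(rep3$sensitivity, 1)
  expect_true(is.na(rep3$specificity))
  expect_error(classification_report(-1, 0, 0, 0),
               class = "pirasurv_bad_input")
})
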