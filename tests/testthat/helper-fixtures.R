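# shared fixtures: record builders and a memoised end-to-end training run
# (trained once per session; reused by the acceptance and relevance tests)

make_record <- function(times, edss, relapses = numeric(),
                        followup = max(times), id = "p1") {
  clinical_record(id, data.frame(time = times, edss = edss),
                  relapse_times = relapses, followup_end = followup)
}

.fixture_env <- new.env(parent = emptyenv())

# strong image-hazard coupling: the ventricle signal is visible in every
# axial slice and the lesion load adds patient-level risk; fixed seeds
strong_hazard_params <- function() {
  hazard_model_params(alpha = -7, beta_lesion = 0.8, beta_ventricle = 1.5)
}

strong_cohort <- function() {
  if (is.null(.fixture_env$cohort)) {
    .fixture_env$cohort <- simulate_imaging_cohort(
      300, strong_hazard_params(),
      phantom_params(image_size = c(64, 64, 12)),
      n_slices = 8L, seed = 11)
  }
  .fixture_env$cohort
}

# two fits with different weight seeds; their cumulative risks are
# ensemble-averaged at prediction time, mirroring the fold-ensemble protocol
strong_fits <- function() {
  if (is.null(.fixture_env$fits)) {
    coh <- strong_cohort()
    .fixture_env$fits <- lapply(c(5, 6), function(s)
      pira_dsn(coh$stacks[1:200], coh$labels[1:200, ],
               config = dsn_config(initial_lr = 1e-3, max_epochs = 15L,
                                   seed = s)))
  }
  .fixture_env$fits
}

strong_fit <- function() strong_fits()[[1L]]

strong_test_cumrisk <- function() {
  if (is.null(.fixture_env$cumrisk)) {
    coh <- strong_cohort()
    .fixture_env$cumrisk <- ensemble_average(
      lapply(strong_fits(), predict, coh$stacks[201:300], type = "cumrisk"))
  }
  .fixture_env$cumrisk
}

# small imaging cohorts for fast tests: lesion geometry scaled down so
# disjoint placement stays feasible on tiny phantoms
tiny_imaging_cohort <- function(n, hp, hw = 16, Z = 6, n_slices = 2L,
                                seed = 1) {
  simulate_imaging_cohort(
    n, hp,
    phantom_params(image_size = c(hw, hw, Z), lesion_radius = 1.5),
    n_slices = n_slices, lesion_lambda = 1.5, lesion_max = 3L, seed = seed)
}

# brute-force oracles -------------------------------------------------------

bf_td_cindex <- function(F, k, d) {
  num <- 0; den <- 0
  n <- length(k)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (d[i] != 1L || !(k[i] < k[j])) next
    den <- den + 1
    if (F[i, k[i]] > F[j, k[i]]) num <- num + 1
    else if (F[i, k[i]] == F[j, k[i]]) num <- num + 0.5
  }
  if (den == 0) NA_real_ else num / den
}

bf_harrell_c <- function(lp, time, event) {
  num <- 0; den <- 0
  n <- length(time)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    if (event[i] == 1 && time[i] < time[j]) {
      den <- den + 1
      if (lp[i] > lp[j]) num <- num + 1
      else if (lp[i] == lp[j]) num <- num + 0.5
    }
  }
  num / den
}

# exact survivor by exhaustive enumeration of Bernoulli outcome sequences
bf_survivor_enum <- function(h) {
  K <- length(h)
  S <- numeric(K)
  grids <- as.matrix(expand.grid(rep(list(0:1), K)))
  prob <- apply(grids, 1, function(g) prod(ifelse(g == 1, h, 1 - h)))
  for (k in seq_len(K)) {
    alive <- apply(grids[, seq_len(k), drop = FALSE], 1,
                   function(g) all(g == 0))
    S[k] <- sum(prob[alive])
  }
  S
}
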