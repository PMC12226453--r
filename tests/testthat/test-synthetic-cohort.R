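test_that("labeller recovers injected PIRA ground truth exactly", {
  coh <- simulate_clinical_cohort(100, pira_fraction = 0.22, seed = 1)
  expect_equal(sum(coh$truth$pira), 22)
  for (i in seq_len(100)) {
    lab <- detect_pira(coh$records[[i]])
    expect_equal(lab$event, coh$truth$pira[i])
    if (lab$event) expect_equal(lab$onset_time, coh$truth$onset_time[i])
  }
})

test_that("a zero PIRA fraction yields zero detected events", {
  coh <- simulate_clinical_cohort(40, pira_fraction = 0, seed = 2)
  labs <- label_cohort(coh$records)
  expect_equal(sum(labs$event), 0L)
})

test_that("the clinical generator is reproducible under a seed", {
  a <- simulate_clinical_cohort(25, seed = 99)
  b <- simulate_clinical_cohort(25, seed = 99)
  expect_identical(a, b)
  expect_error(simulate_clinical_cohort(10, pira_fraction = 1.5),
               class = "pirasurv_bad_input")
})

test_that("injected events hit every CDW threshold band", {
  # baselines 0, 2 and a jittered cohort exercise 1.5- and 1.0-point bands
  coh <- simulate_clinical_cohort(200, pira_fraction = 0.5, seed = 7)
  refs <- coh$truth$baseline_edss[coh$truth$pira]
  expect_true(any(refs == 0))
  expect_true(any(refs > 0))
  for (i in which(coh$truth$pira)) {
    lab <- detect_pira(coh$records[[i]])
    expect_equal(lab$reference_edss, coh$truth$baseline_edss[i])
  }
})

test_that("phantom volumes have the advertised geometry", {
  # no lesions, no noise: clean two-tissue brain with empty lesion mask
  ph <- simulate_phantom_volume(
    phantom_params(lesion_count = 0, noise_sd = 0,
                   image_size = c(32, 32, 16)), seed = 1)
  expect_equal(sum(ph$lesion_mask), 0)
  expect_true(sum(ph$ventricle_mask) > 0)
  expect_true(all(ph$flair[!ph$brain_mask] == 0))
  # FLAIR contrast: lesions bright, ventricles dark
  expect_gt(mean(ph$flair[ph$brain_mask & !ph$ventricle_mask]),
            mean(ph$flair[ph$ventricle_mask]))

  # five lesions give exactly five disjoint connected components
  skip_if_not_installed("igraph")
  ph5 <- simulate_phantom_volume(
    phantom_params(lesion_count = 5, noise_sd = 0,
                   image_size = c(48, 48, 24)), seed = 4)
  vox <- which(ph5$lesion_mask, arr.ind = TRUE)
  n <- nrow(vox)
  adj <- which(as.matrix(dist(vox)) <= 1.01 &
                 upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  g <- igraph::graph_from_edgelist(adj, directed = FALSE)
  g <- igraph::add_vertices(g, n - igraph::vcount(g))
  expect_equal(igraph::count_components(g), 5)

  # determinism under seed
  a <- simulate_phantom_volume(phantom_params(lesion_count = 3,
                                              image_size = c(32, 32, 12)),
                               seed = 5)
  b <- simulate_phantom_volume(phantom_params(lesion_count = 3,
                                              image_size = c(32, 32, 12)),
                               seed = 5)
  expect_identical(a, b)
})

test_that("ventricle scale grows the ventricle mask", {
  p0 <- simulate_phantom_volume(phantom_params(ventricle_scale = 0,
                                               image_size = c(32, 32, 16),
                                               noise_sd = 0), seed = 1)
  p2 <- simulate_phantom_volume(phantom_params(ventricle_scale = 2,
                                               image_size = c(32, 32, 16),
                                               noise_sd = 0), seed = 1)
  expect_gt(sum(p2$ventricle_mask), sum(p0$ventricle_mask))
})

test_that("hazard cohort sampling follows the sequential Bernoulli law", {
  # P(event in interval 1) = h1; P(event in 2) = (1-h1) h2, etc.
  hp <- hazard_model_params(alpha = qlogis(seq(0.1, 0.2, length.out = 11)),
                            beta_lesion = 0, beta_ventricle = 0,
                            censor_rate = 0)
  coh <- simulate_hazard_cohort(40000, hp, seed = 21)
  h <- coh$hazards[1, ]
  p1 <- mean(coh$labels$interval == 1 & coh$labels$event == 1)
  p2 <- mean(coh$labels$interval == 2 & coh$labels$event == 1)
  expect_lt(abs(p1 - h[1]), 0.01)
  expect_lt(abs(p2 - (1 - h[1]) * h[2]), 0.01)
  # true survivor matches the closed-form product
  expect_equal(coh$survivor[1, ], cumprod(1 - h))
})

test_that("default hazard parameters give ~22% observed events at n = 2000", {
  coh <- simulate_hazard_cohort(2000, hazard_model_params(), seed = 8)
  expect_equal(mean(coh$labels$event), 0.22, tolerance = 0.02 / 0.22)
})

test_that("Kaplan-Meier on a large cohort matches the analytic mixture survivor", {
  hp <- hazard_model_params(censor_rate = 0.3)
  coh <- simulate_hazard_cohort(5000, hp, seed = 31)
  km <- kaplan_meier(coh$labels$interval, coh$labels$event)
  S_true <- colMeans(coh$survivor)
  S_km <- km_surv_at(km, seq_len(11))
  expect_lt(max(abs(S_km - S_true)), 0.02)
  expect_true(all(diff(S_km) <= 0))
})

test_that("imaging cohort couples image parameters to hazards deterministically", {
  hp <- hazard_model_params()
  a <- simulate_imaging_cohort(6, hp, phantom_params(image_size = c(32, 32, 12)),
                               n_slices = 4L, seed = 13)
  b <- simulate_imaging_cohort(6, hp, phantom_params(image_size = c(32, 32, 12)),
                               n_slices = 4L, seed = 13)
  expect_identical(a, b)
  expect_equal(length(a$stacks), 6)
  expect_equal(dim(a$stacks[[1]]), c(32, 32, 2, 4))
  expect_true(all(unlist(lapply(a$stacks, range)) >= 0))
  expect_true(all(unlist(lapply(a$stacks, range)) <= 1))
  # hazards reproduce the logistic link on the drawn covariates
  lp <- hp$alpha[1] + hp$beta_lesion * a$covariates$lesion_count +
    hp$beta_ventricle * a$covariates$ventricle_scale
  expect_equal(a$hazards[, 1], plogis(lp))
})
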