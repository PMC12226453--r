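#' Parameters of a two-channel brain phantom
#'
#' The phantom is a coarse anatomical stand-in: an ellipsoidal brain with
#' two ellipsoidal lateral ventricles (dark in both channels) and a number
#' of spherical white-matter lesions (bright on FLAIR, dark on T1). The
#' ventricle size acts as an atrophy surrogate and the lesion count as a
#' lesion-load surrogate; both can drive the synthetic hazard.
#'
#' @param ventricle_scale Non-negative real; ventricle ellipse axes scale as
#'   `base * (0.5 + 0.5 * ventricle_scale)`.
#' @param lesion_count Integer >= 0.
#' @param lesion_radius Lesion radius in voxels (default 2.5).
#' @param image_size Volume dimensions `c(H, W, Z)` (default 64 x 64 x 48).
#' @param noise_sd Standard deviation of additive Gaussian noise
#'   (default 0.02); intensities are clipped at 0 afterwards.
#' @return An object of class `phantom_params`.
#' @export
phantom_params <- function(ventricle_scale = 1, lesion_count = 0,
                           lesion_radius = 2.5,
                           image_size = c(64, 64, 48), noise_sd = 0.02) {
  stopifnot(ventricle_scale >= 0, lesion_count >= 0, lesion_radius > 0,
            length(image_size) == 3, all(image_size >= 4), noise_sd >= 0)
  structure(list(ventricle_scale = ventricle_scale,
                 lesion_count = as.integer(lesion_count),
                 lesion_radius = lesion_radius,
                 image_size = as.integer(image_size),
                 noise_sd = noise_sd),
            class = "phantom_params")
}

# tissue intensities (arbitrary units, before noise)
.phantom_levels <- list(
  flair = c(background = 0, brain = 0.55, ventricle = 0.12, lesion = 0.95),
  t1    = c(background = 0, brain = 0.70, ventricle = 0.15, lesion = 0.35))

# ellipsoid mask on normalized [-1, 1]^3 coordinates
.ellipsoid <- function(xs, ys, zs, centre, axes) {
  q <- outer(outer((xs - centre[1])^2 / axes[1]^2,
                   (ys - centre[2])^2 / axes[2]^2, `+`),
             (zs - centre[3])^2 / axes[3]^2, `+`)
  q <= 1
}

#' Simulate a two-channel brain-phantom volume
#'
#' @param params A [phantom_params()].
#' @param seed Optional integer seed (noise and lesion placement).
#' @param max_tries Bounded retries for disjoint lesion placement; exceeding
#'   them raises an error.
#' @return A list of class `phantom_volume` with 3D arrays `t1`, `flair`,
#'   logical masks `brain_mask`, `ventricle_mask`, `lesion_mask`, the
#'   lesion `centres` (voxel indices) and `params`.
#' @examples
#' ph <- simulate_phantom_volume(
#'   phantom_params(lesion_count = 3, image_size = c(32, 32, 16)), seed = 1)
#' @export
simulate_phantom_volume <- function(params = phantom_params(), seed = NULL,
                                    max_tries = 500L) {
  stopifnot(inherits(params, "phantom_params"))
  if (!is.null(seed)) set.seed(seed)
  d <- params$image_size
  xs <- seq(-1, 1, length.out = d[1])
  ys <- seq(-1, 1, length.out = d[2])
  zs <- seq(-1, 1, length.out = d[3])

  brain <- .ellipsoid(xs, ys, zs, c(0, 0, 0), c(0.85, 0.95, 0.90))
  vfac <- 0.5 + 0.5 * params$ventricle_scale
  vax <- c(0.10, 0.28, 0.40) * vfac
  vent <- .ellipsoid(xs, ys, zs, c(-0.20, 0, 0), vax) |
    .ellipsoid(xs, ys, zs, c(0.20, 0, 0), vax)
  vent <- vent & brain

  # lesion placement: centres inside the brain (with margin), outside the
  # ventricles, pairwise-disjoint spheres
  lesion <- array(FALSE, d)
  centres <- matrix(numeric(0), 0, 3)
  r <- params$lesion_radius
  if (params$lesion_count > 0) {
    margin <- .ellipsoid(xs, ys, zs, c(0, 0, 0),
                         c(0.85, 0.95, 0.90) * 0.8) & !vent
    # keep a safety shell around the ventricles
    vent_shell <- .ellipsoid(xs, ys, zs, c(-0.20, 0, 0), vax * 1.4) |
      .ellipsoid(xs, ys, zs, c(0.20, 0, 0), vax * 1.4)
    allowed <- which(margin & !vent_shell, arr.ind = TRUE)
    if (nrow(allowed) == 0)
      stop_pirasurv("no room to place lesions", "pirasurv_placement")
    tries <- 0L
    while (nrow(centres) < params$lesion_count) {
      tries <- tries + 1L
      if (tries > max_tries)
        stop_pirasurv("lesion placement failed after bounded retries",
                      "pirasurv_placement")
      cand <- allowed[sample.int(nrow(allowed), 1L), ]
      if (nrow(centres) > 0) {
        dist2 <- rowSums(sweep(centres, 2, cand)^2)
        if (any(dist2 <= (2 * r + 1)^2)) next
      }
      centres <- rbind(centres, cand)
    }
    for (i in seq_len(nrow(centres))) {
      c0 <- centres[i, ]
      rng <- lapply(1:3, function(a)
        max(1, floor(c0[a] - r)):min(d[a], ceiling(c0[a] + r)))
      for (ix in rng[[1]]) for (iy in rng[[2]]) for (iz in rng[[3]]) {
        if ((ix - c0[1])^2 + (iy - c0[2])^2 + (iz - c0[3])^2 <= r^2)
          lesion[ix, iy, iz] <- TRUE
      }
    }
    lesion <- lesion & brain
  }

  compose <- function(lv) {
    v <- array(lv[["background"]], d)
    v[brain] <- lv[["brain"]]
    v[vent] <- lv[["ventricle"]]
    v[lesion] <- lv[["lesion"]]
    if (params$noise_sd > 0)
      v <- v + array(rnorm(prod(d), sd = params$noise_sd), d)
    pmax(v, 0)
  }
  structure(list(t1 = compose(.phantom_levels$t1),
                 flair = compose(.phantom_levels$flair),
                 brain_mask = brain, ventricle_mask = vent,
                 lesion_mask = lesion, centres = centres, params = params),
            class = "phantom_volume")
}

#' Parameters of the synthetic discrete-time hazard model
#'
#' The generative counterpart of the survival network: per-interval hazards
#' are `plogis(alpha_j + beta_lesion * lesions + beta_ventricle * vscale)`.
#' The default constant `alpha` was Monte-Carlo calibrated so that, with the
#' default covariate distributions and censoring, the observed event
#' fraction is approximately 0.22.
#'
#' @param alpha Per-interval baseline log-odds (length 1 is recycled to the
#'   grid length).
#' @param beta_lesion,beta_ventricle Log-odds per lesion / per unit of
#'   ventricle scale.
#' @param censor_rate Probability that a patient receives a random
#'   (uniform over intervals) censoring time instead of the administrative
#'   end-of-grid censoring.
#' @param n_intervals Grid length (default 11).
#' @return Object of class `hazard_model_params`.
#' @export
hazard_model_params <- function(alpha = -5.23, beta_lesion = 0.25,
                                beta_ventricle = 0.5, censor_rate = 0.3,
                                n_intervals = 11L) {
  alpha <- rep_len(alpha, n_intervals)
  stopifnot(censor_rate >= 0, censor_rate <= 1)
  structure(list(alpha = alpha, beta_lesion = beta_lesion,
                 beta_ventricle = beta_ventricle,
                 censor_rate = censor_rate,
                 n_intervals = as.integer(n_intervals)),
            class = "hazard_model_params")
}

#' Simulate discrete survival labels from known per-patient hazards
#'
#' Draws per-patient covariates (lesion count ~ Poisson, ventricle scale ~
#' uniform), forms hazards through the logistic link, samples the event
#' interval sequentially (first interval whose Bernoulli trial succeeds)
#' and applies independent censoring: with probability `censor_rate` a
#' uniform censoring interval in `1..K`, otherwise administrative censoring
#' at the end of the grid.
#'
#' @param n Number of patients.
#' @param hparams A [hazard_model_params()].
#' @param lesion_lambda Mean of the Poisson lesion count.
#' @param ventricle_range Range of the uniform ventricle scale.
#' @param lesion_max Cap on the drawn lesion count (default 12).
#' @param seed Optional integer seed.
#' @return A list with `labels` (data.frame `interval`, `event`),
#'   `covariates` (data.frame `lesion_count`, `ventricle_scale`),
#'   `hazards` (n x K matrix) and `survivor` (n x K matrix of true curves).
#' @export
simulate_hazard_cohort <- function(n, hparams = hazard_model_params(),
                                   lesion_lambda = 4,
                                   ventricle_range = c(0, 2),
                                   lesion_max = 12L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  K <- hparams$n_intervals
  lesions <- pmin(rpois(n, lesion_lambda), lesion_max)
  vscale <- runif(n, ventricle_range[1], ventricle_range[2])
  lp <- outer(hparams$beta_lesion * lesions +
                hparams$beta_ventricle * vscale, rep(1, K)) +
    matrix(hparams$alpha, n, K, byrow = TRUE)
  h <- plogis(lp)
  if (any(h <= 0 | h >= 1))
    stop_pirasurv("hazards must lie in (0, 1)", "pirasurv_bad_input")

  u <- matrix(runif(n * K), n, K)
  hit <- u < h
  ev_int <- apply(hit, 1L, function(z) if (any(z)) which(z)[1L] else NA_integer_)
  cens <- ifelse(runif(n) < hparams$censor_rate,
                 sample.int(K, n, replace = TRUE), K)
  event <- !is.na(ev_int) & ev_int <= cens
  interval <- ifelse(event, ev_int, cens)

  list(labels = data.frame(interval = as.integer(interval),
                           event = as.integer(event)),
       covariates = data.frame(lesion_count = lesions,
                               ventricle_scale = vscale),
       hazards = h, survivor = hazard_to_survivor(h))
}

#' Simulate an imaging cohort: phantoms plus discrete survival labels
#'
#' Couples [simulate_hazard_cohort()] covariates to [simulate_phantom_volume()]
#' images: each patient's lesion count and ventricle scale both render the
#' phantom and set the discrete-time hazard, giving an exact ground truth
#' for end-to-end recovery tests of the survival network.
#'
#' @param n Number of patients.
#' @param hparams A [hazard_model_params()].
#' @param phantom A [phantom_params()] template (its `lesion_count` and
#'   `ventricle_scale` are overridden per patient).
#' @param n_slices If non-`NULL`, volumes are immediately reduced to
#'   normalized central slice stacks of this depth (memory-friendly); set
#'   `NULL` to keep full `phantom_volume` objects.
#' @param lesion_lambda,ventricle_range Covariate distributions, as in
#'   [simulate_hazard_cohort()].
#' @param lesion_max Cap on the drawn lesion count (default 12; lower it
#'   for small phantoms where disjoint placement is tight).
#' @param seed Integer seed.
#' @return A list with `stacks` (list of slice stacks) or `volumes`,
#'   `labels`, `covariates`, `hazards`, `survivor` as in
#'   [simulate_hazard_cohort()].
#' @export
simulate_imaging_cohort <- function(n, hparams = hazard_model_params(),
                                    phantom = phantom_params(),
                                    n_slices = 8L, lesion_lambda = 4,
                                    ventricle_range = c(0, 2),
                                    lesion_max = 12L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  base <- simulate_hazard_cohort(n, hparams, lesion_lambda, ventricle_range,
                                 lesion_max = lesion_max)
  out <- base
  imgs <- vector("list", n)
  for (i in seq_len(n)) {
    p <- phantom
    p$lesion_count <- base$covariates$lesion_count[i]
    p$ventricle_scale <- base$covariates$ventricle_scale[i]
    ph <- simulate_phantom_volume(p)
    imgs[[i]] <- if (is.null(n_slices)) ph else
      central_slices(volume_pair(ph$t1, ph$flair), n = n_slices)
  }
  if (is.null(n_slices)) out$volumes <- imgs else out$stacks <- imgs
  out
}
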