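#' Simulate a clinical cohort with known PIRA ground truth
#'
#' Generates per-patient visit schedules, EDSS trajectories (quantised to
#' 0.5 steps), relapses from a Poisson process with transient post-relapse
#' EDSS bumps, and — for a fixed fraction of patients — a sustained
#' disability ramp starting inside a relapse-free window, so that the PIRA
#' labeller has an exact ground truth to recover. Trajectories are
#' noise-free by default (the labeller's fixture tests are exact); an
#' optional jitter mode perturbs non-anchored visits by ±0.5 EDSS for
#' robustness experiments.
#'
#' Defaults mirror an early-MS first-attack cohort: ~22% of patients reach
#' PIRA, annualised relapse rate 0.25/y, administrative follow-up drawn
#' uniformly from 4–12 years, baseline EDSS centred near 1.5.
#'
#' @param n Number of patients.
#' @param pira_fraction Fraction of patients receiving an injected PIRA
#'   event (`round(n * pira_fraction)` patients, default 0.22).
#' @param relapse_rate Poisson relapse rate per year (default 0.25).
#' @param followup_range Administrative follow-up range in years.
#' @param edss_jitter If `TRUE`, adds ±0.5 jitter to visits that are not
#'   PIRA anchors (default `FALSE`).
#' @param seed Integer seed; the same seed reproduces the cohort exactly.
#' @return A list with `records` (list of [clinical_record()]) and `truth`
#'   (data.frame: `patient_id`, `pira`, `onset_time`, `followup_end`,
#'   `baseline_edss`).
#' @examples
#' coh <- simulate_clinical_cohort(20, seed = 1)
#' sum(coh$truth$pira)
#' @export
simulate_clinical_cohort <- function(n, pira_fraction = 0.22,
                                     relapse_rate = 0.25,
                                     followup_range = c(4, 12),
                                     edss_jitter = FALSE, seed = NULL) {
  stopifnot(n >= 1)
  if (pira_fraction < 0 || pira_fraction > 1)
    stop_pirasurv("pira_fraction must be in [0, 1]", "pirasurv_bad_input")
  if (!is.null(seed)) set.seed(seed)
  n_pira <- round(n * pira_fraction)
  pira_ids <- sample.int(n, n_pira)

  records <- vector("list", n)
  truth <- data.frame(patient_id = sprintf("syn%04d", seq_len(n)),
                      pira = FALSE, onset_time = NA_real_,
                      followup_end = NA_real_, baseline_edss = NA_real_)

  edss_levels <- seq(0, 4.5, by = 0.5)
  edss_probs <- c(2, 4, 8, 12, 10, 8, 6, 4, 2, 1) # mode near 1.5-2.0

  for (i in seq_len(n)) {
    fe <- runif(1, followup_range[1], followup_range[2])
    baseline <- sample(edss_levels, 1L, prob = edss_probs)
    # relapses: homogeneous Poisson on [0.6, fe); none in the first 6 months
    # so the 6-month reference visit is never caught in a post-relapse bump
    nrel <- rpois(1L, relapse_rate * fe)
    relapses <- sort(runif(nrel, 0.6, fe))

    is_pira <- i %in% pira_ids
    onset <- NA_real_
    if (is_pira) {
      # rounded to the same 1e-6 grid as the visit schedule so the onset
      # anchor visit matches exactly
      onset <- round(runif(1, 1.0, fe - 1.0), 6)
      # PIRA patients stop relapsing from shortly before onset, so the
      # onset sits in a relapse-free period reaching the end of follow-up;
      # the 0.75 y gap leaves room for a pre-onset re-baseline visit
      relapses <- relapses[relapses < onset - 0.75]
    }

    # visit schedule: first attack, the 6-month reference visit, then
    # roughly 6-12-monthly; post-relapse check visits inside the 3-month
    # exclusion window carry a transient EDSS bump
    times <- c(0, 0.5)
    cur <- 0.5
    repeat {
      cur <- cur + runif(1, 0.5, 1)
      if (cur > fe - 1e-3) break
      times <- c(times, cur)
    }
    bump_times <- relapses + 0.1 # inside (r, r + 0.25)
    bump_times <- bump_times[bump_times < fe]
    times <- c(times, bump_times)
    # PIRA anchors: a re-baseline visit before onset (so the reference
    # resets to baseline EDSS, not onto the ramp), the onset itself and a
    # confirmation visit 6 months later
    if (is_pira) times <- c(times, onset - 0.25, onset, onset + 0.5)
    times <- sort(unique(round(times, 6)))
    # enforce strict increase (collisions are vanishingly rare but possible)
    times <- times[c(TRUE, diff(times) > 1e-6)]

    edss <- rep(baseline, length(times))
    for (r in relapses) {
      bump <- times > r & times < r + 0.25
      edss[bump] <- pmin(10, baseline + 1)
    }
    anchored <- rep(FALSE, length(times))
    if (is_pira) {
      thr <- cdw_threshold(baseline)
      ramp <- times >= onset - 1e-9
      edss[ramp] <- pmin(10, baseline + thr)
      anchored <- ramp | times <= 0.5 + 1e-9 |
        abs(times - (onset - 0.25)) < 1e-9
    } else {
      anchored <- times <= 0.5 + 1e-9
    }
    if (edss_jitter) {
      free <- which(!anchored)
      jit <- sample(c(-0.5, 0, 0.5), length(free), replace = TRUE)
      edss[free] <- pmin(10, pmax(0, edss[free] + jit))
    }

    records[[i]] <- clinical_record(
      truth$patient_id[i],
      visits = data.frame(time = times, edss = edss),
      relapse_times = relapses, followup_end = fe)
    truth$pira[i] <- is_pira
    truth$onset_time[i] <- onset
    truth$followup_end[i] <- fe
    truth$baseline_edss[i] <- baseline
  }
  names(records) <- truth$patient_id
  list(records = records, truth = truth)
}
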