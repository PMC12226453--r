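test_that("relapse-free periods apply the 3-month/6-month window rules", {
  # no relapses: single period from 6 months to end of follow-up
  rec <- make_record(c(0, 1), c(1, 1), followup = 5)
  p <- relapse_free_periods(rec)
  expect_equal(p, data.frame(start = 0.5, end = 5))

  # close relapses: the in-between period is empty and dropped
  rec <- make_record(c(0, 0.5), c(2, 1), relapses = c(1.0, 1.1), followup = 3)
  p <- relapse_free_periods(rec)
  expect_equal(p$start, c(0.5, 1.35))
  expect_equal(p$end, c(1.0, 3.0))

  # single relapse splits follow-up with a 3-month exclusion
  rec <- make_record(c(0, 1), c(1, 1), relapses = 2, followup = 5)
  p <- relapse_free_periods(rec)
  expect_equal(p$start, c(0.5, 2.25))
  expect_equal(p$end, c(2, 5))

  # periods are disjoint and sorted
  expect_true(all(diff(as.vector(t(as.matrix(p)))) >= 0))
})

test_that("reference EDSS re-baselines after relapses and is floored", {
  # the reference is the first EDSS at >= 6 months, not the first visit
  rec <- make_record(c(0.1, 0.5), c(2.0, 1.0), followup = 5)
  s <- reference_edss_series(rec)
  expect_equal(ref_edss_at(s, c(0.5, 2, 5)), c(1, 1, 1))

  # floor: re-baseline EDSS below the 6-month score is pulled up to it
  rec <- make_record(c(0.5, 2.3, 3), c(1.5, 1.0, 1.0), relapses = 2,
                     followup = 5)
  s <- reference_edss_series(rec)
  expect_equal(ref_edss_at(s, 2.5), 1.5)

  # re-baseline above the floor is kept
  rec <- make_record(c(0.5, 2.3, 3), c(1.5, 2.5, 2.5), relapses = 2,
                     followup = 5)
  expect_equal(ref_edss_at(reference_edss_series(rec), 2.5), 2.5)

  # single qualifying visit: constant reference
  rec <- make_record(0.5, 3, followup = 2)
  expect_equal(ref_edss_at(reference_edss_series(rec), c(0.5, 2)), c(3, 3))

  # no visit at or after 6 months: unlabelable
  rec <- make_record(c(0, 0.3), c(1, 1), followup = 0.4)
  expect_error(reference_edss_series(rec), class = "pirasurv_unlabelable")
})

test_that("CDW threshold follows the 1.5/1.0/0.5 reference bands", {
  expect_equal(cdw_threshold(0), 1.5)
  expect_equal(cdw_threshold(3.0), 1.0)
  expect_equal(cdw_threshold(6.0), 0.5)
  expect_equal(cdw_threshold(c(1, 5, 5.5)), c(1.0, 1.0, 0.5))
  # the 0.5 reference is a definitional gap: 1.0 by default, configurable
  expect_equal(cdw_threshold(0.5), 1.0)
  expect_equal(cdw_threshold(0.5, ref05_increase = 1.5), 1.5)
})

test_that("detect_pira finds confirmed worsening in relapse-free periods", {
  # reference 0: a sustained rise to 1.5 qualifies
  rec <- make_record(c(0.5, 1.2, 1.8, 2.5), c(0, 1.5, 1.5, 1.5),
                     followup = 5)
  lab <- detect_pira(rec)
  expect_true(lab$event)
  expect_equal(lab$onset_time, 1.2)
  expect_equal(lab$reference_edss, 0)
  expect_equal(lab$confirmed_at, 1.8)

  # flat EDSS: censored at end of follow-up
  rec <- make_record(c(0.5, 1.5, 3), c(1, 1, 1), followup = 5)
  lab <- detect_pira(rec)
  expect_false(lab$event)
  expect_equal(lab$time, 5)

  # worsening inside the post-relapse exclusion window does not count
  rec <- make_record(c(0.42, 0.5, 1.0, 2.0), c(3, 1, 1, 1),
                     relapses = 0.33, followup = 5)
  expect_false(detect_pira(rec)$event)

  # a relapse between onset and confirmation voids the event
  rec <- make_record(c(0.5, 1.2, 1.8, 2.5), c(0, 1.5, 1.5, 1.5),
                     relapses = 1.5, followup = 5)
  expect_false(detect_pira(rec)$event)

  # an unsustained rise (intermediate visit back at reference) is not CDW
  rec <- make_record(c(0.5, 1.2, 1.5, 1.8), c(1, 2, 1, 2), followup = 5)
  expect_false(detect_pira(rec)$event)

  # no confirmation visit 6 months later: censored
  rec <- make_record(c(0.5, 1.2), c(1, 2.5), followup = 1.4)
  expect_false(detect_pira(rec)$event)
})

test_that("detect_pira is deterministic and onsets lie in relapse-free periods", {
  coh <- simulate_clinical_cohort(60, seed = 42)
  labs1 <- lapply(coh$records, detect_pira)
  labs2 <- lapply(coh$records, detect_pira)
  expect_identical(labs1, labs2)
  for (i in seq_along(labs1)) {
    if (!labs1[[i]]$event) next
    p <- relapse_free_periods(coh$records[[i]])
    t0 <- labs1[[i]]$onset_time
    expect_true(any(t0 >= p$start & t0 < p$end))
  }
})

test_that("extending follow-up never removes an event; shortening censors it", {
  rec <- make_record(c(0.5, 1.2, 1.8, 2.5), c(0, 1.5, 1.5, 1.5),
                     followup = 5)
  lab <- detect_pira(rec)
  expect_true(lab$event)
  longer <- clinical_record("p1", rec$visits, rec$relapse_times, 9)
  lab2 <- detect_pira(longer)
  expect_true(lab2$event)
  expect_equal(lab2$onset_time, lab$onset_time)
  # truncating visits below the onset removes the event
  short <- make_record(c(0.5, 1.0), c(0, 0), followup = 1.1)
  expect_false(detect_pira(short)$event)
})

test_that("PDDS variant requires a 1-point rise with no self-reported relapse", {
  expect_true(pdds_pira(0, 1, FALSE))
  expect_false(pdds_pira(2, 2, FALSE))
  expect_false(pdds_pira(0, 3, TRUE))
  expect_equal(pdds_pira(c(0, 1), c(2, 1), c(FALSE, FALSE)), c(TRUE, FALSE))
  expect_error(pdds_pira(9, 1, FALSE), class = "pirasurv_bad_input")
})

test_that("PDDS cohort tables are labelled row-wise", {
  df <- data.frame(patient_id = c("a", "b", "c"),
                   baseline_pdds = c(0, 2, 0), last_pdds = c(1, 2, 3),
                   relapse_in_window = c(FALSE, FALSE, TRUE))
  out <- pdds_label_table(df)
  expect_equal(out$pira, c(TRUE, FALSE, FALSE))
  f <- withr::local_tempfile(fileext = ".csv")
  write.csv(df, f, row.names = FALSE)
  expect_equal(pdds_label_table(f)$pira, out$pira)
  expect_error(pdds_label_table(df[, 1:3]), class = "pirasurv_bad_input")
})

test_that("discrete labels clamp to the 11-interval yearly grid", {
  expect_equal(to_discrete_label(4.2, TRUE),
               data.frame(interval = 4L, event = 1L))
  expect_equal(to_discrete_label(0.8, FALSE),
               data.frame(interval = 1L, event = 0L))
  expect_equal(to_discrete_label(12.7, FALSE),
               data.frame(interval = 11L, event = 0L))
  # events past the grid are kept by default, censored when configured
  expect_equal(to_discrete_label(12.7, TRUE)$event, 1L)
  expect_equal(to_discrete_label(12.7, TRUE, late_events = "censor")$event, 0L)
  # interval boundaries are half-open [k, k+1)
  expect_equal(to_discrete_label(c(1, 1.999, 2), c(1, 1, 1))$interval,
               c(1L, 1L, 2L))
  expect_error(to_discrete_label(-1, TRUE), class = "pirasurv_bad_input")
})

test_that("clinical tables round-trip through CSV", {
  coh <- simulate_clinical_cohort(8, seed = 3)
  dir <- withr::local_tempdir()
  write_clinical_tables(coh$records, dir)
  back <- read_clinical_tables(file.path(dir, "visits.csv"),
                               file.path(dir, "cohort.csv"),
                               file.path(dir, "relapses.csv"))
  expect_equal(length(back), length(coh$records))
  l1 <- label_cohort(coh$records)
  l2 <- label_cohort(back)
  expect_equal(l1, l2)
})
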