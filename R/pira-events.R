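#' Relapse-free periods of a clinical record
#'
#' A relapse-free period starts 3 months (0.25 y) after a relapse — or 6
#' months (0.5 y) after the first attack for the initial period — and ends
#' at the next relapse (half-open `[start, end)`) or at the end of
#' follow-up. Empty periods (e.g. two relapses less than 3 months apart)
#' are dropped. A relapse at exactly time `t` closes the running period at
#' `t`, so a visit at `t` falls outside it.
#'
#' @param record A [clinical_record()].
#' @return A data.frame with columns `start`, `end` (years), possibly with
#'   zero rows.
#' @examples
#' rec <- clinical_record("p", data.frame(time = 0, edss = 1),
#'                        relapse_times = 2, followup_end = 5)
#' relapse_free_periods(rec) # [0.5, 2) and [2.25, 5)
#' @export
relapse_free_periods <- function(record) {
  stopifnot(inherits(record, "clinical_record"))
  rel <- record$relapse_times
  starts <- c(0.5, rel + 0.25)
  ends <- c(rel, record$followup_end)
  keep <- starts < ends
  data.frame(start = starts[keep], end = ends[keep])
}

#' Reference (re-baseline) EDSS as a step function of time
#'
#' The reference EDSS is the comparator against which disability worsening
#' is judged. It is the first EDSS obtained at least 6 months after the
#' first attack; after every relapse it re-baselines to the EDSS of the
#' first visit at least 3 months after that relapse. It can never fall
#' below the very first EDSS recorded at least 6 months after the first
#' attack (the global floor).
#'
#' @param record A [clinical_record()].
#' @return An object of class `reference_edss` with breakpoint times,
#'   values, the floor, and the domain `[0.5, followup_end]`. Evaluate it
#'   with [ref_edss_at()].
#' @export
reference_edss_series <- function(record) {
  stopifnot(inherits(record, "clinical_record"))
  v <- record$visits
  first6 <- which(v$time >= 0.5)
  if (!length(first6))
    stop_pirasurv(
      sprintf("record %s has no visit at or after 6 months: unlabelable",
              record$patient_id),
      "pirasurv_unlabelable")
  floor_edss <- v$edss[first6[1L]]
  times <- 0.5
  values <- floor_edss
  for (r in record$relapse_times) {
    i <- which(v$time >= r + 0.25)
    if (!length(i)) next # no visit after the exclusion window: keep last ref
    t_new <- v$time[i[1L]]
    val <- max(floor_edss, v$edss[i[1L]])
    # a later relapse re-baselining at the same (or earlier) visit supersedes
    keep <- times < t_new
    times <- c(times[keep], t_new)
    values <- c(values[keep], val)
  }
  structure(list(times = times, values = values, floor = floor_edss,
                 domain = c(0.5, record$followup_end)),
            class = "reference_edss")
}

#' Evaluate a reference-EDSS step function
#'
#' @param series A [reference_edss_series()] result.
#' @param t Numeric vector of times in years (must be `>= 0.5`).
#' @return Reference EDSS values at `t` (right-continuous step function).
#' @export
ref_edss_at <- function(series, t) {
  stopifnot(inherits(series, "reference_edss"))
  if (any(t < series$domain[1] - 1e-9))
    stop_pirasurv("reference EDSS is undefined before 0.5 years",
                  "pirasurv_bad_input")
  idx <- findInterval(t, series$times)
  series$values[pmax(idx, 1L)]
}

#' Minimum EDSS increase that qualifies as disability worsening
#'
#' The confirmed-disability-worsening (CDW) threshold depends on the
#' reference EDSS: an increase of 1.5 points is required from a reference
#' of 0, 1.0 point from references in (0, 5.0], and 0.5 points above 5.0.
#' A reference of exactly 0.5 sits in a band the clinical definition does
#' not spell out; by default it is treated like the (0, 5.0] band
#' (1.0 point), configurable via `ref05_increase`.
#'
#' @param reference Numeric vector of reference EDSS values.
#' @param ref05_increase Required increase when the reference is exactly
#'   0.5 (default 1.0).
#' @return Numeric vector of minimum increases in EDSS points.
#' @examples
#' cdw_threshold(c(0, 3, 6)) # 1.5, 1.0, 0.5
#' @export
cdw_threshold <- function(reference, ref05_increase = 1.0) {
  stopifnot(all(reference >= 0 & reference <= 10))
  out <- ifelse(reference == 0, 1.5, ifelse(reference > 5, 0.5, 1.0))
  out[reference == 0.5] <- ref05_increase
  out
}

#' Detect the first PIRA event in a clinical record
#'
#' A PIRA event is a 6-month confirmed disability worsening occurring in a
#' relapse-free period: a visit whose EDSS exceeds the reference EDSS by at
#' least the CDW threshold, sustained at every subsequent visit up to and
#' including a confirmation visit at least 6 months (0.5 y) later, with no
#' relapse between onset and confirmation. The first such onset is
#' returned; otherwise the record is censored at the end of follow-up.
#'
#' @param record A [clinical_record()].
#' @param confirm_gap Minimum onset-to-confirmation gap in years
#'   (default 0.5, i.e. 6 months on a 365.25-day year).
#' @param ref05_increase Passed to [cdw_threshold()].
#' @return A list of class `pira_label` with elements `event` (logical),
#'   `time` (onset time if event, else `followup_end`), and for events
#'   `onset_time`, `reference_edss`, `confirmed_at`.
#' @export
detect_pira <- function(record, confirm_gap = 0.5, ref05_increase = 1.0) {
  stopifnot(inherits(record, "clinical_record"))
  series <- reference_edss_series(record) # may signal unlabelable
  periods <- relapse_free_periods(record)
  v <- record$visits
  rel <- record$relapse_times
  tol <- 1e-9

  in_period <- function(t) {
    nrow(periods) > 0L &&
      any(t >= periods$start - tol & t < periods$end - tol)
  }

  for (i in seq_len(nrow(v))) {
    t0 <- v$time[i]
    if (t0 < 0.5 - tol || !in_period(t0)) next
    ref <- ref_edss_at(series, t0)
    thr <- cdw_threshold(ref, ref05_increase)
    if (v$edss[i] < ref + thr - tol) next
    # candidate onset: confirmation is the first visit >= t0 + confirm_gap
    conf_idx <- which(v$time >= t0 + confirm_gap - tol)
    if (!length(conf_idx)) next
    j <- conf_idx[1L]
    between <- which(v$time > t0 + tol & v$time <= v$time[j] + tol)
    sustained <- all(v$edss[between] >= ref + thr - tol)
    relapse_free <- !any(rel >= t0 - tol & rel <= v$time[j] + tol)
    if (sustained && relapse_free) {
      return(structure(list(event = TRUE, time = t0, onset_time = t0,
                            reference_edss = ref, confirmed_at = v$time[j]),
                       class = "pira_label"))
    }
  }
  structure(list(event = FALSE, time = record$followup_end),
            class = "pira_label")
}

#' @export
print.pira_label <- function(x, ...) {
  if (x$event)
    cat(sprintf("PIRA event: onset %.2f y (ref EDSS %.1f, confirmed %.2f y)\n",
                x$onset_time, x$reference_edss, x$confirmed_at))
  else
    cat(sprintf("Censored at %.2f y (no PIRA)\n", x$time))
  invisible(x)
}

#' PDDS-based PIRA flag for patient-reported cohorts
#'
#' External cohorts assessed on the Patient Determined Disease Steps carry
#' no exact relapse dates, so PIRA is approximated as an increase of at
#' least 1 PDDS point between baseline and last follow-up with no
#' self-reported relapse in that window.
#'
#' @param baseline_pdds,last_pdds PDDS scores, integers in 0..8.
#' @param relapse_in_window Logical: any self-reported relapse between the
#'   two assessments.
#' @return Logical vector.
#' @examples
#' pdds_pira(0, 1, FALSE) # TRUE
#' pdds_pira(0, 3, TRUE)  # FALSE: relapse exclusion
#' @export
pdds_pira <- function(baseline_pdds, last_pdds, relapse_in_window) {
  ok <- function(x) all(x >= 0 & x <= 8 & is_wholeish(x))
  if (!ok(baseline_pdds) || !ok(last_pdds))
    stop_pirasurv("PDDS scores must be integers in 0..8",
                  "pirasurv_bad_input")
  (last_pdds - baseline_pdds >= 1) & !as.logical(relapse_in_window)
}

#' Apply the PDDS-based PIRA flag to a cohort table
#'
#' Reads (or takes) a table with columns `patient_id`, `baseline_pdds`,
#' `last_pdds`, `relapse_in_window` and applies [pdds_pira()] row-wise.
#'
#' @param x A data.frame, or the path of a CSV with that schema.
#' @return The table with an added logical `pira` column.
#' @export
pdds_label_table <- function(x) {
  df <- if (is.character(x)) read.csv(x) else x
  need <- c("patient_id", "baseline_pdds", "last_pdds", "relapse_in_window")
  if (!all(need %in% names(df)))
    stop_pirasurv(sprintf("missing column(s): %s",
                          paste(setdiff(need, names(df)), collapse = ", ")),
                  "pirasurv_bad_input")
  df$pira <- pdds_pira(df$baseline_pdds, df$last_pdds, df$relapse_in_window)
  df
}

#' Label a cohort of clinical records with discrete survival outcomes
#'
#' Runs [detect_pira()] on every record and converts the event or censoring
#' time to the interval grid with [to_discrete_label()].
#'
#' @param records List of [clinical_record()] objects.
#' @param grid A [time_grid()].
#' @param ... Passed to [detect_pira()].
#' @return A data.frame with columns `patient_id`, `interval`, `event`,
#'   `event_time_years`.
#' @export
label_cohort <- function(records, grid = time_grid(), ...) {
  rows <- lapply(records, function(r) {
    lab <- detect_pira(r, ...)
    dl <- to_discrete_label(lab$time, lab$event, grid)
    data.frame(patient_id = r$patient_id, interval = dl$interval,
               event = dl$event, event_time_years = lab$time)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write cohort labels as CSV
#'
#' @param labels Data.frame from [label_cohort()].
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_labels_csv <- function(labels, path) {
  write.csv(labels, path, row.names = FALSE)
  invisible(path)
}
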