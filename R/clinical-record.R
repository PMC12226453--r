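#' Longitudinal clinical record of one patient
#'
#' Bundles one patient's visit history (EDSS at each visit), relapse dates
#' and follow-up horizon on a continuous time axis measured in years since
#' the first demyelinating attack.
#'
#' @param patient_id Character scalar identifier.
#' @param visits A data.frame with numeric columns `time` (years, strictly
#'   increasing, non-negative) and `edss` (multiples of 0.5 in `[0, 10]`).
#' @param relapse_times Numeric vector of relapse onset times, within
#'   `[0, followup_end]`.
#' @param followup_end Follow-up horizon in years; must be at least the last
#'   visit time.
#' @return An object of class `clinical_record`.
#' @examples
#' rec <- clinical_record("p1",
#'   visits = data.frame(time = c(0, 0.5, 1.5), edss = c(2, 1, 1)),
#'   relapse_times = numeric(), followup_end = 5)
#' @export
clinical_record <- function(patient_id, visits, relapse_times = numeric(),
                            followup_end) {
  stopifnot(is.character(patient_id), length(patient_id) == 1L,
            is.data.frame(visits), all(c("time", "edss") %in% names(visits)))
  visits <- visits[order(visits$time), c("time", "edss")]
  if (nrow(visits) == 0L)
    stop_pirasurv("record has no visits", "pirasurv_bad_input")
  if (any(visits$time < 0))
    stop_pirasurv("visit times must be non-negative", "pirasurv_bad_input")
  if (nrow(visits) > 1L && any(diff(visits$time) <= 0))
    stop_pirasurv("visit times must be strictly increasing",
                  "pirasurv_bad_input")
  bad_edss <- visits$edss < 0 | visits$edss > 10 |
    !is_wholeish(visits$edss * 2)
  if (any(bad_edss))
    stop_pirasurv("EDSS must be a multiple of 0.5 in [0, 10]",
                  "pirasurv_bad_input")
  if (followup_end < max(visits$time))
    stop_pirasurv("followup_end must be >= last visit time",
                  "pirasurv_bad_input")
  relapse_times <- sort(as.numeric(relapse_times))
  if (any(relapse_times < 0 | relapse_times > followup_end))
    stop_pirasurv("relapse times must lie in [0, followup_end]",
                  "pirasurv_bad_input")
  structure(
    list(patient_id = patient_id, visits = visits,
         relapse_times = relapse_times,
         followup_end = as.numeric(followup_end)),
    class = "clinical_record"
  )
}

#' @export
print.clinical_record <- function(x, ...) {
  cat(sprintf("Clinical record %s: %d visits, %d relapses, follow-up %.2f y\n",
              x$patient_id, nrow(x$visits), length(x$relapse_times),
              x$followup_end))
  invisible(x)
}

#' Read a cohort of clinical records from delimited text tables
#'
#' Expects the schemas: visits CSV (`patient_id`, `time_years`, `edss`),
#' relapses CSV (`patient_id`, `time_years`), cohort CSV (`patient_id`,
#' `followup_end_years`). All times are 0-based years since the first attack.
#'
#' @param visits_csv,relapses_csv,cohort_csv File paths. `relapses_csv` may
#'   be `NULL` when no relapses were recorded.
#' @return A named list of [clinical_record()] objects.
#' @export
read_clinical_tables <- function(visits_csv, cohort_csv, relapses_csv = NULL) {
  visits <- read.csv(visits_csv)
  cohort <- read.csv(cohort_csv)
  relapses <- if (is.null(relapses_csv)) {
    data.frame(patient_id = character(), time_years = numeric())
  } else read.csv(relapses_csv)
  stopifnot(all(c("patient_id", "time_years", "edss") %in% names(visits)),
            all(c("patient_id", "followup_end_years") %in% names(cohort)))
  recs <- lapply(seq_len(nrow(cohort)), function(i) {
    id <- as.character(cohort$patient_id[i])
    v <- visits[visits$patient_id == id, ]
    clinical_record(
      id,
      visits = data.frame(time = v$time_years, edss = v$edss),
      relapse_times = relapses$time_years[relapses$patient_id == id],
      followup_end = cohort$followup_end_years[i]
    )
  })
  names(recs) <- as.character(cohort$patient_id)
  recs
}

#' Write a cohort of clinical records as delimited text tables
#'
#' Inverse of [read_clinical_tables()]; writes the three CSV schemas into
#' `dir` as `visits.csv`, `relapses.csv` and `cohort.csv`.
#'
#' @param records List of [clinical_record()] objects.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the three file paths.
#' @export
write_clinical_tables <- function(records, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  visits <- do.call(rbind, lapply(records, function(r)
    data.frame(patient_id = r$patient_id, time_years = r$visits$time,
               edss = r$visits$edss)))
  relapses <- do.call(rbind, lapply(records, function(r)
    if (length(r$relapse_times))
      data.frame(patient_id = r$patient_id, time_years = r$relapse_times)))
  if (is.null(relapses))
    relapses <- data.frame(patient_id = character(), time_years = numeric())
  cohort <- do.call(rbind, lapply(records, function(r)
    data.frame(patient_id = r$patient_id,
               followup_end_years = r$followup_end)))
  paths <- file.path(dir, c("visits.csv", "relapses.csv", "cohort.csv"))
  write.csv(visits, paths[1], row.names = FALSE)
  write.csv(relapses, paths[2], row.names = FALSE)
  write.csv(cohort, paths[3], row.names = FALSE)
  invisible(paths)
}
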