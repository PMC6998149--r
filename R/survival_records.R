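#' Convert outcome records to time-to-flare survival records
#'
#' Builds `(time, event)` pairs for Kaplan-Meier / log-rank input: flared
#' subjects contribute their exact `flare_week` as an event; non-flared
#' subjects are censored at `dropout_week` (last contact) or at `end_week`.
#' The week-24 dropout-as-flare imputation is deliberately *not* applied here
#' (it belongs to the week-24 remission rate only); the dropout is censored.
#'
#' Records whose flares are only interval-coded (`flare_week` missing while a
#' flare interval is present, as in [trial_outcome_fixture()]) are refused:
#' fabricating event times would be invented data.
#'
#' @param records Outcome records (see [remission_rate()]), with a
#'   `flare_week` column for flared subjects.
#' @param end_week Administrative censoring time (default 24).
#' @return Tibble `subject_id`, `group` (arm), `time`, `event`.
#' @export
as_survival_records <- function(records, end_week = 24) {
  records <- validate_outcomes(records)
  flared <- !is.na(records$flare_by)
  if (!"flare_week" %in% names(records)) records$flare_week <- NA_real_
  no_time <- flared & is.na(records$flare_week)
  if (any(no_time)) {
    abort(sprintf(
      paste("Subject(s) %s have interval-coded flares without an exact week;",
            "refusing to fabricate event times for survival analysis."),
      paste(records$subject_id[no_time], collapse = ", ")
    ))
  }
  tibble(
    subject_id = records$subject_id,
    group = records$arm,
    time = ifelse(flared, records$flare_week,
                  pmin(dplyr::coalesce(records$dropout_week, end_week), end_week)),
    event = flared
  )
}
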