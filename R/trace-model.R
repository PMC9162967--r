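#' Construct an oximetry trace
#'
#' One channel's timestamped tissue-saturation series for a single patient,
#' together with the event markers (surgical incision, end of surgery) that
#' bound the intraoperative analysis window. Times are decimal minutes from
#' induction of anaesthesia; values are saturation in percent.
#'
#' Missing samples are represented as gaps in the time grid, never as
#' sentinel values; downstream burden integration applies a configurable
#' maximum-gap tolerance.
#'
#' @param channel one of `"renal_left"`, `"renal_right"`, `"renal_mean"`,
#'   `"cerebral"`, `"peripheral"`.
#' @param times numeric, strictly increasing, minutes from induction.
#' @param values numeric, same length as `times`, percent saturation in
#'   `[0, 100]`.
#' @param incision_time,end_time event times in minutes; must satisfy
#'   `incision_time < end_time`.
#' @return an object of class `oximetry_trace`.
#' @examples
#' tr <- oximetry_trace("cerebral", times = 0:60, values = rep(65, 61),
#'                      incision_time = 10, end_time = 55)
#' @export
oximetry_trace <- function(channel, times, values, incision_time, end_time) {
  channel <- match.arg(channel, OXI_CHANNELS)
  times <- as.numeric(times)
  values <- as.numeric(values)
  x <- structure(
    list(channel = channel, times = times, values = values,
         incision_time = as.numeric(incision_time),
         end_time = as.numeric(end_time)),
    class = "oximetry_trace")
  validate_trace(x)
}

#' Validate an oximetry trace
#'
#' Checks the trace invariants: strictly increasing times, saturations in
#' `[0, 100]` with no missing values, and `incision_time < end_time`.
#'
#' @param x an `oximetry_trace`.
#' @return `x`, invisibly unchanged, or an error describing the violation.
#' @export
validate_trace <- function(x) {
  stopifnot(inherits(x, "oximetry_trace"))
  if (length(x$times) == 0L)
    stop("trace '", x$channel, "': no samples", call. = FALSE)
  if (length(x$times) != length(x$values))
    stop("trace '", x$channel, "': times and values differ in length",
         call. = FALSE)
  if (anyNA(x$times) || anyNA(x$values))
    stop("trace '", x$channel,
         "': NA timestamps/values are not allowed; drop missing samples",
         call. = FALSE)
  if (length(x$times) > 1L && any(diff(x$times) <= 0))
    stop("trace '", x$channel, "': times must be strictly increasing",
         call. = FALSE)
  if (any(x$values < 0 | x$values > 100))
    stop("trace '", x$channel, "': saturation values outside [0, 100]",
         call. = FALSE)
  if (!is.finite(x$incision_time) || !is.finite(x$end_time) ||
      x$incision_time >= x$end_time)
    stop("trace '", x$channel, "': need incision_time < end_time",
         call. = FALSE)
  x
}

#' @export
print.oximetry_trace <- function(x, ...) {
  cat(sprintf(
    "<oximetry_trace> %s: %d samples over [%.1f, %.1f] min; incision %.1f, end %.1f\n",
    x$channel, length(x$times), x$times[1], x$times[length(x$times)],
    x$incision_time, x$end_time))
  invisible(x)
}

#' Construct a serum-creatinine series
#'
#' A single preoperative baseline concentration plus postoperative daily
#' values (days 1-7), all in micromol per litre.
#'
#' @param baseline_value preoperative creatinine, > 0.
#' @param days integer days since surgery, each in 1..7.
#' @param values creatinine concentrations matching `days`.
#' @return an object of class `creatinine_series`.
#' @export
creatinine_series <- function(baseline_value, days = integer(), values = numeric()) {
  baseline_value <- as.numeric(baseline_value)
  days <- as.integer(days)
  values <- as.numeric(values)
  if (!is.finite(baseline_value) || baseline_value <= 0)
    stop("creatinine baseline must be a positive number", call. = FALSE)
  if (length(days) != length(values))
    stop("creatinine days and values differ in length", call. = FALSE)
  if (anyNA(days) || anyNA(values))
    stop("creatinine series contains missing entries", call. = FALSE)
  if (any(days < 1L | days > 7L))
    stop("postoperative creatinine days must lie in 1..7", call. = FALSE)
  if (anyDuplicated(days))
    stop("duplicate postoperative creatinine days", call. = FALSE)
  if (any(values <= 0))
    stop("creatinine values must be positive", call. = FALSE)
  o <- order(days)
  structure(
    list(baseline_value = baseline_value,
         postop = data.frame(day = days[o], value = values[o])),
    class = "creatinine_series")
}

#' Construct a patient record
#'
#' Bundles all oximetry channels, the creatinine series and clinical
#' covariates for one subject.
#'
#' @param patient_id character scalar identifier.
#' @param traces named list of [oximetry_trace()] objects; names must equal
#'   each trace's channel and each channel may appear at most once.
#' @param creatinine a [creatinine_series()].
#' @param arm `"on_pump"` or `"off_pump"`.
#' @param covariates named list of scalar covariates (e.g. `duration_min`,
#'   `n_grafts`, `age`).
#' @return an object of class `patient_record`.
#' @export
patient_record <- function(patient_id, traces, creatinine, arm,
                           covariates = list()) {
  arm <- match.arg(arm, c("on_pump", "off_pump"))
  patient_id <- as.character(patient_id)
  if (length(patient_id) != 1L || is.na(patient_id) || !nzchar(patient_id))
    stop("patient_id must be a non-empty string", call. = FALSE)
  if (!is.list(traces) || length(traces) == 0L)
    stop("patient ", patient_id, ": at least one oximetry trace required",
         call. = FALSE)
  chans <- vapply(traces, function(tr) {
    validate_trace(tr)
    tr$channel
  }, character(1))
  if (anyDuplicated(chans))
    stop("patient ", patient_id, ": duplicate channel '",
         chans[duplicated(chans)][1], "'", call. = FALSE)
  names(traces) <- chans
  if (!inherits(creatinine, "creatinine_series"))
    stop("patient ", patient_id, ": creatinine must be a creatinine_series",
         call. = FALSE)
  structure(
    list(patient_id = patient_id, traces = traces, creatinine = creatinine,
         arm = arm, covariates = covariates),
    class = "patient_record")
}

#' @export
print.patient_record <- function(x, ...) {
  cat(sprintf("<patient_record> %s (%s): channels %s; %d postop creatinine days\n",
              x$patient_id, x$arm, paste(names(x$traces), collapse = ", "),
              nrow(x$creatinine$postop)))
  invisible(x)
}

renal_channels <- function(record)
  intersect(c("renal_left", "renal_right", "renal_mean"), names(record$traces))

trace_covers_window <- function(tr) {
  tr$times[1] <= tr$incision_time &&
    tr$times[length(tr$times)] >= tr$end_time
}

#' Partition a cohort into analysable and excluded records
#'
#' A record is excluded when it lacks every renal channel, lacks the
#' peripheral channel, or when no renal trace or the peripheral trace fails
#' to cover the intraoperative window `[incision_time, end_time]`. This is a
#' classification, not a failure: every input record is returned exactly
#' once, either in `analysable` or in `excluded` with a reason.
#'
#' @param records list of [patient_record()] objects.
#' @return list with elements `analysable` (list of records) and `excluded`
#'   (data.frame with columns `patient_id`, `reason`) plus the excluded
#'   records themselves in `excluded_records`.
#' @export
apply_exclusions <- function(records) {
  reasons <- vapply(records, function(rec) {
    rc <- renal_channels(rec)
    if (length(rc) == 0L) return("no renal data")
    if (!"peripheral" %in% names(rec$traces)) return("no peripheral data")
    if (!any(vapply(rec$traces[rc], trace_covers_window, logical(1))))
      return("insufficient renal data")
    if (!trace_covers_window(rec$traces$peripheral))
      return("insufficient peripheral data")
    ""
  }, character(1))
  keep <- reasons == ""
  list(
    analysable = records[keep],
    excluded = data.frame(
      patient_id = vapply(records[!keep], `[[`, character(1), "patient_id"),
      reason = reasons[!keep]),
    excluded_records = records[!keep])
}
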