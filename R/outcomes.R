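#' Label postoperative renal impairment from a creatinine series
#'
#' A patient is labelled impaired when the serum creatinine rises strictly
#' more than `threshold_frac` (default 10%) above the individual
#' preoperative baseline on any postoperative day within `window_days`
#' (default 7). A rise of exactly the threshold is not impairment, and
#' values outside the window are ignored. This relative-rise definition is
#' deliberately more sensitive than the KDIGO/AKIN/RIFLE acute-kidney-injury
#' stages, which it does not attempt to reproduce.
#'
#' @param series a [creatinine_series()].
#' @param threshold_frac relative-rise threshold as a fraction (0.10 = 10%).
#' @param window_days last postoperative day considered (1..7).
#' @return an `outcome_label`: `impaired` (logical), `max_relative_rise`,
#'   `day_of_max`.
#' @examples
#' s <- creatinine_series(84, days = c(1, 2), values = c(88, 93))
#' label_renal_impairment(s)  # 93/84 - 1 = 10.7% -> impaired
#' @export
label_renal_impairment <- function(series, threshold_frac = 0.10,
                                   window_days = 7) {
  stopifnot(inherits(series, "creatinine_series"))
  if (!is.finite(threshold_frac) || threshold_frac < 0)
    stop("threshold_frac must be non-negative", call. = FALSE)
  po <- series$postop[series$postop$day <= window_days, , drop = FALSE]
  if (nrow(po) == 0L)
    stop("no postoperative creatinine values within days 1..", window_days,
         "; patient cannot be labelled", call. = FALSE)
  rises <- po$value / series$baseline_value - 1
  i <- which.max(rises)
  # strict >: compare concentrations directly so that a rise of exactly
  # the threshold never labels a patient through rounding of the ratio
  impaired <- po$value[i] > series$baseline_value * (1 + threshold_frac)
  structure(list(impaired = impaired,
                 max_relative_rise = rises[i],
                 day_of_max = po$day[i]),
            class = "outcome_label")
}

#' @export
print.outcome_label <- function(x, ...) {
  cat(sprintf("<outcome_label> %s (max rise %.1f%% on day %d)\n",
              if (x$impaired) "impaired" else "not impaired",
              100 * x$max_relative_rise, x$day_of_max))
  invisible(x)
}

#' Label every patient in a cohort
#'
#' @param records list of [patient_record()]s.
#' @inheritParams label_renal_impairment
#' @return data.frame: `patient_id`, `impaired`, `max_relative_rise`,
#'   `day_of_max`.
#' @export
label_cohort <- function(records, threshold_frac = 0.10, window_days = 7) {
  rows <- lapply(records, function(rec) {
    lab <- label_renal_impairment(rec$creatinine, threshold_frac, window_days)
    data.frame(patient_id = rec$patient_id, impaired = lab$impaired,
               max_relative_rise = lab$max_relative_rise,
               day_of_max = lab$day_of_max)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
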