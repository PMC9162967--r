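# Cohort directory layout (documented in README):
#   <dir>/cohort.csv            one row per patient: patient_id, arm,
#                               incision_min, end_min, creat_baseline,
#                               creat_d1..creat_d7 (empty when unmeasured),
#                               plus one column per scalar covariate
#   <dir>/traces/<patient_id>.csv   long format: time_min, channel, value
# Comma-separated, dot decimal, mandatory header row, times in decimal
# minutes. Values are written with 15 significant digits so that a cohort
# round-trips exactly at that precision.

COHORT_FIXED_COLS <- c("patient_id", "arm", "incision_min", "end_min",
                       "creat_baseline", paste0("creat_d", 1:7))

fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "" else format(v, digits = 15, scientific = FALSE,
                                 trim = TRUE)
  }, character(1))
  out
}

#' Write a cohort to a directory of CSV files
#'
#' Inverse of [read_cohort()]: one long-format trace CSV per patient plus a
#' cohort-level CSV of events, creatinine and covariates.
#'
#' @param records list of [patient_record()] objects.
#' @param path output directory (created if absent).
#' @return `path`, invisibly.
#' @export
write_cohort <- function(records, path) {
  dir.create(file.path(path, "traces"), recursive = TRUE, showWarnings = FALSE)
  cov_names <- unique(unlist(lapply(records, function(r) names(r$covariates))))
  rows <- lapply(records, function(rec) {
    cr <- rep(NA_real_, 7)
    cr[rec$creatinine$postop$day] <- rec$creatinine$postop$value
    tr1 <- rec$traces[[1]]
    base <- c(list(patient_id = rec$patient_id, arm = rec$arm,
                   incision_min = tr1$incision_time, end_min = tr1$end_time,
                   creat_baseline = rec$creatinine$baseline_value),
              as.list(setNames(cr, paste0("creat_d", 1:7))))
    for (cn in cov_names)
      base[[cn]] <- if (is.null(rec$covariates[[cn]])) NA
                    else rec$covariates[[cn]]
    as.data.frame(base, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  num_cols <- setdiff(names(tab), c("patient_id", "arm"))
  for (cn in num_cols) tab[[cn]] <- fmt_num(as.numeric(tab[[cn]]))
  write.csv(tab, file.path(path, "cohort.csv"), row.names = FALSE,
            quote = FALSE, na = "")
  for (rec in records) {
    parts <- lapply(rec$traces, function(tr)
      data.frame(time_min = fmt_num(tr$times), channel = tr$channel,
                 value = fmt_num(tr$values)))
    write.csv(do.call(rbind, parts),
              file.path(path, "traces", paste0(rec$patient_id, ".csv")),
              row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Read a cohort from a directory of CSV files
#'
#' Reads the layout written by [write_cohort()]. Records that violate an
#' invariant (non-monotone times, saturations outside `[0, 100]`,
#' malformed numbers, missing creatinine) are returned in a `rejected`
#' table with a reason, never silently dropped. An unreadable `path` is a
#' fatal error.
#'
#' @param path cohort directory containing `cohort.csv` and `traces/`.
#' @return list with `records` (validated [patient_record()]s) and
#'   `rejected` (data.frame `patient_id`, `reason`).
#' @export
read_cohort <- function(path) {
  main <- file.path(path, "cohort.csv")
  if (!dir.exists(path) || !file.exists(main))
    stop("cohort path '", path, "' does not exist or lacks cohort.csv",
         call. = FALSE)
  tab <- read.csv(main, stringsAsFactors = FALSE, colClasses = "character")
  if (!all(c("patient_id", "arm", "incision_min", "end_min",
             "creat_baseline") %in% names(tab)))
    stop("cohort.csv is missing required columns", call. = FALSE)
  records <- list()
  rejected <- data.frame(patient_id = character(), reason = character())
  reject <- function(id, why)
    rejected <<- rbind(rejected, data.frame(patient_id = id, reason = why))

  num <- function(s) {
    s[!nzchar(s)] <- NA_character_
    suppressWarnings(as.numeric(s))
  }
  cov_cols <- setdiff(names(tab), COHORT_FIXED_COLS)

  for (i in seq_len(nrow(tab))) {
    id <- tab$patient_id[i]
    res <- tryCatch({
      tfile <- file.path(path, "traces", paste0(id, ".csv"))
      if (!file.exists(tfile)) stop("no trace file")
      tl <- read.csv(tfile, stringsAsFactors = FALSE,
                     colClasses = "character")
      if (!all(c("time_min", "channel", "value") %in% names(tl)))
        stop("trace file missing columns")
      tms <- num(tl$time_min); vals <- num(tl$value)
      if (anyNA(tms) || anyNA(vals)) stop("malformed timestamp or value")
      inc <- num(tab$incision_min[i]); end <- num(tab$end_min[i])
      traces <- lapply(split(seq_len(nrow(tl)), tl$channel), function(idx)
        oximetry_trace(tl$channel[idx[1]], tms[idx], vals[idx], inc, end))
      days <- which(!is.na(num(unlist(tab[i, paste0("creat_d", 1:7)]))))
      creat <- creatinine_series(
        num(tab$creat_baseline[i]), days,
        num(unlist(tab[i, paste0("creat_d", days)])))
      covs <- lapply(cov_cols, function(cn) num(tab[[cn]][i]))
      names(covs) <- cov_cols
      covs <- covs[!vapply(covs, is.na, logical(1))]
      patient_record(id, traces, creat, tab$arm[i], covs)
    }, error = function(e) conditionMessage(e))
    if (is.character(res)) reject(id, res) else records[[id]] <- res
  }
  list(records = records, rejected = rejected)
}
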