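# Area-under-threshold (AUT) desaturation burdens.
#
# All burdens are time integrals, in %·min, of the positive part of a
# deficit signal over the intraoperative window [incision_time, end_time].
# Two integration rules are provided:
#   * "trapezoid" (default): clipped trapezoid on the piecewise-linear
#     interpolant, with exact handling of threshold crossings inside a
#     sample interval;
#   * "rectangle": the deficit at the left sample is held constant over the
#     interval, i.e. the literal reading of
#     AUT = (threshold - current saturation) x time.
# Sample gaps longer than `gap_tol` contribute zero burden; the total
# within-window gap time is reported alongside each burden.

# Merged time intervals over which consecutive samples are closer than
# gap_tol; isolated samples yield no coverage.
.coverage <- function(times, gap_tol) {
  n <- length(times)
  if (n < 2L) return(matrix(numeric(0), ncol = 2))
  ok <- diff(times) <= gap_tol
  if (!any(ok)) return(matrix(numeric(0), ncol = 2))
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  cbind(times[starts[keep]], times[ends[keep] + 1L])
}

.intersect_window <- function(iv, w0, w1) {
  if (nrow(iv) == 0L) return(iv)
  a <- pmax(iv[, 1], w0); b <- pmin(iv[, 2], w1)
  keep <- b > a
  cbind(a[keep], b[keep])
}

# Integral of max(d(t), 0) over disjoint intervals, d defined by linear
# interpolation ("trapezoid") or left-sample hold ("rectangle") on
# (times, d).
.pos_area <- function(times, d, intervals, method = c("trapezoid", "rectangle")) {
  method <- match.arg(method)
  if (nrow(intervals) == 0L) return(0)
  total <- 0
  n <- length(times)
  for (k in seq_len(nrow(intervals))) {
    a <- intervals[k, 1]; b <- intervals[k, 2]
    inner <- times[times > a & times < b]
    bp <- c(a, inner, b)
    u <- bp[-length(bp)]; v <- bp[-1]
    len <- v - u
    if (method == "rectangle") {
      j <- pmin(pmax(findInterval(u, times), 1L), n)
      total <- total + sum(pmax(d[j], 0) * len)
    } else {
      du <- approx(times, d, xout = u)$y
      dv <- approx(times, d, xout = v)$y
      both_neg <- du <= 0 & dv <= 0
      both_pos <- du >= 0 & dv >= 0
      mixed <- !(both_neg | both_pos)
      total <- total + sum((du[both_pos] + dv[both_pos]) / 2 * len[both_pos])
      if (any(mixed)) {
        dp <- pmax(du[mixed], dv[mixed])
        dn <- pmin(du[mixed], dv[mixed])
        total <- total + sum(len[mixed] * dp^2 / (2 * (dp - dn)))
      }
    }
  }
  total
}

# Shared burden kernel: deficit series on a sample grid, window, gaps.
.burden_integral <- function(times, deficit, w0, w1, gap_tol, method) {
  if (!is.finite(w0) || !is.finite(w1) || w1 <= w0)
    stop("empty analysis window", call. = FALSE)
  iv <- .intersect_window(.coverage(times, gap_tol), w0, w1)
  aut <- .pos_area(times, deficit, iv, method)
  gap <- (w1 - w0) - sum(iv[, 2] - iv[, 1])
  list(aut = max(aut, 0), gap_min = max(gap, 0))
}

burden_result <- function(channel, kind, threshold, aut, gap_min, window) {
  structure(list(channel = channel, kind = kind, threshold = threshold,
                 aut = aut, gap_min = gap_min, window = window),
            class = "burden_result")
}

#' @export
print.burden_result <- function(x, ...) {
  thr <- if (is.na(x$threshold)) "" else
    sprintf(" thr=%s", format(x$threshold))
  cat(sprintf("<burden_result> %s/%s%s: AUT %.2f %%.min (gap %.1f min)\n",
              x$channel, x$kind, thr, x$aut, x$gap_min))
  invisible(x)
}

#' Baseline saturation from the pre-incision window
#'
#' The individual baseline is the arithmetic mean of all samples recorded
#' during the `window_min` minutes immediately preceding surgical incision
#' (default 5 min), after induction of anaesthesia.
#'
#' @param trace an [oximetry_trace()].
#' @param window_min baseline window length in minutes.
#' @return a `baseline_estimate`: channel, value (%), window, n_samples.
#' @export
compute_baseline <- function(trace, window_min = 5) {
  validate_trace(trace)
  w0 <- trace$incision_time - window_min
  sel <- trace$times >= w0 & trace$times < trace$incision_time
  if (!any(sel))
    stop("no samples in baseline window for channel '", trace$channel, "'",
         call. = FALSE)
  structure(list(channel = trace$channel, value = mean(trace$values[sel]),
                 window = c(w0, trace$incision_time),
                 n_samples = sum(sel)),
            class = "baseline_estimate")
}

#' @export
print.baseline_estimate <- function(x, ...) {
  cat(sprintf("<baseline_estimate> %s: %.1f%% (n=%d over [%.1f, %.1f) min)\n",
              x$channel, x$value, x$n_samples, x$window[1], x$window[2]))
  invisible(x)
}

#' Average bilateral renal traces
#'
#' At time points sampled on both sides the merged value is the mean of
#' left and right; at times sampled on one side only, that side's value is
#' used. The Spearman rank correlation of the paired samples is attached
#' for reporting (attribute `bilateral_correlation`).
#'
#' @param left,right `oximetry_trace`s for channels `renal_left` and
#'   `renal_right` with identical event times.
#' @return an `oximetry_trace` with channel `renal_mean`.
#' @export
merge_renal <- function(left, right) {
  validate_trace(left); validate_trace(right)
  if (left$incision_time != right$incision_time ||
      left$end_time != right$end_time)
    stop("left/right renal traces disagree on event times", call. = FALSE)
  if (left$times[length(left$times)] < right$times[1] ||
      right$times[length(right$times)] < left$times[1])
    stop("left and right renal traces have no overlapping samples",
         call. = FALSE)
  # match sample times at nanominute resolution
  key <- function(t) sprintf("%.9f", t)
  lk <- key(left$times); rk <- key(right$times)
  common <- intersect(lk, rk)
  if (length(common) == 0L)
    stop("left and right renal traces have no overlapping samples",
         call. = FALSE)
  li <- match(common, lk); ri <- match(common, rk)
  merged <- data.frame(
    t = c(left$times[li], left$times[-li], right$times[-ri]),
    v = c((left$values[li] + right$values[ri]) / 2,
          left$values[-li], right$values[-ri]))
  merged <- merged[order(merged$t), ]
  rho <- if (length(common) >= 3L)
    suppressWarnings(cor.test(left$values[li], right$values[ri],
                              method = "spearman", exact = FALSE))
  else NULL
  out <- oximetry_trace("renal_mean", merged$t, merged$v,
                        left$incision_time, left$end_time)
  attr(out, "bilateral_correlation") <- list(
    rho = if (is.null(rho)) NA_real_ else unname(rho$estimate),
    p_value = if (is.null(rho)) NA_real_ else rho$p.value,
    n_pairs = length(common))
  out
}

#' Absolute-threshold desaturation burden
#'
#' AUT below a fixed saturation level: the time integral of
#' `max(threshold - S(t), 0)` in %·min over the intraoperative window. The
#' conventional threshold set is 90, 80, 70, 60%.
#'
#' @param trace an [oximetry_trace()].
#' @param threshold absolute saturation threshold in percent, in (0, 100].
#' @param gap_tol maximum sample gap (min) still integrated; longer gaps
#'   contribute zero burden and are reported as `gap_min`.
#' @param method `"trapezoid"` (piecewise-linear, default) or
#'   `"rectangle"` (left-sample hold, the literal deficit-times-time rule).
#' @return a `burden_result`.
#' @export
aut_absolute <- function(trace, threshold, gap_tol = 2,
                         method = c("trapezoid", "rectangle")) {
  method <- match.arg(method)
  validate_trace(trace)
  if (!is.finite(threshold) || threshold <= 0 || threshold > 100)
    stop("absolute threshold must lie in (0, 100]", call. = FALSE)
  r <- .burden_integral(trace$times, threshold - trace$values,
                        trace$incision_time, trace$end_time, gap_tol, method)
  burden_result(trace$channel, "absolute", threshold, r$aut, r$gap_min,
                c(trace$incision_time, trace$end_time))
}

#' Baseline-relative desaturation burden
#'
#' AUT below a fraction of the individual baseline: the time integral of
#' `max((1 - frac) * baseline - S(t), 0)` in %·min. The conventional
#' fractions are 5, 10 and 15% below baseline.
#'
#' @param trace an [oximetry_trace()].
#' @param baseline a `baseline_estimate` from [compute_baseline()], or a
#'   numeric baseline saturation in percent.
#' @param frac fraction below baseline defining the threshold, in (0, 1).
#' @inheritParams aut_absolute
#' @return a `burden_result`.
#' @export
aut_relative <- function(trace, baseline, frac, gap_tol = 2,
                         method = c("trapezoid", "rectangle")) {
  method <- match.arg(method)
  validate_trace(trace)
  b <- if (inherits(baseline, "baseline_estimate")) baseline$value
       else as.numeric(baseline)
  if (!is.finite(b) || b <= 0) stop("baseline must be positive", call. = FALSE)
  if (!is.finite(frac) || frac <= 0 || frac >= 1)
    stop("frac must lie in (0, 1)", call. = FALSE)
  thr <- (1 - frac) * b
  r <- .burden_integral(trace$times, thr - trace$values,
                        trace$incision_time, trace$end_time, gap_tol, method)
  burden_result(trace$channel, "relative", frac, r$aut, r$gap_min,
                c(trace$incision_time, trace$end_time))
}

#' Renal-region-specific differential deoxygenation burden
#'
#' Both channels are renormalised so that the individual baseline equals
#' 100%. The differential deficit `d(t)` is the baseline-normalised
#' peripheral saturation minus the baseline-normalised renal saturation,
#' evaluated on the union of the two channels' sample grids; the burden is
#' the time integral of `max(d(t), 0)` in %·min — i.e. only epochs where
#' the renal region desaturates proportionally more than the periphery
#' accrue burden.
#'
#' @param renal,peripheral `oximetry_trace`s sharing event times.
#' @param renal_baseline,peripheral_baseline `baseline_estimate`s or
#'   numeric baselines (%); computed via [compute_baseline()] when `NULL`.
#' @inheritParams aut_absolute
#' @return a `burden_result` of kind `renal_specific`.
#' @export
renal_specific_burden <- function(renal, peripheral, renal_baseline = NULL,
                                  peripheral_baseline = NULL, gap_tol = 2,
                                  method = c("trapezoid", "rectangle")) {
  method <- match.arg(method)
  validate_trace(renal); validate_trace(peripheral)
  if (renal$incision_time != peripheral$incision_time ||
      renal$end_time != peripheral$end_time)
    stop("renal and peripheral traces disagree on event times", call. = FALSE)
  bval <- function(b, tr) {
    if (is.null(b)) b <- compute_baseline(tr)
    v <- if (inherits(b, "baseline_estimate")) b$value else as.numeric(b)
    if (!is.finite(v) || v <= 0)
      stop("baseline for channel '", tr$channel, "' must be positive",
           call. = FALSE)
    v
  }
  br <- bval(renal_baseline, renal)
  bp <- bval(peripheral_baseline, peripheral)
  w0 <- renal$incision_time; w1 <- renal$end_time
  grid <- sort(unique(c(renal$times, peripheral$times)))
  grid <- grid[grid >= w0 & grid <= w1]
  # restrict to times interpolable on both channels
  grid <- grid[grid >= max(renal$times[1], peripheral$times[1]) &
               grid <= min(renal$times[length(renal$times)],
                           peripheral$times[length(peripheral$times)])]
  if (length(grid) < 2L)
    stop("no overlapping intraoperative support for renal-specific burden",
         call. = FALSE)
  rn <- approx(renal$times, renal$values, xout = grid)$y * 100 / br
  pn <- approx(peripheral$times, peripheral$values, xout = grid)$y * 100 / bp
  d <- pn - rn
  iv <- .intersect_window(.coverage(renal$times, gap_tol), w0, w1)
  ivp <- .intersect_window(.coverage(peripheral$times, gap_tol), w0, w1)
  iv <- .interval_intersection(iv, ivp)
  iv <- .intersect_window(iv, grid[1], grid[length(grid)])
  aut <- .pos_area(grid, d, iv, method)
  gap <- (w1 - w0) - if (nrow(iv)) sum(iv[, 2] - iv[, 1]) else 0
  burden_result("renal_mean", "renal_specific", NA_real_, max(aut, 0),
                max(gap, 0), c(w0, w1))
}

# intersection of two sets of disjoint sorted intervals
.interval_intersection <- function(a, b) {
  if (nrow(a) == 0L || nrow(b) == 0L) return(matrix(numeric(0), ncol = 2))
  out <- NULL
  for (i in seq_len(nrow(a))) {
    lo <- pmax(a[i, 1], b[, 1]); hi <- pmin(a[i, 2], b[, 2])
    keep <- hi > lo
    if (any(keep)) out <- rbind(out, cbind(lo[keep], hi[keep]))
  }
  if (is.null(out)) matrix(numeric(0), ncol = 2) else out
}

#' Default burden-panel configuration
#'
#' @param gap_tol_min maximum integrable sample gap, minutes.
#' @param baseline_window_min baseline window length, minutes.
#' @param integration `"trapezoid"` or `"rectangle"`.
#' @param abs_thresholds absolute thresholds (%) for renal and cerebral.
#' @param rel_fracs relative fractions below baseline for renal/cerebral.
#' @param peripheral_rel_frac the single relative fraction used for the
#'   peripheral channel.
#' @return named list of configuration values.
#' @export
burden_config <- function(gap_tol_min = 2, baseline_window_min = 5,
                          integration = "trapezoid",
                          abs_thresholds = c(90, 80, 70, 60),
                          rel_fracs = c(0.05, 0.10, 0.15),
                          peripheral_rel_frac = 0.10) {
  list(gap_tol_min = gap_tol_min, baseline_window_min = baseline_window_min,
       integration = integration, abs_thresholds = abs_thresholds,
       rel_fracs = rel_fracs, peripheral_rel_frac = peripheral_rel_frac)
}

# Resolve the renal trace for a record: pre-merged mean, bilateral merge,
# or the single available side relabelled as renal_mean.
.resolve_renal <- function(record) {
  tr <- record$traces
  if (!is.null(tr$renal_mean)) return(tr$renal_mean)
  if (!is.null(tr$renal_left) && !is.null(tr$renal_right))
    return(merge_renal(tr$renal_left, tr$renal_right))
  side <- tr$renal_left %||% tr$renal_right
  if (is.null(side)) return(NULL)
  oximetry_trace("renal_mean", side$times, side$values,
                 side$incision_time, side$end_time)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Full desaturation-burden panel for one patient
#'
#' Computes, for the (possibly merged) renal channel and the cerebral
#' channel, the AUT at every configured absolute threshold and relative
#' fraction; for the peripheral channel, the single configured relative
#' burden; and the renal-region-specific differential burden. For a fully
#' populated record with the default configuration this yields 16 burdens.
#'
#' @param record an analysable [patient_record()].
#' @param config a [burden_config()].
#' @return data.frame with columns `patient_id`, `channel`, `kind`,
#'   `threshold`, `aut_pct_min`, `gap_min`; baselines (and the bilateral
#'   renal correlation, when computed) are attached as attributes
#'   `baselines` and `bilateral_correlation`.
#' @export
burden_panel <- function(record, config = burden_config()) {
  renal <- .resolve_renal(record)
  cerebral <- record$traces$cerebral
  peripheral <- record$traces$peripheral
  with_chan <- function(expr, chan)
    tryCatch(expr, error = function(e)
      stop("patient ", record$patient_id, ", channel ", chan, ": ",
           conditionMessage(e), call. = FALSE))
  rows <- list(); baselines <- list()
  add <- function(br) rows[[length(rows) + 1L]] <<- data.frame(
    patient_id = record$patient_id, channel = br$channel, kind = br$kind,
    threshold = br$threshold, aut_pct_min = br$aut, gap_min = br$gap_min)
  panel_for <- function(tr, abs_thr, rel_fr) {
    bl <- with_chan(compute_baseline(tr, config$baseline_window_min),
                    tr$channel)
    baselines[[tr$channel]] <<- bl
    for (thr in abs_thr)
      add(with_chan(aut_absolute(tr, thr, config$gap_tol_min,
                                 config$integration), tr$channel))
    for (fr in rel_fr)
      add(with_chan(aut_relative(tr, bl, fr, config$gap_tol_min,
                                 config$integration), tr$channel))
    bl
  }
  bl_renal <- if (!is.null(renal))
    panel_for(renal, config$abs_thresholds, config$rel_fracs)
  if (!is.null(cerebral))
    panel_for(cerebral, config$abs_thresholds, config$rel_fracs)
  bl_perip <- if (!is.null(peripheral))
    panel_for(peripheral, numeric(0), config$peripheral_rel_frac)
  if (!is.null(renal) && !is.null(peripheral))
    add(with_chan(renal_specific_burden(renal, peripheral, bl_renal,
                                        bl_perip, config$gap_tol_min,
                                        config$integration),
                  "renal_specific"))
  out <- do.call(rbind, rows)
  attr(out, "baselines") <- data.frame(
    channel = names(baselines),
    value = vapply(baselines, `[[`, numeric(1), "value"),
    n_samples = vapply(baselines, `[[`, numeric(1), "n_samples"),
    row.names = NULL)
  if (!is.null(renal) && !is.null(attr(renal, "bilateral_correlation")))
    attr(out, "bilateral_correlation") <- attr(renal, "bilateral_correlation")
  out
}

#' Per-patient predictor panel for ROC analysis
#'
#' One row per analysable patient with every candidate predictor of
#' postoperative renal impairment: the three channel baselines, the 16
#' burdens of [burden_panel()], and the preoperative creatinine.
#'
#' @param records list of analysable [patient_record()]s.
#' @param config a [burden_config()].
#' @return wide data.frame keyed by `patient_id`; missing channels yield
#'   `NA` predictors.
#' @export
build_predictor_panel <- function(records, config = burden_config()) {
  pct <- function(f) sprintf("%02d", round(100 * f))
  rows <- lapply(records, function(rec) {
    pan <- burden_panel(rec, config)
    bl <- attr(pan, "baselines")
    g <- function(chan, kind, thr) {
      i <- pan$channel == chan & pan$kind == kind &
        (is.na(thr) | (!is.na(pan$threshold) & pan$threshold == thr))
      if (any(i)) pan$aut_pct_min[which(i)[1]] else NA_real_
    }
    gb <- function(chan) {
      i <- bl$channel == chan
      if (any(i)) bl$value[which(i)[1]] else NA_real_
    }
    out <- list(patient_id = rec$patient_id,
                srt_baseline = gb("renal_mean"),
                sct_baseline = gb("cerebral"),
                spt_baseline = gb("peripheral"))
    for (thr in config$abs_thresholds) {
      out[[paste0("srt_abs_", thr)]] <- g("renal_mean", "absolute", thr)
      out[[paste0("sct_abs_", thr)]] <- g("cerebral", "absolute", thr)
    }
    for (fr in config$rel_fracs) {
      out[[paste0("srt_rel_", pct(fr))]] <- g("renal_mean", "relative", fr)
      out[[paste0("sct_rel_", pct(fr))]] <- g("cerebral", "relative", fr)
    }
    out[[paste0("spt_rel_", pct(config$peripheral_rel_frac))]] <-
      g("peripheral", "relative", config$peripheral_rel_frac)
    out$renal_specific <- g("renal_mean", "renal_specific", NA)
    out$preop_creatinine <- rec$creatinine$baseline_value
    as.data.frame(out)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
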