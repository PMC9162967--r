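# Independent oracles and fixture builders shared across tests.

# dense rectangle-rule integral (midpoint sampling, step dt) of
# max(threshold - S(t), 0) on the piecewise-linear interpolant of
# (times, values)
dense_aut <- function(times, values, threshold, w0, w1, dt = 0.001) {
  tt <- seq(w0, w1, by = dt)
  tt <- tt[tt < w1] + dt / 2
  s <- approx(times, values, xout = tt, rule = 2)$y
  sum(pmax(threshold - s, 0)) * dt
}

# dense rectangle-rule integral of the positive normalised differential
dense_renal_specific <- function(rt, rv, rb, pt, pv, pb, w0, w1, dt = 0.001) {
  tt <- seq(w0, w1, by = dt)
  tt <- tt[tt < w1] + dt / 2
  rn <- approx(rt, rv, xout = tt, rule = 2)$y * 100 / rb
  pn <- approx(pt, pv, xout = tt, rule = 2)$y * 100 / pb
  sum(pmax(pn - rn, 0)) * dt
}

# exhaustive pair-count AUROC with ties counted one half
pair_auroc <- function(x, y) {
  pos <- x[y]; neg <- x[!y]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# random piecewise-linear trace on an irregular grid covering its window
random_pl_trace <- function(channel = "renal_mean", n = 60,
                            lo = 55, hi = 100) {
  gaps <- runif(n - 1, 0.1, 1.5)
  times <- c(0, cumsum(gaps))
  values <- runif(n, lo, hi)
  w0 <- times[5]; w1 <- times[n - 4]
  oximetry_trace(channel, times, values, w0, w1)
}

make_flat_trace <- function(channel, value, incision = 20, end = 120,
                            by = 0.5, t0 = 0, t1 = end + 5) {
  tt <- seq(t0, t1, by = by)
  oximetry_trace(channel, tt, rep(value, length(tt)), incision, end)
}

make_creat <- function(baseline, values, days = seq_along(values)) {
  creatinine_series(baseline, days, values)
}

# minimal analysable record with flat traces at given channel levels
make_record <- function(id = "T001", renal = 80, cerebral = 65,
                        peripheral = 84, arm = "off_pump",
                        incision = 20, end = 120) {
  patient_record(
    id,
    list(make_flat_trace("renal_left", renal, incision, end),
         make_flat_trace("renal_right", renal, incision, end),
         make_flat_trace("cerebral", cerebral, incision, end),
         make_flat_trace("peripheral", peripheral, incision, end)),
    make_creat(84, c(85, 86)), arm,
    covariates = list(duration_min = end - incision, n_grafts = 3, age = 63))
}
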