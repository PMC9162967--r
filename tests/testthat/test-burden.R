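test_that("baseline is the mean of the pre-incision window", {
  expect_equal(compute_baseline(make_flat_trace("cerebral", 80))$value, 80)
  # two samples placed symmetrically in the window
  tr <- oximetry_trace("cerebral", c(16, 19, 25, 30), c(75, 85, 60, 60),
                       20, 30)
  bl <- compute_baseline(tr)
  expect_equal(bl$value, 80)
  expect_equal(bl$n_samples, 2L)
  expect_equal(bl$window, c(15, 20))
  # samples at or after incision are excluded from the window
  tr2 <- oximetry_trace("cerebral", c(16, 20, 25), c(75, 99, 60), 20, 25)
  expect_equal(compute_baseline(tr2)$value, 75)
  expect_error(compute_baseline(oximetry_trace("cerebral", 20:30,
                                               rep(60, 11), 20, 30)),
               "baseline window.*cerebral")
})

test_that("baseline estimate recovers a known generating mean", {
  set.seed(401)
  tt <- seq(15, 20 - 1 / 12, by = 1 / 12)  # 60 samples over 5 min
  tr <- oximetry_trace("renal_left", tt, pmin(rnorm(60, 82, 1), 100), 20, 40)
  expect_lt(abs(compute_baseline(tr)$value - 82), 0.5)  # 3 se of the mean
})

test_that("bilateral merge averages common samples and keeps singletons", {
  l <- make_flat_trace("renal_left", 80)
  r <- make_flat_trace("renal_right", 80)
  m <- merge_renal(l, r)
  expect_equal(m$channel, "renal_mean")
  expect_equal(m$values, l$values)
  expect_equal(attr(m, "bilateral_correlation")$n_pairs, length(l$times))

  r10 <- oximetry_trace("renal_right", l$times, l$values - 10,
                        l$incision_time, l$end_time)
  m2 <- merge_renal(l, r10)
  expect_equal(m2$values, l$values - 5)

  # one-sided samples pass through unaveraged
  l3 <- oximetry_trace("renal_left", c(0, 2, 4), c(80, 82, 84), 1, 3.5)
  r3 <- oximetry_trace("renal_right", c(0, 1, 4), c(70, 75, 74), 1, 3.5)
  m3 <- merge_renal(l3, r3)
  expect_equal(m3$times, c(0, 1, 2, 4))
  expect_equal(m3$values, c(75, 75, 82, 79))
  expect_error(
    merge_renal(oximetry_trace("renal_left", 0:5, rep(80, 6), 1, 4),
                oximetry_trace("renal_right", 10:15, rep(80, 6), 1, 4)),
    "no overlapping")
})

test_that("merge reports the rank correlation of a designed bilateral pair", {
  set.seed(402)
  n <- 200
  tt <- seq(0, by = 0.5, length.out = n)
  z <- rnorm(n)
  left <- 80 + 5 * (sqrt(0.81) * z + sqrt(1 - 0.81) * rnorm(n))
  right <- 80 + 5 * (sqrt(0.81) * z + sqrt(1 - 0.81) * rnorm(n))
  m <- merge_renal(
    oximetry_trace("renal_left", tt, pmin(pmax(left, 0), 100), 10, 90),
    oximetry_trace("renal_right", tt, pmin(pmax(right, 0), 100), 10, 90))
  rho <- attr(m, "bilateral_correlation")$rho
  expect_lt(abs(rho - 0.80), 0.10)
})

test_that("absolute AUT matches closed forms", {
  tr <- make_flat_trace("renal_mean", 85, incision = 20, end = 30)
  expect_equal(aut_absolute(tr, 90)$aut, 50)                # (90-85) x 10
  expect_equal(aut_absolute(tr, 90, method = "rectangle")$aut, 50)
  expect_equal(aut_absolute(make_flat_trace("renal_mean", 95), 90)$aut, 0)
  # linear ramp 90 -> 80 over 10 min: triangle area 50
  tt <- seq(20, 30, 0.5)
  ramp <- oximetry_trace("renal_mean", tt, seq(90, 80, length.out = 21),
                         20, 30)
  expect_equal(aut_absolute(ramp, 90)$aut, 50)
  expect_equal(aut_absolute(ramp, 90)$aut,
               dense_aut(tt, ramp$values, 90, 20, 30), tolerance = 1e-3)
  expect_error(aut_absolute(tr, 0), "threshold")
})

test_that("relative AUT matches the printed-formula closed forms", {
  tr <- oximetry_trace("peripheral", seq(10, 15, 0.5), rep(72, 11), 10, 15)
  expect_equal(aut_relative(tr, 80, 0.05)$aut, 20)  # (76-72) x 5
  expect_equal(aut_relative(tr, 80, 0.05, method = "rectangle")$aut, 20)
  # trace everywhere at/above the relative threshold
  expect_equal(aut_relative(make_flat_trace("peripheral", 80), 80, 0.10)$aut,
               0)
  # step: 76 for 3 min then 80 for 3 min, baseline 85, frac 0.10 -> thr 76.5
  tt <- c(seq(10, 12.9, 0.1), seq(13, 16, 0.1))
  vv <- c(rep(76, 30), rep(80, 31))
  step <- oximetry_trace("peripheral", tt, vv, 10, 16)
  expect_equal(aut_relative(step, 85, 0.10, method = "rectangle")$aut, 1.5)
  expect_equal(aut_relative(step, 85, 0.10)$aut,
               dense_aut(tt, vv, 76.5, 10, 16), tolerance = 1e-2)
  expect_error(aut_relative(tr, 0, 0.05), "baseline")
  expect_error(aut_relative(tr, 80, 1.2), "frac")
})

test_that("gaps beyond the tolerance contribute zero burden and are logged", {
  # 10-min hole in an otherwise constant 85% trace
  tt <- c(seq(20, 25, 0.5), seq(35, 40, 0.5))
  tr <- oximetry_trace("renal_mean", tt, rep(85, length(tt)), 20, 40)
  b <- aut_absolute(tr, 90, gap_tol = 2)
  expect_equal(b$aut, 50)        # only the two covered 5-min stretches
  expect_equal(b$gap_min, 10)
  # a generous tolerance integrates across the hole
  b2 <- aut_absolute(tr, 90, gap_tol = 20)
  expect_equal(b2$aut, 100)
  expect_equal(b2$gap_min, 0)
})

test_that("renal-specific burden matches normalised closed forms", {
  # both channels flat at baseline: differential identically zero
  r <- make_flat_trace("renal_mean", 80, incision = 20, end = 120)
  p <- make_flat_trace("peripheral", 84, incision = 20, end = 120)
  expect_equal(renal_specific_burden(r, p, 80, 84)$aut, 0)
  # renal at 90% of baseline, peripheral at baseline, for 10 min -> 100
  tt <- seq(0, 35, 0.25)
  rv <- ifelse(tt >= 20 & tt <= 30, 72, 80)
  rr <- oximetry_trace("renal_mean", tt, rv, 20, 30)
  pp <- oximetry_trace("peripheral", tt, rep(84, length(tt)), 20, 30)
  got <- renal_specific_burden(rr, pp, 80, 84)$aut
  expect_equal(got, 100, tolerance = 1e-6)
  # peripheral proportionally lower than renal throughout: clipped to 0
  pv <- rep(84 * 0.85, length(tt))
  pl <- oximetry_trace("peripheral", tt, pv, 20, 30)
  expect_equal(renal_specific_burden(rr, pl, 80, 84)$aut, 0)
  expect_error(renal_specific_burden(rr, pp, 0, 84), "positive")
})

test_that("renal-specific burden uses the union of both sample grids", {
  # channels sampled on offset grids; oracle on the dense interpolant
  rt <- seq(10, 40, 1)
  pt <- seq(10.5, 40, 1)
  set.seed(403)
  rv <- 80 - cumsum(rnorm(length(rt), 0, 0.5))
  pv <- 84 + cumsum(rnorm(length(pt), 0, 0.5))
  rr <- oximetry_trace("renal_mean", rt, pmin(pmax(rv, 0), 100), 15, 38)
  pp <- oximetry_trace("peripheral", pt, pmin(pmax(pv, 0), 100), 15, 38)
  got <- renal_specific_burden(rr, pp, 80, 84)$aut
  want <- dense_renal_specific(rt, rr$values, 80, pt, pp$values, 84,
                               15, 38)
  expect_equal(got, want, tolerance = 0.1)
})

test_that("burden panel yields the full 16-burden layout", {
  rec <- make_record()
  pan <- burden_panel(rec)
  expect_equal(nrow(pan), 16L)
  expect_equal(sum(pan$channel == "renal_mean" & pan$kind == "absolute"), 4L)
  expect_equal(sum(pan$channel == "cerebral" & pan$kind == "relative"), 3L)
  expect_equal(sum(pan$channel == "peripheral"), 1L)
  expect_equal(pan$threshold[pan$channel == "peripheral"], 0.10)
  expect_equal(sum(pan$kind == "renal_specific"), 1L)
  # flat traces at baseline: every relative burden is zero
  expect_true(all(pan$aut_pct_min[pan$kind != "absolute"] == 0))
  bl <- attr(pan, "baselines")
  expect_setequal(bl$channel, c("renal_mean", "cerebral", "peripheral"))
  expect_equal(bl$value[bl$channel == "peripheral"], 84)
})

test_that("scripted dips reproduce per-episode closed-form areas", {
  # two triangular renal dips on a flat 80% trace, incision 20 end 120:
  #   dip A: to 60 over [30, 40]  -> area below 70 = depth 10, width 5: 25
  #   dip B: to 70 over [60, 68]  -> never below 70 - eps
  tt <- seq(0, 125, 0.25)
  dipA <- pmax(0, 20 * (1 - abs(tt - 35) / 5))
  dipB <- pmax(0, 10 * (1 - abs(tt - 64) / 4))
  vv <- 80 - dipA - dipB
  tr <- oximetry_trace("renal_mean", tt, vv, 20, 120)
  expect_equal(aut_absolute(tr, 70)$aut, 25)
  # area below 80 = full triangles: 20*10/2 + 10*8/2 = 140
  expect_equal(aut_absolute(tr, 80)$aut, 140)
  # relative 10% below baseline 80 -> threshold 72: triangle A contributes
  # depth 12 over width 6 (36), triangle B depth 2 over width 1.6 (1.6)
  expect_equal(aut_relative(tr, 80, 0.10)$aut, 37.6)
})

test_that("burden invariants hold on random piecewise-linear traces", {
  set.seed(404)
  for (i in 1:20) {
    tr <- random_pl_trace()
    auts <- vapply(c(60, 70, 80, 90), function(th)
      aut_absolute(tr, th)$aut, numeric(1))
    expect_true(all(auts >= 0))
    expect_true(all(diff(auts) >= -1e-9))  # non-decreasing in threshold
    rels <- vapply(c(0.15, 0.10, 0.05), function(fr)
      aut_relative(tr, 85, fr)$aut, numeric(1))
    expect_true(all(diff(rels) >= -1e-9))  # non-decreasing as frac falls

    # additivity when split at a sample point inside the window
    mid_i <- which(tr$times > tr$incision_time &
                     tr$times < tr$end_time)[3]
    mid <- tr$times[mid_i]
    left <- oximetry_trace(tr$channel, tr$times, tr$values,
                           tr$incision_time, mid)
    right <- oximetry_trace(tr$channel, tr$times, tr$values, mid,
                            tr$end_time)
    expect_equal(aut_absolute(left, 85)$aut + aut_absolute(right, 85)$aut,
                 aut_absolute(tr, 85)$aut, tolerance = 1e-9)
  }
})

test_that("doubling a constant-deficit episode doubles its burden exactly", {
  one <- make_flat_trace("renal_mean", 70, incision = 20, end = 50)
  two <- make_flat_trace("renal_mean", 70, incision = 20, end = 80)
  expect_equal(aut_absolute(two, 80)$aut, 2 * aut_absolute(one, 80)$aut)
})
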