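test_that("dilation speed matches the two-sided difference definition", {
  expect_equal(dilation_speed(rep(5, 10), 1 / 120), rep(0, 10))
  x <- rep(5, 10); x[6:10] <- 15  # one +10 px jump at 120 Hz
  sp <- dilation_speed(x, 1 / 120)
  expect_equal(sp[5], 1200)
  expect_equal(sp[6], 1200)
  expect_equal(sp[4], 0)
  expect_error(dilation_speed(c(1, 2), 0.01), "at least 3")
})

test_that("artifact detection flags blinks but not clean traces", {
  sched <- sparse_schedule(6, labels = rep("LSGS", 6))
  clean <- simulate_pupil_session(sched, pupil_sim_params(noise_sd = 0,
                                                          blink_rate = 0),
                                  seed = 1)
  expect_equal(sum(detect_artifacts(clean$recording$left_px, 120)), 0)
  # also on the standard densely packed session
  dense <- simulate_pupil_session(build_session(seed = 3),
                                  pupil_sim_params(noise_sd = 0,
                                                   blink_rate = 0), seed = 1)
  expect_equal(sum(detect_artifacts(dense$recording$left_px, 120)), 0)
  blinky <- simulate_pupil_session(sched, pupil_sim_params(noise_sd = 0.2,
                                                           blink_rate = 12),
                                   seed = 2)
  mask <- detect_artifacts(blinky$recording$left_px, 120)
  t_s <- blinky$recording$time_s
  for (i in seq_len(nrow(blinky$blinks))) {
    inside <- t_s >= blinky$blinks$start[i] & t_s <= blinky$blinks$end[i]
    expect_true(all(mask[inside]))
  }
  # blink edges are local speed maxima, far above the typical speed
  sp <- dilation_speed(blinky$recording$left_px, 1 / 120)
  edge <- which.min(abs(t_s - blinky$blinks$start[1]))
  expect_gt(max(sp[edge + (0:7)]), 10 * stats::median(sp, na.rm = TRUE))
})

test_that("a constant trace (zero MAD) flags nothing", {
  expect_equal(sum(detect_artifacts(rep(42, 500), 120)), 0)
})

test_that("gap interpolation is linear inside and nearest-value at edges", {
  got <- interpolate_gaps(c(4, NA, NA, 6), c(FALSE, TRUE, TRUE, FALSE))
  expect_equal(round(got$trace, 3), c(4, 4.667, 5.333, 6))
  expect_equal(got$interpolated, c(FALSE, TRUE, TRUE, FALSE))
  same <- interpolate_gaps(c(1, 2, 3), rep(FALSE, 3))
  expect_equal(same$trace, c(1, 2, 3))
  lead <- interpolate_gaps(c(NA, NA, 5, 7), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(lead$trace, c(5, 5, 5, 7))
  expect_error(interpolate_gaps(c(NA, NA), c(TRUE, TRUE)), "all samples")
})

test_that("the low-pass filter has unit DC gain and the stated roll-off", {
  expect_equal(lowpass(rep(3, 600), 10, 120), rep(3, 600), tolerance = 1e-9)
  t <- seq(0, 10, by = 1 / 120)
  mid <- seq(200, length(t) - 200)  # avoid filter edge transients
  hi <- sin(2 * pi * 30 * t)
  out_hi <- lowpass(hi, 10, 120)
  atten_db <- 20 * log10(max(abs(out_hi[mid])) / 1)
  expect_lt(atten_db, -20)
  lo <- sin(2 * pi * 1 * t)
  out_lo <- lowpass(lo, 10, 120)
  expect_lt(abs(max(abs(out_lo[mid])) - 1), 0.05)
  expect_error(lowpass(hi, 60, 120), "Nyquist")
})

test_that("epochs have the right geometry and exact interpolation fractions", {
  sched <- sparse_schedule(8)
  sim <- simulate_pupil_session(sched, pupil_sim_params(noise_sd = 0,
                                                        blink_rate = 0),
                                seed = 1)
  n <- nrow(sim$recording)
  interp <- rep(FALSE, n)
  ep <- epoch_pupil(sim$recording$left_px, interp, sched,
                    t0 = sim$recording$time_s[1])
  expect_equal(ncol(ep$data), 420)  # 3.5 s x 120 Hz
  expect_equal(nrow(ep$data), 8)
  expect_equal(ep$interp_fraction, rep(0, 8))
  expect_false(any(ep$rejected))
  # interp_fraction is exactly (interpolated samples) / (epoch length)
  interp2 <- interp
  idx1 <- round((sched$onset[1] - sim$recording$time_s[1]) * 120) + 1
  interp2[idx1:(idx1 + 41)] <- TRUE   # 42 of the 360 post-onset samples
  ep2 <- epoch_pupil(sim$recording$left_px, interp2, sched,
                     t0 = sim$recording$time_s[1])
  expect_equal(ep2$interp_fraction[1], 42 / 420)
})

test_that("trial rejection is a step function at the 25% threshold", {
  sched <- sparse_schedule(4)
  sim <- simulate_pupil_session(sched, pupil_sim_params(noise_sd = 0,
                                                        blink_rate = 0),
                                seed = 1)
  t0 <- sim$recording$time_s[1]
  mark <- function(n_interp) {
    interp <- rep(FALSE, nrow(sim$recording))
    idx1 <- round((sched$onset[1] - t0) * 120) + 1 - 60
    interp[idx1:(idx1 + n_interp - 1)] <- TRUE
    epoch_pupil(sim$recording$left_px, interp, sched, t0 = t0)
  }
  expect_false(mark(105)$rejected[1])  # exactly 25%: retained
  expect_true(mark(106)$rejected[1])   # one sample over: rejected
  expect_true(mark(126)$rejected[1])   # 30%
  expect_false(mark(42)$rejected[1])   # 10%
})

test_that("dataset quality labels are step functions at 25% and 50%", {
  fake_ep <- function(rate, n = 100) {
    ep <- matrix_pupil_epochs(matrix(0, n, 12), rep("LSGS", n))
    ep$rejected <- seq_len(n) <= rate * n
    ep
  }
  expect_equal(assess_dataset_quality(fake_ep(0))$label, "correct")
  expect_equal(assess_dataset_quality(fake_ep(0.25))$label, "correct")
  expect_equal(assess_dataset_quality(fake_ep(0.26))$label, "poor")
  expect_equal(assess_dataset_quality(fake_ep(0.30))$label, "poor")
  expect_equal(assess_dataset_quality(fake_ep(0.50))$label, "poor")
  expect_equal(assess_dataset_quality(fake_ep(0.51))$label, "excluded")
  expect_equal(assess_dataset_quality(fake_ep(0.60))$label, "excluded")
})

test_that("eye selection follows reflex, then quality, then the right eye", {
  q <- function(label, rate) structure(list(label = label,
                                            rejection_rate = rate),
                                       class = "pupil_quality")
  expect_equal(select_eye(q("correct", 0.1), q("correct", 0.05), "left"),
               "left")
  expect_equal(select_eye(q("correct", 0.2), q("correct", 0.1)), "right")
  expect_equal(select_eye(q("correct", 0.1), q("correct", 0.1)), "right")
  expect_equal(select_eye(q("excluded", 0.9), q("poor", 0.3)), "right")
  expect_error(select_eye(q("excluded", 0.9), q("excluded", 0.8)),
               "both eyes")
})

test_that("baseline correction zeroes the pre-trial mean per trial", {
  ep <- matrix_pupil_epochs(matrix(7, 5, 420), rep("LSGS", 5))
  expect_equal(unname(ep$data), matrix(0, 5, 420))
  # baseline 2 px then plateau 5 px
  d <- cbind(matrix(2, 3, 60), matrix(5, 3, 360))
  ep2 <- matrix_pupil_epochs(d, rep("LSGS", 3))
  expect_equal(unique(as.vector(ep2$data[, 61:420])), 3)
  in_bl <- ep2$times >= -0.5 & ep2$times < 0
  expect_equal(rowMeans(ep2$data[, in_bl]), rep(0, 3), tolerance = 1e-9)
})

test_that("noiseless epochs reproduce the injected kernel through the filter", {
  sched <- sparse_schedule(6, labels = rep("LSGS", 6))
  p <- pupil_sim_params(noise_sd = 0, blink_rate = 0, amp_generic = 1)
  sim <- simulate_pupil_session(sched, p, seed = 1)
  pd <- pupil_pipeline(sim$recording, sched)
  expect_equal(sum(pd$epochs$rejected), 0)
  avg <- colMeans(pd$epochs$data)
  k <- pdr_kernel(pd$epochs$times)
  expect_lt(max(abs(avg - k)), 0.02)  # zero-phase 10 Hz filter tolerance
})
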