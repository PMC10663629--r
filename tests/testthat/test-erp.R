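test_that("the band-pass filter passes the band and rejects outside it", {
  t <- seq(0, 8, by = 1 / 250)
  mid <- seq(300, length(t) - 300)
  in_band <- sin(2 * pi * 10 * t)
  expect_lt(abs(max(abs(bandpass(in_band)[mid])) - 1), 0.05)
  hi <- sin(2 * pi * 60 * t)
  expect_lt(20 * log10(max(abs(bandpass(hi)[mid]))), -20)
  dc <- rep(5, length(t))
  expect_lt(max(abs(bandpass(dc)[mid])), 0.05)
  expect_error(bandpass(in_band, low = 0, high = 45), "band")
  expect_error(bandpass(in_band, low = 50, high = 45), "band")
})

test_that("EEG epochs span 386 samples and keep their labels", {
  sched <- sparse_schedule(10, soa_s = 3)
  mont <- grid_montage()
  sim <- simulate_eeg_session(sched, eeg_sim_params(noise_sd = 1), seed = 1)
  ep <- epoch_eeg(sim$data, sched, mont, t0 = sim$times[1])
  expect_equal(dim(ep$data), c(10, 32, 386))
  expect_equal(ep$labels, sched$trial_label)
  expect_equal(ep$n_dropped, 0)
  # a trial at the recording edge is dropped and counted
  sched2 <- dplyr::bind_rows(sched,
                             dplyr::mutate(sched[1, ],
                                           onset = max(sim$times) + 5))
  ep2 <- epoch_eeg(sim$data, sched2, mont, t0 = sim$times[1])
  expect_equal(ep2$n_dropped, 1)
  expect_equal(dim(ep2$data)[1], 10)
})

test_that("channel rejection applies the amplitude and variance rules", {
  mont <- grid_montage()
  withr::with_seed(2, {
    ep <- noise_erp_epochs(20, 20, mont, noise_sd = 5)
    # channel 7: 120 µV excursions in 60% of epochs
    hit <- seq_len(24)
    ep$data[hit, 7, 100] <- 120
    # channel 20: inflated variance (Z well above 4)
    ep$data[, 20, ] <- ep$data[, 20, ] * 8
    out <- reject_channels(ep)
  })
  expect_false(out$valid_channels[7])
  expect_false(out$valid_channels[20])
  expect_equal(sum(!out$valid_channels), 2)
  # borderline amplitude channel (exactly 50% of epochs) is retained by the
  # amplitude rule (strictly "more than"); variance passes disabled to
  # isolate it
  withr::with_seed(3, {
    ep2 <- noise_erp_epochs(20, 20, mont, noise_sd = 5)
    ep2$data[seq_len(20), 5, 100] <- 120
    out2 <- reject_channels(ep2, n_iter = 0)
  })
  expect_true(out2$valid_channels[5])
  # homogeneous clean channels: none removed
  withr::with_seed(4, {
    clean <- reject_channels(noise_erp_epochs(20, 20, mont, noise_sd = 5))
  })
  expect_true(all(clean$valid_channels))
})

test_that("epoch rejection applies the electrode-fraction and variance rules", {
  mont <- grid_montage()
  withr::with_seed(5, {
    ep <- noise_erp_epochs(20, 20, mont, noise_sd = 5)
    # epoch 3: 150 µV on 5/32 electrodes (~15.6% > 10%)
    ep$data[3, 1:5, 50] <- 150
    # epoch 12: variance inflated
    ep$data[12, , ] <- ep$data[12, , ] * 8
    out <- reject_epochs(ep)
  })
  expect_false(out$valid_epochs[3])
  expect_false(out$valid_epochs[12])
  # an epoch at exactly 10% of electrodes survives the amplitude rule
  # (strictly "more than"); variance passes disabled to isolate it
  withr::with_seed(55, {
    epb <- noise_erp_epochs(20, 20, mont, noise_sd = 5)
    epb$data[8, 1:3, 50] <- 150   # 3/32 electrodes = 9.4%
    epb$data[9, 1:4, 50] <- 150   # 4/32 electrodes = 12.5%
    outb <- reject_epochs(epb, n_iter = 0)
  })
  expect_true(outb$valid_epochs[8])
  expect_false(outb$valid_epochs[9])
  withr::with_seed(6, {
    clean <- reject_epochs(noise_erp_epochs(20, 20, mont, noise_sd = 5))
  })
  expect_true(all(clean$valid_epochs))
})

test_that("the iterative variance rejection unmasks channels stepwise", {
  mont <- grid_montage()
  withr::with_seed(7, {
    ep <- noise_erp_epochs(20, 20, mont, noise_sd = 2)
    ep$data[, 10, ] <- ep$data[, 10, ] * 30  # huge
    ep$data[, 11, ] <- ep$data[, 11, ] * 10  # masked until 10 is removed
    out <- reject_channels(ep, amp_thresh = 1e6)
  })
  expect_false(out$valid_channels[10])
  expect_false(out$valid_channels[11])
  # deterministic: same input, same result
  withr::with_seed(7, {
    ep2 <- noise_erp_epochs(20, 20, mont, noise_sd = 2)
    ep2$data[, 10, ] <- ep2$data[, 10, ] * 30
    ep2$data[, 11, ] <- ep2$data[, 11, ] * 10
    out2 <- reject_channels(ep2, amp_thresh = 1e6)
  })
  expect_identical(out$valid_channels, out2$valid_channels)
})

test_that("spline interpolation reconstructs constant and linear fields", {
  mont <- grid_montage()
  # constant field: interpolated value equals the constant
  ep <- noise_erp_epochs(2, 2, mont, noise_sd = 0)
  ep$data[, , ] <- 3.5
  ep$valid_channels[12] <- FALSE
  ep$data[, 12, ] <- -99
  out <- interpolate_channels(ep)
  expect_true(out$valid_channels[12])
  expect_equal(unique(as.vector(out$data[, 12, ])), 3.5, tolerance = 1e-8)
  # linear gradient in x: reconstruction within 5%
  ep2 <- noise_erp_epochs(2, 2, mont, noise_sd = 0)
  xs <- mont$channels$x
  for (tr in 1:4) ep2$data[tr, , ] <- xs + 1
  ep2$valid_channels[12] <- FALSE
  ep2$data[, 12, ] <- 0
  out2 <- interpolate_channels(ep2)
  truth <- xs[12] + 1
  expect_lt(max(abs(out2$data[, 12, ] - truth)) / truth, 0.05)
  # valid channels are untouched
  expect_equal(out2$data[, -12, ], ep2$data[, -12, ])
  # an isolated channel without enough valid neighbours stays invalid
  ep3 <- noise_erp_epochs(2, 2, mont, noise_sd = 1)
  ep3$valid_channels[c(1, 2, 9)] <- FALSE  # corner E01's neighbours gone
  out3 <- interpolate_channels(ep3)
  expect_false(out3$valid_channels[1])
})

test_that("average re-referencing zeroes the channel mean and is idempotent", {
  mont <- grid_montage()
  withr::with_seed(8, ep <- noise_erp_epochs(4, 4, mont, noise_sd = 2))
  ep$data <- ep$data + 5
  out <- rereference_average(ep)
  for (tr in c(1, 5))
    expect_equal(max(abs(colMeans(out$data[tr, , ]))), 0, tolerance = 1e-9)
  # pairwise channel differences preserved
  expect_equal(out$data[1, 3, ] - out$data[1, 17, ],
               ep$data[1, 3, ] - ep$data[1, 17, ], tolerance = 1e-9)
  twice <- rereference_average(out)
  expect_equal(twice$data, out$data, tolerance = 1e-12)
})

test_that("ERP baseline uses the 800 ms before the fifth sound", {
  mont <- grid_montage()
  ep <- noise_erp_epochs(2, 2, mont, noise_sd = 0)
  ep$data[, , ] <- 4
  out <- baseline_erp(ep)
  expect_equal(unique(as.vector(out$data)), 0)
  # the window spans -0.2 to +0.6 s: a post-fifth-sound deflection survives
  ep2 <- noise_erp_epochs(2, 2, mont, noise_sd = 0)
  late <- ep2$times > 0.7
  ep2$data[, , late] <- 10
  out2 <- baseline_erp(ep2)
  expect_equal(unique(as.vector(out2$data[, , late])), 10)
  in_bl <- out2$times >= -0.2 & out2$times < 0.6
  expect_equal(max(abs(out2$data[, , in_bl])), 0)
})

test_that("EEG quality thresholds act at 75% channels and 30% epochs", {
  mont <- grid_montage()
  ep <- noise_erp_epochs(20, 20, mont, noise_sd = 1)
  expect_equal(erp_quality(ep), "correct")
  ep_ch <- ep; ep_ch$valid_channels[1:8] <- FALSE   # 75% exactly
  expect_equal(erp_quality(ep_ch), "correct")
  ep_ch2 <- ep; ep_ch2$valid_channels[1:9] <- FALSE  # 71.9%
  expect_equal(erp_quality(ep_ch2), "poor")
  ep_ep <- ep; ep_ep$valid_epochs[1:28] <- FALSE     # 30% exactly
  expect_equal(erp_quality(ep_ep), "correct")
  ep_ep2 <- ep; ep_ep2$valid_epochs[1:29] <- FALSE   # 27.5%
  expect_equal(erp_quality(ep_ep2), "poor")
})

test_that("the triple-threshold criterion needs 5 samples and 10 contiguous electrodes", {
  mont <- grid_montage()
  # 12 adjacent electrodes (a 3 x 4 sub-grid), 200 ms (50 samples), high SNR
  block12 <- c(2:5, 10:13, 18:21)
  samp200 <- 301:350  # 1.004-1.200 s, inside the global window
  withr::with_seed(9, {
    hit <- noise_erp_epochs(25, 25, mont, noise_sd = 1, effect = 3,
                            effect_channels = block12,
                            effect_samples = samp200)
    res <- triple_threshold_effect(hit, contrast_spec("mve"))
  })
  expect_true(res$significant)
  expect_gte(max(tidy(res)$n_channels), 10)
  # same effect on only 4 consecutive samples: not significant
  withr::with_seed(10, {
    short <- noise_erp_epochs(25, 25, mont, noise_sd = 1, effect = 3,
                              effect_channels = block12,
                              effect_samples = 301:304)
    res_s <- triple_threshold_effect(short, contrast_spec("mve"))
  })
  expect_false(res_s$significant)
  # same effect on only 9 contiguous electrodes: not significant
  withr::with_seed(12, {
    nine <- noise_erp_epochs(25, 25, mont, noise_sd = 1, effect = 3,
                             effect_channels = c(2:4, 10:12, 18:20),
                             effect_samples = samp200)
    res_9 <- triple_threshold_effect(nine, contrast_spec("mve"))
  })
  expect_false(res_9$significant)
  # 10 scattered (non-contiguous) electrodes do not count either
  withr::with_seed(13, {
    scat <- noise_erp_epochs(25, 25, mont, noise_sd = 1, effect = 3,
                             effect_channels = c(1, 3, 5, 7, 9, 11, 22, 24,
                                                 26, 28),
                             effect_samples = samp200)
    res_sc <- triple_threshold_effect(scat, contrast_spec("mve"))
  })
  expect_false(res_sc$significant)
})

test_that("effects outside the expected window are ignored", {
  mont <- grid_montage()
  block12 <- c(2:5, 10:13, 18:21)
  withr::with_seed(14, {
    early <- noise_erp_epochs(25, 25, mont, noise_sd = 1, effect = 3,
                              effect_channels = block12,
                              effect_samples = 60:110)  # 0.04-0.24 s
    res <- triple_threshold_effect(early, contrast_spec("global"))
  })
  expect_false(res$significant)
})

test_that("component mode also finds the injected cluster", {
  mont <- grid_montage()
  block12 <- c(2:5, 10:13, 18:21)
  withr::with_seed(15, {
    hit <- noise_erp_epochs(25, 25, mont, noise_sd = 1, effect = 3,
                            effect_channels = block12,
                            effect_samples = 301:350)
    res <- triple_threshold_effect(hit, contrast_spec("mve"),
                                   mode = "component")
  })
  expect_true(res$significant)
})

test_that("pure-noise simulations rarely trigger the triple threshold", {
  withr::with_seed(16, {
    mont <- grid_montage()
    hits <- vapply(1:100, function(i) {
      ep <- noise_erp_epochs(20, 20, mont, noise_sd = 1)
      triple_threshold_effect(ep, contrast_spec("mve"))$significant
    }, logical(1))
  })
  expect_lt(mean(hits), 0.20)
})

test_that("the full ERP pipeline recovers injected effects end to end", {
  mont <- grid_montage()
  # documented strong-effect setting: mmn 8 µV, p3b 12 µV, noise 4 µV
  sched <- build_session(seed = 101)
  p <- eeg_sim_params(noise_sd = 4, mmn_amp = 8, p3b_amp = 12)
  sim <- simulate_eeg_session(sched, p, seed = 1)
  erp <- erp_pipeline(sim$data, sched, mont, t0 = sim$times[1])
  expect_equal(erp$quality, "correct")
  expect_true(triple_threshold_effect(erp$epochs,
                                      contrast_spec("global"))$significant)
  expect_true(triple_threshold_effect(erp$epochs,
                                      contrast_spec("local"))$significant)
  # matched noise, no P3b: no global effect
  p0 <- eeg_sim_params(noise_sd = 4, mmn_amp = 8, p3b_amp = 0)
  sim0 <- simulate_eeg_session(sched, p0, seed = 2)
  erp0 <- erp_pipeline(sim0$data, sched, mont, t0 = sim0$times[1])
  expect_false(triple_threshold_effect(erp0$epochs,
                                       contrast_spec("global"))$significant)
})
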