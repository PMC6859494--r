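test_that("degenerate catch probability yields an all-catch session", {
  ses <- generate_session(session_config(n_trials = 30, p_catch = 1, seed = 2))
  expect_true(all(ses$trials$type == "catch"))
  expect_true(all(is.finite(ses$trials$stim_time_s)))  # virtual stimulus times
})

test_that("multimotor block schedule alternates R,L,R,L in 50-trial blocks", {
  ses <- generate_session(session_config(n_trials = 200, task = "multimotor",
                                         block_length_trials = 50, seed = 5))
  expected <- rep(c("right", "left", "right", "left"), each = 50)
  expect_identical(ses$trials$block_side, expected)
  expect_identical(ses$truth$switch_trials, c(51L, 101L, 151L))
})

test_that("identical config and seed reproduce the session exactly", {
  cfg <- session_config(n_trials = 60, seed = 11)
  expect_identical(generate_session(cfg), generate_session(cfg))
})

test_that("no lick violates the quiet period before any stimulus", {
  for (seed in 1:5) {
    ses <- generate_session(session_config(n_trials = 80, task = "multimotor",
                                           spont_rate_hz = 0.3, seed = seed))
    licks <- session_licks(ses$trials)
    q <- ses$truth$config$quiet_period_s
    for (t0 in ses$trials$stim_time_s) {
      expect_false(any(licks$time_s >= t0 - q & licks$time_s < t0))
    }
  }
})

test_that("invalid session configuration is rejected", {
  expect_error(session_config(p_catch = 1.2), "probability")
  expect_error(session_config(isi_mean_s = -1), "positive")
  expect_error(calcium_config(frac_left_tuned = 0.7, frac_right_tuned = 0.7,
                              frac_untuned = 0), "sum to 1")
})

test_that("calcium forward model honors its degenerate limits", {
  ses <- quiet_session(n_trials = 5, seed = 3)
  # no events, no noise, no contamination -> flat baseline
  cfg <- calcium_config(n_neurons = 2, frac_left_tuned = 0, frac_right_tuned = 0,
                        frac_untuned = 1, noise_sd = 0, contaminant_sd = 0,
                        background_rate_hz = 0, alpha_mean = 0, alpha_sd = 0,
                        seed = 3)
  cal <- generate_calcium(cfg, ses$trials, ses$truth)
  expect_true(all(cal$neurons[[1]]$f_soma == cfg$baseline_f0))
  # alpha_true = 0 -> soma is exactly signal + baseline + noise (no surround)
  cfg2 <- calcium_config(n_neurons = 1, frac_left_tuned = 0,
                         frac_right_tuned = 0, frac_untuned = 1,
                         background_rate_hz = 0.2, alpha_mean = 0,
                         alpha_sd = 0, seed = 4)
  cal2 <- generate_calcium(cfg2, ses$trials, ses$truth)
  nrn <- cal2$neurons[[1]]
  expect_equal(nrn$f_soma,
               neuropil_correct(nrn$f_soma, nrn$f_surround, alpha = 0))
})

test_that("known alpha restores the contamination-free trace exactly", {
  ses <- quiet_session(n_trials = 5, seed = 7)
  cfg <- calcium_config(n_neurons = 3, seed = 7)
  cal <- generate_calcium(cfg, ses$trials, ses$truth)
  for (j in 1:3) {
    nrn <- cal$neurons[[j]]
    clean <- nrn$f_soma - nrn$alpha * nrn$f_surround
    expect_equal(neuropil_correct(nrn), clean, tolerance = 1e-12)
  }
})

test_that("untuned neurons' event counts are independent of block side", {
  # chi-square test of per-block event counts; expect non-significant on
  # average over seeds
  pvals <- vapply(1:20, function(seed) {
    ses <- generate_session(session_config(n_trials = 60, task = "multimotor",
                                           block_length_trials = 15,
                                           seed = seed))
    cfg <- calcium_config(n_neurons = 1, frac_left_tuned = 0,
                          frac_right_tuned = 0, frac_untuned = 1,
                          background_rate_hz = 0.3, seed = seed)
    cal <- generate_calcium(cfg, ses$trials, ses$truth)
    ev <- cal$truth$events[[1]]
    # assign events to blocks by stimulus-midpoint boundaries
    n <- nrow(ses$trials)
    bnd <- c(0, ses$trials$stim_time_s[-n] + diff(ses$trials$stim_time_s) / 2,
             ses$truth$duration_s)
    idx <- findInterval(ev, bnd[-c(1, length(bnd))]) + 1L
    side <- ses$trials$block_side[pmin(idx, n)]
    counts <- table(factor(side, levels = c("left", "right")))
    lens <- tapply(diff(bnd), ses$trials$block_side, sum)[c("left", "right")]
    suppressWarnings(
      stats::chisq.test(counts, p = lens / sum(lens))$p.value)
  }, numeric(1))
  expect_gt(mean(pvals), 0.1)   # uniform p-values average 0.5
})

test_that("jaw generator respects its degenerate limits and determinism", {
  ses <- quiet_session(n_trials = 6, seed = 9)
  j0 <- generate_jaw(ses$trials, ses$truth, small_rate_hz = 0, seed = 9)
  expect_length(j0$truth$small_onsets, 0)
  # zero-amplitude movements leave the SD at baseline level
  j1 <- generate_jaw(ses$trials, ses$truth, small_rate_hz = 0.3,
                     small_snr = 0, noise_model = "iid", seed = 9)
  jref <- generate_jaw(ses$trials, ses$truth, small_rate_hz = 0,
                       noise_model = "iid", seed = 9)
  expect_lt(abs(sd(j1$position) / sd(jref$position) - 1), 0.05)
  # determinism
  expect_identical(generate_jaw(ses$trials, ses$truth, seed = 4),
                   generate_jaw(ses$trials, ses$truth, seed = 4))
})

test_that("planted small movements are isolated and within the session", {
  ses <- quiet_session(n_trials = 30, seed = 13)
  jaw <- generate_jaw(ses$trials, ses$truth, n_small = 40, seed = 13)
  on <- jaw$truth$small_onsets
  expect_length(on, 40)
  expect_true(all(diff(on) >= 1.6))
  expect_true(all(on > 0 & on < ses$truth$duration_s))
})

test_that("widefield generator records ground truth and validates spots", {
  wf <- generate_widefield(shape = c(40, 40),
                           spots = list(list(center = c(30, 40),
                                             amplitude = 0.03, sigma_px = 4,
                                             lag_s = 0.05)),
                           n_trials = 10, seed = 21)
  expect_identical(wf$truth$centers[[1]], c(30, 40))
  expect_error(generate_widefield(shape = c(20, 20),
                                  spots = list(list(center = c(30, 5),
                                                    amplitude = 0.01,
                                                    sigma_px = 2, lag_s = 0))),
               "outside")
  expect_error(generate_widefield(pre_s = 0.5), "pre-stimulus")
})

test_that("zero-amplitude spots give a dF/F indistinguishable from zero", {
  wf <- generate_widefield(shape = c(30, 30), spots = list(), n_trials = 50,
                           noise_sd = 0.01, seed = 3)
  dff <- compute_dff(wf$movie, wf$stim_frame)
  post <- dff$dff[, , wf$stim_frame:(wf$stim_frame + 30)]
  # frames of one pixel share its F0 error: effective n is the pixel count
  se <- sd(post) / sqrt(prod(dim(post)[1:2]))
  expect_lt(abs(mean(post)), 3 * se)
})

test_that("two-spot lags separate early and late response windows", {
  wf <- generate_widefield(shape = c(50, 50),
                           spots = list(list(center = c(40, 40),
                                             amplitude = 0.05, sigma_px = 4,
                                             lag_s = 0.05),
                                        list(center = c(10, 10),
                                             amplitude = 0.05, sigma_px = 4,
                                             lag_s = 0.15)),
                           n_trials = 50, noise_sd = 0.005, seed = 8)
  im <- response_images(compute_dff(wf$movie, wf$stim_frame))
  # early window: only the early spot exceeds half its own max
  expect_gt(im$early[40, 40], 0.5 * max(im$early))
  expect_lt(im$early[10, 10], 0.5 * max(im$early))
  expect_gt(im$late[10, 10], 0.25 * max(im$late))
})

test_that("motor-map generator attenuates far sites and honors noisy_frac", {
  mm <- generate_motormap_trials(hotspot = list(x = 0.5, y = 0.5,
                                                sigma_mm = 0.5,
                                                amplitude_deg = 8),
                                 n_trials = 3, seed = 5)
  far <- which(mm$truth$sites$x == 3 & mm$truth$sites$y == 3)
  expect_lt(mm$truth$amplitude_deg[far], 1e-4)
  # all-noisy trials are all excluded by the inclusion rule
  mm2 <- generate_motormap_trials(grid_x_mm = c(0, 0.5), grid_y_mm = c(0, 0.5),
                                  hotspot = list(x = 0.25, y = 0.25,
                                                 sigma_mm = 0.5,
                                                 amplitude_deg = 5),
                                  n_trials = 4, noisy_frac = 1, seed = 6)
  expect_true(all(!vapply(mm2$trials, include_trial, logical(1))))
  expect_error(build_map(mm2$trials), "missing|sites")
  # determinism
  expect_identical(generate_motormap_trials(n_trials = 2, seed = 3),
                   generate_motormap_trials(n_trials = 2, seed = 3))
})
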