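test_that("neuropil correction is the stated elementwise identity", {
  soma <- c(1, 2, 3, 4)
  surr <- c(1, 1, 2, 2)
  expect_identical(neuropil_correct(soma, surr, alpha = 0), soma)
  signal <- sin(1:100)
  surr4 <- rep(surr, 25)
  expect_equal(neuropil_correct(signal + 0.4 * surr4, surr4, alpha = 0.4),
               signal, tolerance = 1e-12)
  expect_error(neuropil_correct(1:3, 1:4, alpha = 0.5), "length")
  expect_warning(neuropil_correct(soma, surr, alpha = 1.4), "outside")
})

test_that("neuropil correction is linear in its input", {
  soma <- rnorm(200)
  surr <- rnorm(200)
  expect_equal(neuropil_correct(3 * soma, 3 * surr, alpha = 0.38),
               3 * neuropil_correct(soma, surr, alpha = 0.38))
})

test_that("correction improves correlation with the true signal", {
  ses <- quiet_session(n_trials = 8, seed = 2)
  cfg <- calcium_config(n_neurons = 4, frac_left_tuned = 0,
                        frac_right_tuned = 0, frac_untuned = 1,
                        background_rate_hz = 0.3, contaminant_sd = 25,
                        alpha_mean = 0.6, alpha_sd = 0.1, seed = 2)
  cal <- generate_calcium(cfg, ses$trials, ses$truth)
  for (j in seq_along(cal$neurons)) {
    nrn <- cal$neurons[[j]]
    truth <- cal$truth$signal[[j]]
    expect_gt(cor(neuropil_correct(nrn), truth), cor(nrn$f_soma, truth))
  }
})

test_that("noise model recovers mode and sigma of a clean Gaussian trace", {
  set.seed(42)
  x <- rnorm(1e5, 5, 1)
  nm <- fit_noise_model(x, frame_rate_hz = 30, block_s = 1e5 / 30)
  expect_lt(abs(nm$blocks$f_mode[1] - 5), 0.05)
  expect_lt(abs(nm$blocks$sigma_noise[1] - 1), 0.05)
})

test_that("sigma estimate matches the explicit symmetrization oracle", {
  set.seed(7)
  x <- rnorm(3000, 2, 0.5) + ifelse(runif(3000) < 0.05, 4, 0)
  nm <- fit_noise_model(x, frame_rate_hz = 30, block_s = 100)
  m <- nm$blocks$f_mode[1]
  below <- x[x <= m]
  sym <- c(below, 2 * m - x[x < m])   # originals plus reflection, mode once
  expect_identical(nm$blocks$sigma_noise[1], sd(sym))
})

test_that("noise model is translation-equivariant and rejects flat traces", {
  set.seed(8)
  x <- rnorm(6000, 0, 1)
  a <- fit_noise_model(x, 30, 100)
  b <- fit_noise_model(x + 10, 30, 100)
  expect_equal(b$blocks$f_mode, a$blocks$f_mode + 10, tolerance = 1e-6)
  expect_equal(b$blocks$sigma_noise, a$blocks$sigma_noise, tolerance = 1e-9)
  expect_error(fit_noise_model(rep(1, 4000), 30, 100), "constant")
})

test_that("blocks tile the trace with the partial remainder merged", {
  set.seed(9)
  x <- rnorm(7500)   # 250 s at 30 Hz: 2 blocks, 2nd absorbs the last 50 s
  nm <- fit_noise_model(x, 30, 100)
  expect_identical(nrow(nm$blocks), 2L)
  expect_identical(nm$blocks$start, c(1L, 3001L))
  expect_identical(nm$blocks$end, c(3000L, 7500L))
  # shorter than a block -> one block
  nm1 <- fit_noise_model(rnorm(900), 30, 100)
  expect_identical(nrow(nm1$blocks), 1L)
})

test_that("z-scoring standardizes per block and is affine-invariant", {
  set.seed(10)
  x <- rnorm(9000, 3, 2)
  nm <- fit_noise_model(x, 30, 100)
  z <- zscore_trace(x, nm)
  expect_lt(abs(median(z)), 0.05)
  # block boundary uses each block's own parameters
  b <- nm$blocks
  i <- b$start[2]
  expect_equal(z[i], (x[i] - b$f_mode[2]) / b$sigma_noise[2])
  # gain and offset on the raw trace cancel in z (same block structure)
  y <- 4 * x + 7
  zy <- zscore_trace(y, fit_noise_model(y, 30, 100))
  expect_equal(zy, z, tolerance = 0.05)
  # trace equal to the mode inside a block maps to 0
  x2 <- c(rnorm(3000), rnorm(3000, 5))
  nm2 <- fit_noise_model(x2, 30, 100)
  x3 <- x2
  x3[10] <- nm2$blocks$f_mode[1]
  expect_equal(zscore_trace(x3, nm2)[10], 0, tolerance = 1e-9)
})

test_that("infrequent-activity filter counts upward crossings only", {
  fr <- 30
  expect_false(filter_infrequent(rep(0, 600 * fr), fr)$keep)
  # 60 transients in 600 s crossing z = 5 -> 0.1 Hz, kept
  z <- rep(0, 600 * fr)
  at <- seq(100, by = 295, length.out = 60)
  for (i in at) z[i:(i + 3)] <- 6
  res <- filter_infrequent(z, fr)
  expect_identical(res$n_events, 60L)
  expect_equal(res$rate_hz, 0.1, tolerance = 1e-9)
  expect_true(res$keep)
  # plateau above threshold counts exactly once
  zp <- c(rep(0, 10), rep(7, 50), rep(0, 10))
  expect_identical(filter_infrequent(zp, fr)$n_events, 1L)
})

test_that("alignment samples the native grid without interpolation", {
  z <- seq_len(900) * 1.0   # index ramp makes sampled frames identifiable
  al <- align_trace(z, 10, frame_rate_hz = 30, pre_ms = 1000, post_ms = 1000)
  expect_identical(ncol(al$mat), 61L)          # -30..30 frames
  expect_identical(al$mat[1, 31], z[301])      # frame nearest t = 10 s
  # event too close to the start is dropped with a warning
  expect_warning(al2 <- align_trace(z, c(0.1, 10), 30, 1000, 1000), "dropped")
  expect_identical(nrow(al2$mat), 1L)
  expect_error(suppressWarnings(align_trace(z, 0.1, 30, 1000, 1000)),
               "no valid events")
  # identical events give identical rows
  al3 <- align_trace(z, c(12, 12), 30, 500, 500)
  expect_identical(al3$mat[1, ], al3$mat[2, ])
})

test_that("responsiveness test flags deterministic offsets and honors the
           15-event minimum", {
  n_time <- 40
  fr <- 30
  base <- matrix(rnorm(20 * n_time), 20)
  al <- aligned_from_matrix(base, fr, t0_ms = -800)
  resp <- al
  sel <- resp$time_ms >= 0 & resp$time_ms < 200
  resp$mat[, sel] <- resp$mat[, sel] + 2
  r <- test_responsiveness(resp, "stimulus")
  expect_true(r$significant)
  expect_gt(r$mean_response, 1.5)
  r14 <- test_responsiveness(aligned_from_matrix(base[1:14, ], fr, -800),
                             "stimulus")
  expect_true(r14$excluded)
  expect_false(r14$significant)
})

test_that("population trajectories separate orthogonal response groups", {
  t_grid <- 60
  n <- 20
  bump <- exp(-((seq_len(t_grid) - 30)^2) / 50)
  curves <- list(
    catA = rbind(matrix(rep(bump, 10), 10, byrow = TRUE),
                 matrix(0, 10, t_grid)),
    catB = rbind(matrix(0, 10, t_grid),
                 matrix(rep(bump, 10), 10, byrow = TRUE)))
  curves <- lapply(curves, function(m) m + matrix(rnorm(n * t_grid, 0, 0.01),
                                                  n))
  pt <- population_trajectory(curves)
  # rank-2 construction: first two PCs explain ~everything
  expect_gt(sum(pt$explained_variance), 0.98)
  expect_true(all(diff(pt$explained_variance) <= 0))
  # trajectories separate: peak-time distance far exceeds baseline jitter
  dist_ab <- sqrt(rowSums((pt$trajectories$catA - pt$trajectories$catB)^2))
  expect_gt(max(dist_ab), 5 * min(dist_ab[1:5]))
  # identical category means coincide
  pt2 <- population_trajectory(list(a = curves$catA, b = curves$catA))
  expect_equal(pt2$trajectories$a, pt2$trajectories$b, tolerance = 1e-9)
  expect_error(population_trajectory(list(a = curves$catA)), "categories")
})
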