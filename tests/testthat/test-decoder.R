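test_that("the hand-computed two-neuron example decodes right", {
  tuning <- rbind(c(0.1, 1.1), c(1.1, 0.1))
  colnames(tuning) <- c("left", "right")
  dec <- lick_decoder(tuning, epsilon = 1e-12)
  res <- decode_licks(dec, matrix(c(1, 0), 1))
  # LL(R) - LL(L) = log(1.1) - log(0.1) > 0
  expect_identical(res$decoded, "right")
  expect_equal(unname(res$loglik[1, "right"] - res$loglik[1, "left"]),
               log(1.1 / 0.1), tolerance = 1e-6)
})

test_that("decisions agree exactly with the brute-force sum r*log f oracle", {
  vals <- c(0.1, 0.5, 1, 1.5, 2, 3)
  eps <- 1e-3
  # exhaustive for one neuron: all tuning pairs x integer activities 0..3
  for (fl in vals) for (fr in vals) for (r in 0:3) {
    dec <- lick_decoder(rbind(c(fl, fr)), epsilon = eps)
    got <- decode_licks(dec, matrix(r, 1), seed = 1)
    want <- oracle_decode(dec$tuning, matrix(r, 1), eps)
    if (!is.na(want) && !got$tie) {
      expect_identical(got$decoded, as.character(want)[1])
    } else {
      expect_lt(abs(attr(want, "diff")), 1e-6)
    }
  }
  # random sweep over the full size range (ties excluded)
  set.seed(99)
  for (rep in 1:300) {
    n <- sample(2:5, 1)
    t <- sample(1:10, 1)
    tuning <- matrix(sample(vals, 2 * n, replace = TRUE), n,
                     dimnames = list(NULL, c("left", "right")))
    act <- matrix(sample(0:3, n * t, replace = TRUE), t)
    dec <- lick_decoder(tuning, epsilon = eps)
    got <- decode_licks(dec, act, seed = rep)
    want <- oracle_decode(tuning, act, eps)
    ok <- !is.na(want) & !got$tie
    expect_identical(got$decoded[ok], as.character(want)[ok])
    expect_true(all(abs(attr(want, "diff")[got$tie]) < 1e-6))
  }
})

test_that("bias correction never changes a decision", {
  set.seed(3)
  tuning <- matrix(abs(rnorm(20)), 10,
                   dimnames = list(NULL, c("left", "right")))
  act <- matrix(rnorm(80, 1), 8)
  d1 <- decode_licks(lick_decoder(tuning, epsilon = 0.01,
                                  bias_mode = "log_mean"), act, seed = 5)
  d2 <- decode_licks(lick_decoder(tuning, epsilon = 0.01,
                                  bias_mode = "raw_mean"), act, seed = 5)
  expect_identical(d1$decoded, d2$decoded)
  # adding a per-neuron constant to both log tunings leaves decisions fixed
  dec <- lick_decoder(tuning, epsilon = 0.01)
  dec$log_tuning <- dec$log_tuning + rnorm(10)
  d3 <- decode_licks(dec, act, seed = 5)
  expect_identical(d3$decoded, d1$decoded)
})

test_that("symmetric tuning forces ties resolved at chance", {
  tuning <- matrix(rep(c(0.5, 1.2, 2), 2), 3,
                   dimnames = list(NULL, c("left", "right")))
  dec <- lick_decoder(tuning, epsilon = 0.01)
  act <- matrix(abs(rnorm(3000)), 1000)
  res <- decode_licks(dec, act, actual = rep("right", 1000), seed = 42)
  expect_true(all(res$tie))
  expect_lt(abs(res$performance - 0.5), 0.05)
})

test_that("label permutation centers performance at chance", {
  set.seed(12)
  tuning <- matrix(abs(rnorm(16, 1)), 8,
                   dimnames = list(NULL, c("left", "right")))
  dec <- lick_decoder(tuning, epsilon = 0.01)
  act <- matrix(abs(rnorm(8 * 200)), 200)
  actual <- sample(c("left", "right"), 200, replace = TRUE)
  base <- decode_licks(dec, act, actual = actual, seed = 1)$decoded
  perfs <- vapply(1:300, function(i) mean(base == sample(actual)), numeric(1))
  expect_lt(abs(mean(perfs) - 0.5), 0.02)
})

test_that("non-finite activity raises an error naming the trial", {
  dec <- lick_decoder(rbind(c(1, 2), c(2, 1)), epsilon = 0.01)
  act <- matrix(1, 3, 2)
  act[2, 1] <- NA
  expect_error(decode_licks(dec, act), "trial\\(s\\) 2")
})

test_that("tuning estimation applies the inclusion rules", {
  fr <- 30
  make_resp <- function(n_l, n_r, gain_r = 1, gain_l = 0) {
    mk <- function(n, gain) {
      mat <- matrix(rnorm(n * 40, 0, 0.3), n)
      al <- aligned_from_matrix(mat, fr, t0_ms = -800)
      sel <- al$time_ms >= -100 & al$time_ms < 100
      al$mat[, sel] <- al$mat[, sel] + gain
      al
    }
    list(left = mk(n_l, gain_l), right = mk(n_r, gain_r))
  }
  set.seed(21)
  # a clean right-preferring neuron: f = (~0, ~1)
  responses <- replicate(6, make_resp(20, 20), simplify = FALSE)
  dec <- compute_tuning(responses)
  expect_identical(dec$status, "ok")
  expect_equal(unname(colMeans(coef(dec))), c(0, 1), tolerance = 0.15)
  # a neuron with 14 right licks is dropped
  responses14 <- responses
  responses14[[1]] <- make_resp(20, 14)
  dec14 <- compute_tuning(responses14)
  expect_identical(nrow(coef(dec14)), 5L)
  # fewer than 5 qualifying neurons excludes the whole field of view
  dec4 <- compute_tuning(responses[1:4])
  expect_identical(dec4$status, "excluded")
  expect_match(dec4$reason, "4 qualifying")
  expect_error(decode_licks(dec4, matrix(0, 1, 4)), "excluded")
})

test_that("performance never degrades as tuning separation grows", {
  set.seed(77)
  deltas <- c(0, 0.4, 1, 2)
  mean_perf <- vapply(deltas, function(d) {
    perfs <- vapply(1:20, function(s) {
      set.seed(1000 + s)
      n <- 10
      tuning <- cbind(left = rep(c(1 + d, 1), each = n / 2),
                      right = rep(c(1, 1 + d), each = n / 2))
      dec <- lick_decoder(tuning, epsilon = 0.01)
      actual <- sample(c("left", "right"), 100, replace = TRUE)
      act <- t(vapply(actual, function(a) {
        rpois(n, tuning[, a])
      }, numeric(n)))
      decode_licks(dec, act, actual = actual, seed = s)$performance
    }, numeric(1))
    mean(perfs)
  }, numeric(1))
  expect_true(all(diff(mean_perf) >= -0.02))
  expect_gt(mean_perf[4], 0.9)
})

test_that("decoder performance approaches the Bayes-optimal benchmark", {
  # Poisson-count population, rates 1 vs 3 for the preferred direction: the
  # decoder's log-tuning rule is compared with the exact likelihood-ratio
  # classifier built from the generative model
  set.seed(5)
  n <- 20
  pref <- rep(c("left", "right"), each = 10)
  rates <- function(d) ifelse(pref == d, 3, 1)
  tuning <- cbind(left = rates("left"), right = rates("right"))
  dec <- lick_decoder(tuning, epsilon = 1e-6)
  actual <- sample(c("left", "right"), 400, replace = TRUE)
  act <- t(vapply(actual, function(a) rpois(n, rates(a)), numeric(n)))
  perf <- decode_licks(dec, act, actual = actual, seed = 2)$performance
  # exact Bayes rule for Poisson: sum r log(rate_d) - sum rate_d
  ll <- function(d) act %*% log(rates(d)) - sum(rates(d))
  bayes <- ifelse(ll("right") > ll("left"), "right", "left")
  bayes_perf <- mean(bayes == actual)
  expect_lt(abs(perf - bayes_perf), 0.05)
})

test_that("pre/post window evaluation excludes trials with pre-window licks", {
  ses <- generate_session(session_config(n_trials = 120, task = "multimotor",
                                         seed = 55))
  cl <- classify_trials(ses$trials)
  cfg <- calcium_config(n_neurons = 8, preparatory_rate_hz = 0.4, seed = 55)
  cal <- generate_calcium(cfg, cl, ses$truth)
  z <- do.call(rbind, lapply(cal$neurons, function(nrn) {
    f <- neuropil_correct(nrn)
    zscore_trace(f, fit_noise_model(f, 30))
  }))
  tuning <- cbind(left = as.numeric(cal$truth$class == "left"),
                  right = as.numeric(cal$truth$class == "right"))
  dec <- lick_decoder(tuning, epsilon = 0.05)
  out <- decoder_performance_by_window(z, cl, dec, frame_rate_hz = 30,
                                       seed = 55)
  expect_true(out$n_trials > 0)
  expect_true(is.finite(out$pre$performance))
  expect_true(is.finite(out$post$performance))
  # the generator's quiet period means no violating trial exists here
  expect_identical(out$excluded_pre_lick, 0L)
  # a hand-built hit trial with a pre-window contact is excluded
  t_end <- max(cl$stim_time_s) + 20
  viol <- trial_row(trial_id = 999L, block_side = "right",
                    stim_time_s = t_end,
                    licks_right = c(t_end - 0.5, t_end + 0.3))
  viol <- classify_trials(viol, task = "multimotor")
  out2 <- decoder_performance_by_window(z, rbind(cl, viol),
                                        dec, frame_rate_hz = 30, seed = 55)
  expect_identical(out2$excluded_pre_lick, 1L)
  expect_identical(out2$n_trials, out$n_trials)
})
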