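# Trace smoothing, step detection, dwell extraction and ramp event reading
# on programmatically generated fixtures with known ground truth.

test_that("smoothing preserves constants and suppresses white noise", {
  flat <- mt_trace(seq(0, 4.995, by = 0.005), rep(10, 1000), rep(50, 1000))
  for (m in c("fft", "ma")) {
    sm <- smooth_trace(flat, 10, method = m)
    expect_equal(sm$height_nm, rep(50, 1000), tolerance = 1e-9)
  }
  set.seed(42)
  noisy <- mt_trace(seq(0, 49.995, by = 0.005), rep(10, 10000),
                    rnorm(10000, 0, 3))
  for (m in c("fft", "ma")) {
    sm <- smooth_trace(noisy, 10, method = m)
    ratio <- sd(noisy$height_nm) / sd(sm$height_nm)
    # variance reduction by about the window size -> sd by ~sqrt(10)
    expect_gt(ratio, 2.2)
    expect_lt(ratio, 4.5)
  }
  expect_error(smooth_trace(flat, 2000), "exceeds")
  expect_identical(smooth_trace(flat, 1), flat)
})

test_that("smoothing keeps a step edge within the window width", {
  tr <- make_step_trace(5, 30, duration = 10, sigma = 0, seed = 1)
  sm <- smooth_trace(tr, 10)
  # crossing of the half-step level stays within +/- window samples of truth
  cross <- which(sm$height_nm >= 15)[1]
  true_idx <- which(tr$time_s >= 5)[1]
  expect_lte(abs(cross - true_idx), 10)
})

test_that("step detection is exact on noiseless traces and robust in noise", {
  # noiseless two-level trace
  tr0 <- make_step_trace(5, 30, duration = 10, sigma = 0, seed = 1)
  fit0 <- detect_steps(tr0, min_step = 10)
  expect_equal(nrow(fit0$events), 1)
  expect_equal(fit0$events$step_nm, 30, tolerance = 1e-9)
  expect_equal(fit0$events$time_s, 5, tolerance = 1 / 200)
  # 30 nm step in 3 nm noise at 200 Hz
  tr <- make_step_trace(5, 30, duration = 10, sigma = 3, seed = 2)
  fit <- detect_steps(tr, min_step = 10)
  expect_equal(nrow(fit$events), 1)
  expect_equal(fit$events$step_nm, 30, tolerance = 3 / 30) # +/- 3 nm
  expect_lt(abs(fit$events$time_s - 5), 0.05)
  # flat noisy trace: no events, and that is not an error
  flat <- make_step_trace(numeric(0), numeric(0), sigma = 3, seed = 3)
  expect_equal(nrow(detect_steps(flat, min_step = 10)$events), 0)
})

test_that("detection is invariant to a constant height offset", {
  tr <- make_step_trace(c(3, 7), c(30, 140), duration = 12, sigma = 3,
                        seed = 4)
  shifted <- make_step_trace(c(3, 7), c(30, 140), duration = 12, sigma = 3,
                             seed = 4, offset = 1000)
  a <- detect_steps(tr, min_step = 10)$events
  b <- detect_steps(shifted, min_step = 10)$events
  expect_equal(a$time_s, b$time_s)
  expect_equal(a$step_nm, b$step_nm, tolerance = 1e-9)
})

test_that("programmed steps >= 20 nm are recovered across the noise range", {
  # across the instrument's height-uncertainty range, at least 95% of
  # programmed steps are found with size error within 2 sigma
  for (sigma in c(2, 3, 5)) {
    found <- 0L; total <- 0L
    for (i in 1:30) {
      size <- sample(c(20, 25, 30, 90, 140), 1)
      t_step <- runif(1, 2, 8)
      tr <- make_step_trace(t_step, size, duration = 10, sigma = sigma,
                            seed = 7000 + 100 * sigma + i)
      ev <- detect_steps(tr, min_step = 10)$events
      total <- total + 1L
      hit <- which(abs(ev$time_s - t_step) < 0.25 &
                     abs(ev$step_nm - size) <= 2 * sigma)
      if (length(hit)) found <- found + 1L
    }
    expect_gte(found / total, 0.95)
  }
})

test_that("the HMM fit resolves two-level hopping", {
  set.seed(9)
  # telegraph signal between 0 and 6 nm in 2 nm noise
  n <- 4000
  state <- integer(n); state[1] <- 0L
  for (i in 2:n) state[i] <- if (runif(1) < 0.01) 1L - state[i - 1] else state[i - 1]
  h <- state * 6 + rnorm(n, 0, 2)
  hm <- gaussian_hmm(h, K = 2)
  expect_equal(sort(hm$means), c(0, 6), tolerance = 0.15)
  expect_equal(mean(hm$path - 1), mean(state), tolerance = 0.05)
  # detect_steps with the hmm backend finds ~6 nm steps
  tr <- mt_trace(seq(0, (n - 1) / 200, by = 1 / 200), rep(2.5, n), h)
  fit <- detect_steps(tr, min_step = 2, method = "hmm", max_states = 2)
  expect_gt(nrow(fit$events), 5)
  expect_equal(median(abs(fit$events$step_nm)), 6, tolerance = 0.2)
})

test_that("dwell extraction reads hold windows and censors honestly", {
  fs <- 200
  mk_cycle_trace <- function(dwells, hold_dur = 20, low_dur = 2,
                             force = 45, step = 150, sigma = 2, seed = 1) {
    set.seed(seed)
    n_cyc <- length(dwells)
    cyc_n <- (low_dur + hold_dur) * fs
    tt <- (seq_len(cyc_n * n_cyc) - 1) / fs
    h <- numeric(length(tt)); ff <- numeric(length(tt))
    holds <- data.frame(start_s = numeric(n_cyc), end_s = numeric(n_cyc),
                        force_pN = force)
    for (c in seq_len(n_cyc)) {
      off <- (c - 1) * cyc_n
      lo <- off + seq_len(low_dur * fs); hi <- off + low_dur * fs +
        seq_len(hold_dur * fs)
      ff[lo] <- 1; ff[hi] <- force
      t_jump <- tt[hi[1]]
      if (is.finite(dwells[c]))
        h[hi] <- ifelse(tt[hi] >= t_jump + dwells[c], step, 40)
      else h[hi] <- 40
      holds$start_s[c] <- t_jump; holds$end_s[c] <- tt[hi[length(hi)]]
    }
    h <- h + rnorm(length(h), 0, sigma)
    mt_trace(tt, ff, h, fs, metadata = list(holds = holds))
  }
  pr <- force_protocol("jump", hold_force = 45, hold_duration = 20,
                       low_duration = 2, n_cycles = 3)
  tr <- mk_cycle_trace(c(12.3, Inf, 5.7))
  dw <- extract_dwell_times(tr, pr, min_step = 20)
  expect_equal(nrow(dw), 3)
  expect_equal(dw$dwell_s[1], 12.3, tolerance = 2 / fs)
  expect_true(dw$censored[2])
  expect_equal(dw$dwell_s[2], 20, tolerance = 2 / fs)
  expect_equal(dw$dwell_s[3], 5.7, tolerance = 2 / fs)
  # empty input and missing metadata
  expect_equal(nrow(extract_dwell_times(list(), pr)), 0)
  bare <- mt_trace(0:9 / fs, rep(45, 10), rnorm(10))
  expect_error(extract_dwell_times(bare, pr), "hold-phase")
  expect_error(extract_dwell_times(tr, force_protocol("constant", force = 45)),
               "jump")
})

test_that("ramp events read the force at the step and enforce monotonicity", {
  fs <- 200; rate <- 5
  tt <- seq(0, 20 - 1 / fs, by = 1 / fs)
  ff <- 1 + rate * tt
  set.seed(11)
  # rupture programmed at 65 pN with a 140 nm step
  h <- ifelse(ff >= 65, 140, 0) + rnorm(length(tt), 0, 3)
  tr <- mt_trace(tt, ff, h, fs)
  ev <- rupture_events_from_ramp(tr, rate, min_step = 20)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$force_pN, 65, tolerance = 0.5 / 65)
  # two-step cascade stays ordered
  h2 <- ifelse(ff >= 40, 30, 0) + ifelse(ff >= 65, 140, 0) +
    rnorm(length(tt), 0, 3)
  ev2 <- rupture_events_from_ramp(mt_trace(tt, ff, h2, fs), rate,
                                  min_step = 20)
  expect_equal(nrow(ev2), 2)
  expect_true(all(diff(ev2$time_s) > 0))
  expect_equal(ev2$force_pN, c(40, 65), tolerance = 0.02)
  # no steps -> empty, non-monotone force -> error
  flat <- mt_trace(tt, ff, rnorm(length(tt), 0, 3), fs)
  expect_equal(nrow(rupture_events_from_ramp(flat, rate, min_step = 20)), 0)
  wob <- mt_trace(tt, ff + c(0, rep(c(2, -2), length.out = length(tt) - 1)),
                  h, fs)
  expect_error(rupture_events_from_ramp(wob, rate), "not monotone")
})

test_that("events are classified by the nearest predicted step", {
  cs <- construct_presets("actn1_shear_full")
  ev <- data.frame(force_pN = c(45, 45), step_nm = c(31, 150))
  cl <- classify_events(ev, cs)
  expect_equal(cl$label, c("unfold_one", "rupture_unfold_rest"))
})
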