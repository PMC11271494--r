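# The synthetic-data generators: dwell tables, clustered sub-states and
# full bead-height traces with ground truth.

test_that("generated dwells are exponential at the Bell rate", {
  b <- bell_params(0.1, 0)  # force-independent, rate 0.1/s
  d <- generate_dwells(b, 10, 10000, rng_seed = 3)
  expect_lt(abs(mean(d$dwell_s) - 10), 0.3)
  expect_false(any(d$censored))
  # heavy censoring
  slow <- generate_dwells(bell_params(1e-6, 0), 10, 200, censor_at = 1,
                          rng_seed = 4)
  expect_true(all(slow$censored))
  expect_true(all(slow$dwell_s == 1))
  # reproducible under a fixed seed
  expect_identical(generate_dwells(b, 10, 50, rng_seed = 11)$dwell_s,
                   generate_dwells(b, 10, 50, rng_seed = 11)$dwell_s)
})

test_that("clustered dwells interconvert slowly between sub-states", {
  subs <- list(list(params = bell_params(1, 0), weight = 0.5),
               list(params = bell_params(0.01, 0), weight = 0.5))
  d <- generate_clustered_dwells(subs, switch_prob = 0.05, force = 10,
                                 n = 2000, rng_seed = 6)
  # bimodal log-dwell distribution: both populations present in proportion
  expect_gt(min(table(d$substate)) / 2000, 0.2)
  # sub-state labels are block-correlated (few switches)
  expect_lt(mean(diff(d$substate) != 0), 0.15)
  # per-cluster means match the generating rates
  expect_equal(mean(d$dwell_s[d$substate == 1]), 1, tolerance = 0.2)
  expect_equal(mean(d$dwell_s[d$substate == 2]), 100, tolerance = 0.2)
  # no switching: everything stays in the initial sub-state
  d0 <- generate_clustered_dwells(subs, 0, 10, 100, rng_seed = 7)
  expect_equal(length(unique(d0$substate)), 1)
  # single sub-state reduces to the plain generator
  d1 <- generate_clustered_dwells(list(list(params = bell_params(0.1, 0),
                                            weight = 1)),
                                  0.5, 10, 3000, rng_seed = 8)
  expect_lt(abs(mean(d1$dwell_s) - 10), 0.6)
  expect_error(generate_clustered_dwells(subs, 1.5, 10, 10), "\\[0, 1\\]")
})

test_that("noiseless traces step by exactly the state extension difference", {
  cs <- construct_presets("actn1_shear_full")
  pr <- force_protocol("constant", force = 45, duration = 30)
  g <- generate_trace(cs, bell_params(0.3, 0), pr, noise_model(0),
                      rng_seed = 12)
  expect_gte(nrow(g$truth), 1)
  fit <- detect_steps(g$trace, min_step = 20)
  expect_equal(nrow(fit$events), 1)
  expect_equal(fit$events$step_nm, g$truth$step_nm[1], tolerance = 1e-9)
  # with all four domains unfolding on rupture, the generated step equals
  # the composite state height difference at the clamp force
  nd <- 4
  before <- tether_state(TRUE, "shielded", n_domains = nd)
  after <- tether_state(FALSE, "unfolded", n_domains = nd)
  manual <- (series_extension(state_to_series(cs, after), 45)) -
    (series_extension(state_to_series(cs, before), 45) + cs$loop_end_to_end)
  expect_equal(g$truth$step_nm[1], manual, tolerance = 1e-9)
})

test_that("trace generation is byte-identical under a fixed seed", {
  cs <- construct_presets("actn1_shear_full")
  pr <- force_protocol("jump", hold_force = 40, hold_duration = 10,
                       low_duration = 1, n_cycles = 3)
  g1 <- generate_trace(cs, bell_params(0.02, 0.2), pr, noise_model(3),
                       rng_seed = 21)
  g2 <- generate_trace(cs, bell_params(0.02, 0.2), pr, noise_model(3),
                       rng_seed = 21)
  expect_identical(g1$trace$height_nm, g2$trace$height_nm)
  expect_identical(g1$truth, g2$truth)
})

test_that("jump-cycle traces carry hold windows and transient artifacts", {
  cs <- construct_presets("actn1_shear_full")
  pr <- force_protocol("jump", hold_force = 45, hold_duration = 15,
                       low_duration = 2, n_cycles = 4)
  g <- generate_trace(cs, bell_params(0.005, 0), pr, noise_model(0),
                      rng_seed = 31, jump_artifact_nm = 6)
  holds <- attr(g$trace, "metadata")$holds
  expect_equal(nrow(holds), 4)
  expect_equal(holds$force_pN, rep(45, 4))
  # the artifact is present right after the jump but absent from the truth
  i0 <- which(g$trace$time_s >= holds$start_s[1])[1]
  base <- g$trace$height_nm[i0 + 100]  # 0.5 s after the jump
  expect_gt(g$trace$height_nm[i0] - base, 3)
  expect_false(any(abs(g$truth$time_s - holds$start_s) < 1e-9))
})

test_that("hopping traces occupy two levels in proportion to the rates", {
  cs <- construct_presets("sr23_sr23")
  pk <- pair_kinetics(bell_params(0.6, 1), bell_params(30, -4))
  f <- 2.5
  pr <- force_protocol("constant", force = f, duration = 60)
  g <- generate_trace(cs, pk, pr, noise_model(1), rng_seed = 41)
  k_off <- bell_rate(pk$unpair, f)
  k_on <- bell_rate(pk$repair, f)
  # fraction of time spent ruptured matches k_off / (k_off + k_on)
  lvl <- g$trace$height_nm > mean(range(g$trace$height_nm))
  expect_equal(mean(lvl), k_off / (k_off + k_on), tolerance = 0.15)
  # suitable for two-state HMM fitting
  fit <- detect_steps(g$trace, min_step = 2, method = "hmm", max_states = 2)
  expect_gt(nrow(fit$events), 10)
})

test_that("ramp traces rupture near the most probable force", {
  cs <- construct_presets("actn1_shear_full")
  pr <- force_protocol("ramp", from = 1, to = 100, rate = 5)
  b <- bell_params(1e-3, 0.5)
  forces <- vapply(1:15, function(i) {
    g <- generate_trace(cs, b, pr, noise_model(3), rng_seed = 100 + i)
    ev <- rupture_events_from_ramp(g$trace, 5, min_step = 40)
    if (nrow(ev)) ev$force_pN[1] else NA_real_
  }, numeric(1))
  expect_gte(sum(!is.na(forces)), 14)
  # Evans-Ritchie modal force ~52 pN; sample mean lies in a loose band
  expect_gt(mean(forces, na.rm = TRUE), 40)
  expect_lt(mean(forces, na.rm = TRUE), 65)
})
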