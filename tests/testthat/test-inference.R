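# Lifetime estimation, the M-resample bootstrap, Bell fitting, force
# histograms and the re-dimerization logistic.

test_that("censored-exponential MLE has its closed forms", {
  expect_equal(fit_lifetime(dwell_records(45, c(2, 2, 2)))$tau_s, 2)
  # one 5 s rupture plus a 20 s censored hold: tau = (5 + 20) / 1
  est <- fit_lifetime(dwell_records(45, c(5, 20), censored = c(FALSE, TRUE)))
  expect_equal(est$tau_s, 25)
  expect_equal(est$k_rupture * est$tau_s, 1)
  # large-sample consistency
  set.seed(31)
  d <- dwell_records(20, rexp(5000, 1 / 10))
  expect_lt(abs(fit_lifetime(d)$tau_s - 10), 3 * 10 / sqrt(5000))
  # fully censored data flag an unbounded estimate instead of erroring
  allc <- fit_lifetime(dwell_records(45, c(30, 30), censored = TRUE))
  expect_true(allc$unbounded)
  expect_equal(allc$tau_s, Inf)
})

test_that("bootstrap lifetime estimates behave like a resampling scheme", {
  # identical dwells: zero spread
  same <- dwell_records(45, rep(3, 25))
  b <- bootstrap_rates(same, bootstrap_config(20, rng_seed = 1))
  expect_equal(b$k_sd, 0)
  expect_equal(b$tau_mean, 3)
  # fixed seed: bit-identical estimates
  d <- generate_dwells(bell_params(0.05, 0.4), 30, 60, rng_seed = 5)
  b1 <- bootstrap_rates(d, bootstrap_config(20, rng_seed = 7))
  b2 <- bootstrap_rates(d, bootstrap_config(20, rng_seed = 7))
  expect_identical(b1$boot_k, b2$boot_k)
  # bootstrap spread tracks the sampling error tau/sqrt(N) within factor 2
  set.seed(17)
  d200 <- dwell_records(25, rexp(200, 1 / 10))
  bb <- bootstrap_rates(d200, bootstrap_config(20, rng_seed = 3))
  theo <- 10 / sqrt(200)
  expect_gt(bb$tau_sd, theo / 2)
  expect_lt(bb$tau_sd, theo * 2)
  # the bootstrap mean converges to the point MLE as M grows
  big <- bootstrap_rates(d200, bootstrap_config(500, rng_seed = 9))
  expect_equal(big$k_mean, fit_lifetime(d200)$k_rupture, tolerance = 0.02)
  # the figure-style cumulative-probability fit agrees with the MLE
  be <- bootstrap_rates(d200, bootstrap_config(50, rng_seed = 11),
                        estimator = "ecdf")
  expect_equal(be$k_mean, fit_lifetime(d200)$k_rupture, tolerance = 0.1)
  expect_error(bootstrap_rates(dwell_records(45, 3), bootstrap_config(20)),
               "at least 2")
  expect_error(bootstrap_config(1), ">= 2")
})

test_that("Bell fitting is exact on noiseless rates and equivariant", {
  env <- polymer_env()
  truth <- bell_params(1e-3, 0.5)
  f <- c(10, 20, 30, 40, 50)
  pts <- data.frame(force_pN = f, k = bell_rate(truth, f))
  fit <- fit_bell(pts)
  expect_equal(coef(fit)[["k0"]], 1e-3, tolerance = 1e-10)
  expect_equal(coef(fit)[["delta"]], 0.5, tolerance = 1e-10)
  # two points determine the line exactly
  fit2 <- fit_bell(pts[c(1, 5), ])
  expect_equal(unname(coef(fit2)), c(1e-3, 0.5), tolerance = 1e-10)
  # shifting the force axis by c multiplies k0 by exp(-delta c / kBT)
  shifted <- data.frame(force_pN = f + 7, k = pts$k)
  fs <- fit_bell(shifted)
  expect_equal(coef(fs)[["delta"]], 0.5, tolerance = 1e-10)
  expect_equal(coef(fs)[["k0"]], 1e-3 * exp(-0.5 * 7 / env$kBT),
               tolerance = 1e-8)
  # predictions invert to lifetimes
  expect_equal(predict(fit, 30, type = "lifetime"),
               1 / bell_rate(truth, 30), tolerance = 1e-8)
  expect_error(fit_bell(data.frame(force_pN = c(1, 2), k = c(-1, 2))),
               "positive")
  expect_error(fit_bell(pts[1, ]), ">= 2")
})

test_that("the dwell-to-Bell pipeline recovers generating parameters", {
  truth <- bell_params(1e-3, 0.5)
  dws <- make_dwell_table(truth, c(20, 30, 40, 50, 60), 50, seed = 4)
  fit <- bell_from_dwells(dws, bootstrap_config(20, rng_seed = 4))
  expect_lt(abs(coef(fit)[["delta"]] - 0.5), 2 * fit$se[["delta"]])
  expect_lt(abs(log(coef(fit)[["k0"]] / 1e-3)),
            2 * fit$se[["k0"]] / coef(fit)[["k0"]] + 2 * 0.5)
  expect_equal(nrow(fit$boot), 20)
  # deterministic under the seed
  fit2 <- bell_from_dwells(dws, bootstrap_config(20, rng_seed = 4))
  expect_identical(fit$boot, fit2$boot)
})

test_that("force histograms yield Gaussian peaks", {
  set.seed(23)
  x <- rnorm(2000, 50, 5)
  pk <- fit_force_histogram(x, 1)
  expect_equal(pk$mean_pN, 50, tolerance = 0.4 / 50)
  expect_equal(pk$sd_pN, 5, tolerance = 0.1)
  # well-separated mixture
  y <- c(rnorm(1200, 40, 3), rnorm(800, 65, 3))
  pk2 <- fit_force_histogram(y, 2)
  expect_equal(pk2$mean_pN, c(40, 65), tolerance = 0.01)
  expect_equal(pk2$weight, c(0.6, 0.4), tolerance = 0.05)
  expect_error(fit_force_histogram(rep(5, 20), 1), "degenerate")
  expect_error(fit_force_histogram(rnorm(5), 1), "at least 10")
})

test_that("the re-dimerization logistic is recovered and complementary", {
  env <- polymer_env()
  f <- seq(1, 6, by = 0.5)
  p <- 1 / (exp((f - 2.7) * 5 / env$kBT) + 1)
  fit <- fit_redimerization(data.frame(force_pN = f, probability = p))
  expect_equal(coef(fit)[["Fc"]], 2.7, tolerance = 1e-6)
  expect_equal(coef(fit)[["delta_x"]], 5, tolerance = 1e-6)
  # half-transition exactly at Fc; rupture is the complement everywhere
  expect_equal(predict(fit, 2.7), 0.5)
  expect_equal(predict(fit, f, type = "rupture") +
                 predict(fit, f, type = "redimerization"), rep(1, length(f)))
  # noisy grid still localises Fc
  set.seed(13)
  pn <- pmin(pmax(p + rnorm(length(p), 0, 0.05), 0), 1)
  fitn <- fit_redimerization(data.frame(force_pN = f, probability = pn))
  expect_lt(abs(coef(fitn)[["Fc"]] - 2.7), 0.2)
  expect_error(fit_redimerization(data.frame(force_pN = 1:2,
                                             probability = c(0.9, 0.1))),
               "at least 3")
  expect_error(fit_redimerization(data.frame(force_pN = 1:3,
                                             probability = c(1.2, 0.5, 0))),
               "\\[0, 1\\]")
})

test_that("exponential mixtures separate well-spaced dwell populations", {
  set.seed(41)
  x <- c(rexp(300, 1), rexp(300, 0.01))
  fit <- exp_mixture_fit(x, 2)
  expect_equal(fit$rates[1], 1, tolerance = 0.3)
  expect_equal(fit$rates[2], 0.01, tolerance = 0.3)
  expect_equal(fit$weights, c(0.5, 0.5), tolerance = 0.1)
})
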