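# Bell rates, exact first-passage lifetimes of the multivalent dimer model,
# and the Gillespie/ramp simulators checked against their closed-form and
# linear-solve oracles.

test_that("Bell rate follows the exponential force dependence", {
  b <- bell_params(1e-3, 0.8)
  expect_equal(bell_rate(b, 0), 1e-3)
  expect_equal(bell_rate(b, 20), 0.050723, tolerance = 1e-4)
  # force-independent when delta = 0
  expect_equal(bell_rate(bell_params(2, 0), c(0, 50, 500)), rep(2, 3))
  # overflow guard: finite and capped at extreme forces
  expect_true(is.finite(bell_rate(b, 1e6)))
  expect_lte(bell_rate(bell_params(1, 5), 1e5), 1e12)
  expect_error(bell_rate(b, -1), "non-negative")
  expect_error(bell_params(-1, 0.5), "non-negative")
  expect_error(pair_kinetics(bell_params(1, 0.5), bell_params(1, 0.5)),
               "<= 0")
  expect_error(domain_kinetics(bell_params(1, 0.5), bell_params(1, 2)),
               "<= 0")
})

test_that("exact mean lifetime reduces to closed forms", {
  env <- polymer_env()
  up <- bell_params(0.1, 0.5)
  # one irreversible pair: single exponential step
  m1 <- multivalent_dimer_model(1, pair_kinetics(up))
  expect_equal(mean_lifetime_exact(m1, 10), 1 / bell_rate(up, 10))
  # irreversible peeling from one end: sum of n identical stage times
  k10 <- bell_rate(up, 10)
  m3 <- multivalent_dimer_model(3, pair_kinetics(up), peel_from = "one")
  expect_equal(mean_lifetime_exact(m3, 10), 3 / k10, tolerance = 1e-10)
  # peeling from both ends: stage rates 2k, 2k, k
  m3b <- multivalent_dimer_model(3, pair_kinetics(up), peel_from = "both")
  expect_equal(mean_lifetime_exact(m3b, 10), 1 / (2 * k10) * 2 + 1 / k10,
               tolerance = 1e-10)
  # fast re-pairing amplifies the lifetime far beyond a single pair
  m2 <- multivalent_dimer_model(
    2, pair_kinetics(up, bell_params(50, -0.5)))
  expect_gt(mean_lifetime_exact(m2, 10), 10 * mean_lifetime_exact(m1, 10))
  # rupture must be reachable
  dead <- multivalent_dimer_model(2, pair_kinetics(bell_params(0, 0.5)))
  expect_error(mean_lifetime_exact(dead, 10), "unreachable|singular")
})

test_that("mean lifetime decreases with force for rupture-ward slip bonds", {
  m <- multivalent_dimer_model(
    2, pair_kinetics(bell_params(0.1, 0.5), bell_params(5, -0.5)),
    domain_kinetics(bell_params(0.05, 0.8), bell_params(1, -1)))
  lt <- mean_lifetime_exact(m, c(2, 5, 10, 20, 40))
  expect_true(all(diff(lt) < 0))
})

test_that("Gillespie trajectories agree with the exact first-passage oracle", {
  up <- bell_params(0.5, 0.3)
  # one irreversible pair at 10 pN
  m1 <- multivalent_dimer_model(1, pair_kinetics(up))
  s1 <- simulate_constant_force(m1, 10, 1000, rng_seed = 11,
                                record_events = FALSE)
  mu1 <- mean_lifetime_exact(m1, 10)
  se1 <- stats::sd(s1$times) / sqrt(1000)
  expect_lt(abs(mean(s1$times) - mu1), 3 * se1)
  # two reversible pairs
  m2 <- multivalent_dimer_model(2, pair_kinetics(up, bell_params(2, -0.3)))
  s2 <- simulate_constant_force(m2, 10, 1000, rng_seed = 12,
                                record_events = FALSE)
  mu2 <- mean_lifetime_exact(m2, 10)
  se2 <- stats::sd(s2$times) / sqrt(1000)
  expect_lt(abs(mean(s2$times) - mu2), 3 * se2)
  # determinism under a fixed seed
  a <- simulate_constant_force(m2, 10, 50, rng_seed = 99)
  b <- simulate_constant_force(m2, 10, 50, rng_seed = 99)
  expect_identical(a$times, b$times)
  expect_identical(a$events, b$events)
  # all-zero rates give censored results, not an exception
  frozen <- multivalent_dimer_model(1, pair_kinetics(bell_params(0, 0)))
  sf <- simulate_constant_force(frozen, 10, 3, rng_seed = 1)
  expect_true(all(sf$censored))
  expect_true(all(is.na(sf$times)))
})

test_that("event sequences respect the boundary-peeling rule", {
  up <- bell_params(0.5, 0.3)
  m3 <- multivalent_dimer_model(3, pair_kinetics(up, bell_params(1, -0.3)))
  s <- simulate_constant_force(m3, 10, 20, rng_seed = 5)
  for (ev in s$events) {
    unpaired <- logical(3)
    for (r in seq_len(nrow(ev))) {
      p <- ev$pair[r]
      if (ev$type[r] == "unpair") {
        # only end-most intact pairs may un-pair
        intact <- which(!unpaired)
        expect_true(p %in% range(intact))
        unpaired[p] <- TRUE
      } else if (ev$type[r] == "repair") {
        intact <- which(!unpaired)
        expect_true(p == min(intact) - 1 || p == max(intact) + 1)
        unpaired[p] <- FALSE
      }
    }
  }
})

test_that("ramp rupture follows the most-probable-force closed form", {
  b <- bell_params(1e-3, 0.5)
  env <- polymer_env()
  expect_equal(evans_ritchie_modal_force(b, 5), 52.3163, tolerance = 1e-4)
  # doubling the loading rate shifts the modal force by kBT/delta * ln 2
  expect_equal(evans_ritchie_modal_force(b, 10) -
                 evans_ritchie_modal_force(b, 5),
               env$kBT / 0.5 * log(2), tolerance = 1e-10)
  # larger transition distance: rupture earlier and in a narrower band
  pr <- force_protocol("ramp", from = 0, to = 120, rate = 5)
  s_small <- simulate_ramp(bell_params(1e-3, 0.3), pr, 400, rng_seed = 21)
  s_large <- simulate_ramp(bell_params(1e-3, 1.5), pr, 400, rng_seed = 22)
  expect_lt(mean(s_large$forces), mean(s_small$forces))
  expect_lt(stats::sd(s_large$forces), stats::sd(s_small$forces))
  # same seed, same forces
  expect_identical(simulate_ramp(b, pr, 30, rng_seed = 7)$forces,
                   simulate_ramp(b, pr, 30, rng_seed = 7)$forces)
  expect_error(force_protocol("ramp", from = 0, to = 100, rate = -5),
               "towards")
})

test_that("multivalency amplifies lifetimes monotonically in pair count", {
  pairk <- pair_kinetics(bell_params(0.5, 0.3), bell_params(2, -0.3))
  tab <- lifetime_vs_pairs(pairk, n_pairs = 1:4, forces = c(5, 10, 20))
  for (f in unique(tab$force_pN)) {
    lt <- tab$mean_lifetime_s[tab$force_pN == f]
    expect_true(all(diff(lt) > 0), info = sprintf("force %g", f))
  }
  # table entries equal the exact solver
  m3 <- multivalent_dimer_model(3, pairk)
  expect_equal(tab$mean_lifetime_s[tab$n_pairs == 3 & tab$force_pN == 10],
               mean_lifetime_exact(m3, 10))
  # without re-pairing the lifetime is the sum of stage waits
  irrev <- pair_kinetics(bell_params(0.5, 0.3))
  k <- bell_rate(bell_params(0.5, 0.3), 10)
  tab0 <- lifetime_vs_pairs(irrev, n_pairs = 2, forces = 10,
                            peel_from = "one")
  expect_equal(tab0$mean_lifetime_s, 2 / k, tolerance = 1e-10)
})
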