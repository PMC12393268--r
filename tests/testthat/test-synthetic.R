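test_that("photon simulation is deterministic under a seed and obeys trace invariants", {
  m <- molecule_model(distance_nm = 8.4, donor_bleach_time_s = 1.5,
                      acceptor_bleach_time_s = 0.8)
  inst <- instrument_model()
  a <- simulate_molecule(m, inst, duration_s = 2, seed = 11)
  b <- simulate_molecule(m, inst, duration_s = 2, seed = 11)
  expect_identical(a, b)
  expect_true(all(diff(a$macrotimes_s) > 0))
  expect_true(all(a$microtimes_ns >= 0 & a$microtimes_ns < inst$tcspc_window_ns))
  expect_true(all(a$channels %in% c("donor", "acceptor")))
  c2 <- simulate_molecule(m, inst, duration_s = 2, seed = 12)
  expect_false(identical(a$macrotimes_s, c2$macrotimes_s))
})

test_that("a molecule bleached at time zero with no background yields an empty trace", {
  m <- molecule_model(distance_nm = 8.4, background_rate_hz = 0,
                      donor_bleach_time_s = 0, acceptor_bleach_time_s = 0)
  tr <- simulate_molecule(m, instrument_model(), duration_s = 1, seed = 1)
  expect_length(tr$macrotimes_s, 0)
  m$donor_rate_hz <- Inf
  expect_error(simulate_molecule(m, instrument_model(), 1, seed = 1),
               "non-finite")
})

test_that("at r = r0 (E = 0.5) the mean donor microtime is tau_D/2 under a delta IRF", {
  tau_d <- 3.0
  m <- molecule_model(distance_nm = 8.4, forster_radius_nm = 8.4,
                      donor_only_lifetime_ns = tau_d, background_rate_hz = 0,
                      donor_rate_hz = 4000,
                      donor_bleach_time_s = 120, acceptor_bleach_time_s = 120)
  expect_equal(m$efficiency, 0.5)
  inst <- delta_instrument(center = 0)
  tr <- simulate_molecule(m, inst, duration_s = 60, seed = 3)
  micro <- tr$microtimes_ns[tr$channels == "donor"]
  expect_gt(length(micro), 1e5)
  tau <- tau_d * 0.5
  ## window truncation shifts the mean by W e^{-W/tau}/(1 - e^{-W/tau})
  W <- inst$tcspc_window_ns
  expected <- tau - W * exp(-W / tau) / (1 - exp(-W / tau))
  expect_lt(abs(mean(micro) - expected), 3 * tau / sqrt(length(micro)))
})

test_that("donor count rate before acceptor bleach scales as donor_rate * (1 - E)", {
  m <- molecule_model(distance_nm = 8.4, background_rate_hz = 0,
                      donor_rate_hz = 4000,
                      donor_bleach_time_s = 100, acceptor_bleach_time_s = 50)
  tr <- simulate_molecule(m, instrument_model(), duration_s = 50, seed = 5)
  n_d <- sum(tr$channels == "donor")
  expect_gt(n_d, 1e4)
  rate <- n_d / 50
  target <- 4000 * (1 - m$efficiency)
  expect_lt(abs(rate - target), 3 * sqrt(target * 50) / 50)
})

test_that("delta-IRF microtimes pass a one-sample exponentiality check", {
  tau <- 1.5
  m <- molecule_model(tau_da_ns = tau, background_rate_hz = 0,
                      donor_rate_hz = 2000,
                      donor_bleach_time_s = 100, acceptor_bleach_time_s = 100)
  inst <- delta_instrument(center = 0)
  tr <- simulate_molecule(m, inst, duration_s = 10, seed = 7)
  micro <- tr$microtimes_ns[tr$channels == "donor"][1:10000]
  W <- inst$tcspc_window_ns
  ptrunc <- function(q) (1 - exp(-q / tau)) / (1 - exp(-W / tau))
  ks <- suppressWarnings(stats::ks.test(micro, ptrunc))
  expect_gt(ks$p.value, 0.01)
})

test_that("condition ensembles honour the open fraction and the mixture mean", {
  expect_error(simulate_condition(10, 1.2, seed = 1), "open_fraction")
  allopen <- simulate_condition(15, 1, seed = 1, target_donor_photons = 200,
                                post_bleach_s = 0.1, tail_s = 0.1)
  expect_true(all(allopen$labels$state == "open"))

  sim <- simulate_condition(200, 0.74, seed = 2, target_donor_photons = 200,
                            post_bleach_s = 0.1, tail_s = 0.1)
  phat <- mean(sim$labels$state == "open")
  expect_lt(abs(phat - 0.74), 2.58 * sqrt(0.74 * 0.26 / 200))  # binomial 99% CI
  tau <- sim$labels$expected_lifetime_ns
  target <- (1 - 0.74) * 1.3 + 0.74 * 2.7
  expect_lt(abs(mean(tau) - target), 3 * stats::sd(tau) / sqrt(length(tau)))
})

test_that("umbrella windows sample the biased density exactly", {
  ## flat surface: pure harmonic => Gaussian(c, 1/k)
  w <- simulate_umbrella_windows(function(x) 0 * x, centers = 1.5,
                                 spring_k = 25, n_samples = 4000, seed = 4)
  s <- w[[1]]$samples
  expect_lt(abs(mean(s) - 1.5), 3 / sqrt(25 * 4000))
  expect_lt(abs(stats::var(s) - 1 / 25), 3 * sqrt(2 / 4000) / 25)

  ## quadratic surface (a/2)x^2 with bias at c: Gaussian mean k c / (a + k)
  a <- 10; k <- 40; c0 <- 0.8
  w2 <- simulate_umbrella_windows(function(x) a / 2 * x^2, centers = c0,
                                  spring_k = k, n_samples = 4000, seed = 9,
                                  domain = c(-3, 3))
  s2 <- w2[[1]]$samples
  expect_lt(abs(mean(s2) - k * c0 / (a + k)), 3 / sqrt((a + k) * 4000))

  expect_identical(simulate_umbrella_windows(function(x) 0 * x, 0, 25, 100, 5),
                   simulate_umbrella_windows(function(x) 0 * x, 0, 25, 100, 5))
  expect_error(simulate_umbrella_windows(function(x) 0 * x, numeric(0), 25, 10, 1),
               "empty")
  expect_error(simulate_umbrella_windows(function(x) ifelse(x > 0, Inf, 0),
                                         0, 25, 10, 1, domain = c(-1, 1)),
               "finite")
})

test_that("bead frames are reproducible, fully labelled, and honour overrides", {
  f1 <- simulate_bead_frames(3, 50, 10, 20, seed = 6, n_other_beads = 5)
  f2 <- simulate_bead_frames(3, 50, 10, 20, seed = 6, n_other_beads = 5)
  expect_identical(f1, f2)
  expect_true(all(f1[[1]]$group %in% c("lipid", "atp_site", "other")))
  expect_length(f1[[1]]$group, 65)
  expect_equal(nrow(f1[[1]]$coordinates), 65)

  ov <- data.frame(bead_id = 1:2, residue = c(721, 1186),
                   group = c("protein", "protein"),
                   x = c(0, 30), y = c(0, 40), z = c(0, 0))
  fr <- simulate_bead_frames(1, 1, 1, 10, seed = 1, coords_override = ov)[[1]]
  expect_equal(fr$coordinates[, 1], c(0, 30))
  expect_equal(residue_distance(fr), 50)
})
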