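test_that("bunching is exact, discards remainders, and never spans levels", {
  lev <- mk_level(2500)
  b <- bunch_photons(lev, 1000)
  expect_length(b, 2)
  expect_equal(b[[1]], c(0, 1000))
  expect_equal(b[[2]], c(1000, 2000))
  expect_length(bunch_photons(mk_level(999), 1000), 0)
  ## concatenation is gap-free from the first photon of the level
  lev2 <- mk_level(3200, start = 17L)
  b2 <- bunch_photons(lev2, 1000)
  expect_equal(b2[[1]][1], 17)
  for (i in seq_len(length(b2) - 1)) expect_equal(b2[[i]][2], b2[[i + 1]][1])
  expect_error(bunch_photons(lev, 50), ">= 100")
})

test_that("delta-IRF maximum-likelihood lifetime equals the sample mean", {
  inst <- delta_instrument(center = 0)
  micro <- fretstates:::with_seed(31, sim_microtimes(2000, 1.5, fwhm = 0, center = 0))
  est <- fit_bunch_mle(micro, inst, background_fraction = 0)
  expect_false(est$flagged)
  expect_lt(abs(est$lifetime_ns - mean(micro)) / mean(micro), 0.01)
})

test_that("bunch MLE recovers lifetimes at the information limit", {
  ## 3x the model's Cramer-Rao sd (0.126 ns for tau = 3 ns, 12.5 ns window,
  ## FWHM 0.3 ns, 5% background, n = 1000)
  inst <- instrument_model()
  errs <- vapply(1:300, function(r) {
    micro <- fretstates:::with_seed(6000 + r,
                                    sim_microtimes(1000, 3.0, b = 0.05))
    fit_bunch_mle(micro, inst, background_fraction = 0.05)$lifetime_ns - 3.0
  }, numeric(1))
  expect_gte(mean(abs(errs) < 0.378), 0.99)
  expect_lt(abs(mean(errs)), 0.05)

  for (tau in c(1.3, 2.7)) {  # bias stays small across the fitted peaks
    e <- vapply(1:200, function(r) {
      micro <- fretstates:::with_seed(7000 + 1000 * tau + r,
                                      sim_microtimes(1000, tau, b = 0.05))
      fit_bunch_mle(micro, inst, background_fraction = 0.05)$lifetime_ns - tau
    }, numeric(1))
    expect_lt(abs(mean(e)), 0.05)
  }
})

test_that("degenerate input pins the estimate at the lower bound, flagged", {
  est <- fit_bunch_mle(rep(2.5, 500), instrument_model())
  expect_true(est$flagged)
  expect_equal(est$lifetime_ns, 0.05)
})

test_that("the fitted lifetime is a local optimum, invariant to photon order", {
  inst <- instrument_model()
  micro <- fretstates:::with_seed(41, sim_microtimes(1000, 2.0, b = 0.05))
  est <- fit_bunch_mle(micro, inst, background_fraction = 0.05)
  ll <- function(tau) fretstates:::decay_loglik(micro, tau, inst, 0.05)
  expect_gte(est$loglik, ll(est$lifetime_ns + 1e-5) - 1e-9)
  expect_gte(est$loglik, ll(est$lifetime_ns - 1e-5) - 1e-9)
  est2 <- fit_bunch_mle(fretstates:::with_seed(1, sample(micro)), inst,
                        background_fraction = 0.05)
  expect_equal(est$lifetime_ns, est2$lifetime_ns, tolerance = 1e-9)
})

test_that("Gaussian closed form and tabulated IRF convolution agree", {
  fwhm <- 0.3; center <- 0.5
  sig <- fwhm / (2 * sqrt(2 * log(2)))
  tg <- seq(center - 6 * sig, center + 6 * sig, by = 0.004)
  tab <- instrument_model(irf_table = data.frame(time_ns = tg,
                                                 weight = stats::dnorm(tg, center, sig)))
  gau <- instrument_model(irf_fwhm_ns = fwhm, irf_center_ns = center)
  micro <- fretstates:::with_seed(51, sim_microtimes(2000, 2.5, b = 0.05))
  t_gau <- fit_bunch_mle(micro, gau, background_fraction = 0.05)$lifetime_ns
  t_tab <- fit_bunch_mle(micro, tab, background_fraction = 0.05)$lifetime_ns
  expect_lt(abs(t_gau - t_tab), 1e-3)
})

test_that("decay histograms conserve photons and match the model density", {
  micro <- fretstates:::with_seed(61, sim_microtimes(1000, 2.0))
  h <- build_decay_histogram(micro, 250)
  expect_equal(sum(h$counts), 1000)
  expect_error(build_decay_histogram(micro, 1), ">= 2")

  h0 <- build_decay_histogram(rep(0.01, 50), 25)
  expect_equal(h0$counts[1], 50L)

  ## chi-square goodness of fit of simulated photons against the model
  inst <- instrument_model()
  micro2 <- fretstates:::with_seed(62, sim_microtimes(20000, 2.0, b = 0.05))
  nb <- 50
  h2 <- build_decay_histogram(micro2, nb)
  fine <- seq(0.0005, 12.5 - 0.0005, by = 0.001)
  dens <- 0.95 * fretstates:::decay_signal_density(fine, 2.0, inst) + 0.05 / 12.5
  pr <- vapply(seq_len(nb), function(i) {
    lo <- h2$bin_edges_ns[i]; hi <- h2$bin_edges_ns[i + 1]
    sum(dens[fine >= lo & fine < hi]) * 0.001
  }, numeric(1))
  pr <- pr / sum(pr)
  expd <- 20000 * pr
  stat <- sum((h2$counts - expd)^2 / expd)
  p <- stats::pchisq(stat, df = nb - 1, lower.tail = FALSE)
  expect_gt(p, 0.01)
})

test_that("per-trace lifetime fitting returns one row per bunch", {
  m <- molecule_model(tau_da_ns = 2.0, donor_rate_hz = 4000,
                      background_rate_hz = 0,
                      donor_bleach_time_s = 2, acceptor_bleach_time_s = 2)
  tr <- simulate_molecule(m, instrument_model(), 1.2, seed = 71)
  n_d <- sum(tr$channels == "donor")
  lev <- mk_level(n_d, molecule_id = tr$molecule_id)
  out <- fit_trace_lifetimes(tr, list(lev), instrument_model(),
                             background_fraction = 0)
  expect_equal(nrow(out), n_d %/% 1000)
  expect_true(all(abs(out$lifetime_ns - 2.0) < 0.4))
})
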