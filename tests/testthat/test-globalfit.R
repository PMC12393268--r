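test_that("a pure open-state condition is assigned an amplitude near one", {
  ## a mixed condition anchors the shared compact peak; the pure condition's
  ## amplitude then identifies its (single) open state
  d <- fretstates:::with_seed(81, {
    rbind(data.frame(tau = draw_mixture(500, 0.6)$tau, cond = "mixed"),
          data.frame(tau = stats::rnorm(400, 2.7, 0.67), cond = "pure"))
  })
  fit <- fret_global_fit(d$tau, condition = d$cond, seed = 1)
  expect_gte(unname(fit$amplitude["pure"]), 0.97)
  expect_lt(abs(fit$amplitude[["mixed"]] - 0.6), 0.08)
})

test_that("relabelling conditions permutes amplitudes and preserves shared parameters", {
  d <- fretstates:::with_seed(82, {
    rbind(data.frame(tau = draw_mixture(300, 0.3)$tau, cond = "a"),
          data.frame(tau = draw_mixture(300, 0.8)$tau, cond = "b"))
  })
  f1 <- fret_global_fit(d$tau, condition = d$cond, seed = 3)
  swapped <- c(a = "zz", b = "aa")[d$cond]
  f2 <- fret_global_fit(d$tau, condition = swapped, seed = 3)
  expect_equal(f1$mu, f2$mu, tolerance = 1e-6)
  expect_equal(f1$sigma, f2$sigma, tolerance = 1e-6)
  expect_equal(unname(f1$amplitude[c("a", "b")]),
               unname(f2$amplitude[c("zz", "aa")]), tolerance = 1e-6)
})

test_that("the EM log-likelihood is non-decreasing across iterations", {
  d <- fretstates:::with_seed(83, draw_mixture(500, 0.6))
  fit <- fret_global_fit(d$tau, condition = rep("c", 500), seed = 2)
  expect_true(all(diff(fit$loglik_trace) > -1e-6))
  expect_true(fit$converged)
})

test_that("with amplitudes tied the fit reduces to an ordinary two-component mixture", {
  skip_if_not_installed("mclust")
  suppressMessages(library(mclust))
  d <- fretstates:::with_seed(84, draw_mixture(800, 0.65))
  fit <- fret_global_fit(d$tau, condition = rep("pool", 800), seed = 4,
                         truncate = FALSE)
  mc <- mclust::Mclust(d$tau, G = 2, modelNames = "V", verbose = FALSE)
  expect_equal(fit$loglik, mc$loglik, tolerance = 1e-4)
  expect_gte(fit$loglik, mc$loglik - 1e-6)  # never worse than the oracle
  ## the likelihood surface is flat near the optimum; parameters agree to
  ## within the optimizers' convergence scales
  expect_equal(fit$mu, unname(mc$parameters$mean), tolerance = 0.02)
  expect_equal(fit$sigma, unname(sqrt(mc$parameters$variance$sigmasq)),
               tolerance = 0.03)
})

test_that("generating amplitudes are recovered from large samples", {
  amps <- c(lo = 0.30, mid = 0.74, hi = 0.96)
  d <- fretstates:::with_seed(85, {
    do.call(rbind, lapply(names(amps), function(nm)
      data.frame(tau = draw_mixture(2000, amps[[nm]])$tau, cond = nm)))
  })
  fit <- fret_global_fit(d$tau, condition = d$cond, seed = 5)
  ## 3 sigma of the binomial component of the amplitude uncertainty
  expect_true(all(abs(fit$amplitude[names(amps)] - amps) <=
                    3 * sqrt(amps * (1 - amps) / 2000) + 0.01))
  expect_lt(abs(fit$mu[1] - 1.3), 0.05)
  expect_lt(abs(fit$mu[2] - 2.7), 0.05)
  expect_true(all(is.finite(fit$se[c("mu_compact", "mu_open")])))
})

test_that("fit methods are coherent with the fitted model", {
  d <- fretstates:::with_seed(86, draw_mixture(600, 0.7))
  fit <- fret_global_fit(d$tau, condition = rep("c", 600), seed = 6)
  ## density integrates to ~1 over the positive axis
  tg <- seq(0.001, 8, by = 0.001)
  dens <- predict(fit, data.frame(lifetime_ns = tg, condition = "c"))
  expect_equal(sum(dens) * 0.001, 1, tolerance = 0.01)
  post <- predict(fit, data.frame(lifetime_ns = c(1.0, 3.0), condition = "c"),
                  type = "posterior")
  expect_lt(post[1], 0.5); expect_gt(post[2], 0.5)

  sim <- simulate(fit, seed = 9)
  expect_equal(nrow(sim), 600)
  expect_true(all(sim$lifetime_ns >= 0.05))

  res <- residuals(fit)
  expect_true(all(is.finite(res$pearson)))
  expect_lt(mean(abs(res$pearson)), 2)

  cf <- coef(fit)
  expect_named(cf, c("mu_compact", "mu_open", "sigma_compact", "sigma_open", "a_c"))
  ll <- logLik(fit)
  expect_equal(attr(ll, "df"), 5)
  s <- summary(fit, calibration = fret_calibration(8.4, 3.0))
  expect_equal(nrow(s$distances), 2)

  expect_error(fret_global_fit(d$tau[1:20], condition = rep("c", 20)), ">= 30")
})

test_that("EGF-induced amplitude changes subtract printed amplitudes", {
  stub <- mk_fit_stub(c(noEGF = 0.69, EGF = 0.91), c(0.02, 0.015))
  ch <- open_amplitude_change(stub, "noEGF", "EGF")
  expect_equal(ch$delta, 0.22)
  expect_equal(ch$se, sqrt(0.02^2 + 0.015^2))
  expect_equal(open_amplitude_change(stub, "noEGF", "noEGF")$delta, 0)
  stub2 <- mk_fit_stub(c(noEGF = 0.87, EGF = 0.60), c(0.02, 0.02))
  expect_equal(open_amplitude_change(stub2, "noEGF", "EGF")$delta, -0.27)
  expect_error(open_amplitude_change(stub, "noEGF", "missing"), "present")
})

test_that("one-way ANOVA matches its classical definition", {
  g1 <- fretstates:::with_seed(87, stats::rnorm(12, 1))
  g2 <- fretstates:::with_seed(88, stats::rnorm(15, 1.4))
  g3 <- fretstates:::with_seed(89, stats::rnorm(9, 0.8))

  ## two groups: F equals the squared pooled t statistic
  two <- anova_compare(list(g1, g2))
  tt <- stats::t.test(g1, g2, var.equal = TRUE)
  expect_equal(two$F, unname(tt$statistic)^2, tolerance = 1e-10)

  expect_equal(anova_compare(list(c(1, 2, 3), c(1, 2, 3)))$F, 0)

  ## brute-force sums of squares
  three <- anova_compare(list(g1, g2, g3))
  y <- c(g1, g2, g3); k <- 3; N <- length(y)
  ssb <- sum(vapply(list(g1, g2, g3), function(g)
    length(g) * (mean(g) - mean(y))^2, numeric(1)))
  ssw <- sum(vapply(list(g1, g2, g3), function(g)
    sum((g - mean(g))^2), numeric(1)))
  f_ref <- (ssb / (k - 1)) / (ssw / (N - k))
  expect_equal(three$F, f_ref, tolerance = 1e-10)
  expect_equal(three$df, c(2, N - 3))

  deg <- anova_compare(list(c(1, 1), c(1, 1)))
  expect_true(deg$flagged)
  expect_error(anova_compare(list(g1)), ">= 2 groups")
})
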