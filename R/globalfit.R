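#' Global two-state Gaussian fit of per-bunch lifetime distributions
#'
#' Fits all conditions' per-bunch donor lifetime distributions jointly with a
#' two-component Gaussian mixture in which the peak positions and widths are
#' shared across conditions and only the relative amplitude of the two
#' states varies per condition. The model for a lifetime `t` in condition
#' `c` is
#' \deqn{(1 - a_c)\,N(t; \mu_1, \sigma_1) + a_c\,N(t; \mu_2, \sigma_2),}
#' with `mu_1 < mu_2` enforced by relabelling, so `a_c` is the open-state
#' (long-lifetime) amplitude. Fitting is by maximum likelihood on the
#' unbinned lifetimes: multi-start expectation-maximization, optionally
#' followed by direct maximization of the positivity-truncated likelihood
#' (components renormalized on `t > 0`; the effect is negligible for the
#' lifetime scales involved but keeps the density proper). Standard errors
#' come from the observed information matrix at the optimum.
#'
#' @param x A formula `lifetime ~ condition` (with `data`), or a numeric
#'   vector of lifetimes (with `condition`).
#' @param ... Passed to methods.
#' @return An object of class `fret_global_fit`; see Details for components.
#'   Methods: `print`, `summary`, `coef`, `logLik`, `predict`, `plot`,
#'   `simulate`, `residuals`.
#' @details The returned object contains `mu` and `sigma` (length-2 shared
#'   parameters, compact then open), `amplitude` (named per-condition
#'   open-state fractions), `se` (named standard errors), `loglik`,
#'   `loglik_trace` (EM iterations of the winning start), `n` (bunches per
#'   condition), `converged`, `iterations`.
#' @examples
#' set.seed(1)
#' d <- data.frame(
#'   lifetime_ns = c(rnorm(300, 1.3, 0.35), rnorm(700, 2.7, 0.67)),
#'   condition = "demo")
#' fit <- fret_global_fit(lifetime_ns ~ condition, data = d, seed = 1)
#' coef(fit)
#' @export
fret_global_fit <- function(x, ...) UseMethod("fret_global_fit")

#' @rdname fret_global_fit
#' @param data Data frame holding the formula variables.
#' @export
fret_global_fit.formula <- function(x, data, ...) {
  mf <- stats::model.frame(x, data)
  fit <- fret_global_fit.default(mf[[1]], condition = mf[[2]], ...)
  fit$call <- match.call()
  fit
}

#' @rdname fret_global_fit
#' @param condition Factor (or coercible) assigning each lifetime to a
#'   measurement condition.
#' @param init Optional list with starting values `mu` (length 2), `sigma`
#'   (length 2), `amplitude` (per condition).
#' @param n_starts Number of seeded EM starts (default 10).
#' @param seed Integer seed for the start jitter.
#' @param max_iter,tol EM iteration cap and log-likelihood convergence
#'   tolerance.
#' @param truncate Renormalize the Gaussian components on `t > 0` and polish
#'   the EM solution by direct likelihood maximization (default TRUE).
#' @param weight_by Per-"bunch" likelihood terms (default) or per-"molecule"
#'   averaging of bunch contributions (requires `molecule`).
#' @param molecule Optional molecule identifier per lifetime, used when
#'   `weight_by = "molecule"`.
#' @export
fret_global_fit.default <- function(x, condition, init = NULL, n_starts = 10,
                                    seed = 1, max_iter = 1e4, tol = 1e-8,
                                    truncate = TRUE,
                                    weight_by = c("bunch", "molecule"),
                                    molecule = NULL, ...) {
  tau <- as.numeric(x)
  weight_by <- match.arg(weight_by)
  condition <- factor(condition)
  if (length(tau) != length(condition))
    stop("lifetimes and condition labels must have equal length")
  keep <- is.finite(tau)
  tau <- tau[keep]; condition <- droplevels(condition[keep])
  n_c <- table(condition)
  if (length(n_c) < 1) stop("at least one condition required")
  if (any(n_c < 30))
    stop("each condition needs >= 30 bunch lifetimes; short: ",
         paste(names(n_c)[n_c < 30], collapse = ", "))
  w <- rep(1, length(tau))
  if (weight_by == "molecule") {
    if (is.null(molecule)) stop("weight_by = 'molecule' requires 'molecule'")
    molecule <- molecule[keep]
    w <- 1 / as.numeric(table(molecule)[as.character(molecule)])
  }

  starts <- gf_starts(tau, condition, init, n_starts, seed)
  best <- NULL
  for (st in starts) {
    em <- gf_em(tau, condition, st, max_iter, tol, w)
    if (is.null(best) || (em$converged && !best$converged) ||
        (em$converged == best$converged && em$loglik > best$loglik))
      best <- em
  }
  if (!best$converged)
    stop("global fit failed to converge in all starts; best loglik ",
         format(best$loglik), " after ", best$iterations, " iterations")

  if (truncate) best <- gf_polish(tau, condition, best, w)
  best <- gf_relabel(best)
  se <- gf_se(tau, condition, best, truncate, w)

  structure(list(mu = best$mu, sigma = best$sigma,
                 amplitude = stats::setNames(best$a, levels(condition)),
                 se = se, loglik = best$loglik,
                 loglik_trace = best$trace, n = as.integer(n_c),
                 conditions = levels(condition),
                 converged = best$converged, iterations = best$iterations,
                 truncated = truncate, weight_by = weight_by,
                 data = list(lifetime_ns = tau, condition = condition),
                 call = match.call()),
            class = "fret_global_fit")
}

## ---- internals -------------------------------------------------------------

gf_starts <- function(tau, condition, init, n_starts, seed) {
  C <- nlevels(condition)
  base <- list(mu = as.numeric(stats::quantile(tau, c(0.25, 0.75))),
               sigma = rep(stats::sd(tau) / 2, 2), a = rep(0.5, C))
  if (base$mu[1] >= base$mu[2]) base$mu <- base$mu + c(-0.1, 0.1)
  starts <- list(if (!is.null(init))
    list(mu = init$mu, sigma = init$sigma,
         a = rep_len(init$amplitude, C)) else base)
  for (s in seq_len(max(n_starts - 1, 0))) {
    starts[[s + 1]] <- with_seed(child_seed(seed, stage_index("globalfit"), s), {
      list(mu = sort(stats::runif(2, min(tau), max(tau))),
           sigma = rep(stats::sd(tau), 2) * stats::runif(2, 0.3, 1),
           a = stats::runif(C, 0.1, 0.9))
    })
  }
  starts
}

## EM with shared (mu, sigma) and per-condition amplitudes; weights w allow
## per-molecule downweighting. Log-likelihood is monotone by construction.
gf_em <- function(tau, condition, start, max_iter, tol, w) {
  mu <- start$mu; sigma <- pmax(start$sigma, 1e-3)
  a <- pmin(pmax(start$a, 1e-3), 1 - 1e-3)
  ci <- as.integer(condition)
  ll_old <- -Inf; trace <- numeric(0); converged <- FALSE
  for (it in seq_len(max_iter)) {
    d1 <- (1 - a[ci]) * stats::dnorm(tau, mu[1], sigma[1])
    d2 <- a[ci] * stats::dnorm(tau, mu[2], sigma[2])
    tot <- d1 + d2
    tot[tot < 1e-300] <- 1e-300
    ll <- sum(w * log(tot))
    trace <- c(trace, ll)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol) { converged <- TRUE; break }
    ll_old <- ll
    r <- d2 / tot                       # open-state responsibility
    a <- vapply(seq_len(max(ci)), function(c)
      sum(w[ci == c] * r[ci == c]) / sum(w[ci == c]), numeric(1))
    a <- pmin(pmax(a, 1e-6), 1 - 1e-6)
    w1 <- w * (1 - r); w2 <- w * r
    mu <- c(sum(w1 * tau) / sum(w1), sum(w2 * tau) / sum(w2))
    sigma <- pmax(c(sqrt(sum(w1 * (tau - mu[1])^2) / sum(w1)),
                    sqrt(sum(w2 * (tau - mu[2])^2) / sum(w2))), 1e-3)
  }
  list(mu = mu, sigma = sigma, a = a, loglik = ll, trace = trace,
       iterations = it, converged = converged)
}

## truncated (t > 0, renormalized) mixture log-likelihood
gf_trunc_ll <- function(theta, tau, ci, C, w) {
  mu <- theta[1:2]; sigma <- exp(theta[3:4])
  a <- stats::plogis(theta[4 + seq_len(C)])
  z <- stats::pnorm(0, mu, sigma, lower.tail = FALSE)  # mass above 0
  d1 <- (1 - a[ci]) * stats::dnorm(tau, mu[1], sigma[1]) / z[1]
  d2 <- a[ci] * stats::dnorm(tau, mu[2], sigma[2]) / z[2]
  tot <- d1 + d2
  tot[tot < 1e-300] <- 1e-300
  sum(w * log(tot))
}

gf_polish <- function(tau, condition, em, w) {
  ci <- as.integer(condition); C <- max(ci)
  theta0 <- c(em$mu, log(em$sigma), stats::qlogis(pmin(pmax(em$a, 1e-6), 1 - 1e-6)))
  opt <- stats::optim(theta0, function(th) -gf_trunc_ll(th, tau, ci, C, w),
                      method = "BFGS", control = list(maxit = 500, reltol = 1e-12))
  em$mu <- opt$par[1:2]; em$sigma <- exp(opt$par[3:4])
  em$a <- stats::plogis(opt$par[4 + seq_len(C)])
  em$loglik <- -opt$value
  em
}

gf_relabel <- function(fit) {
  if (fit$mu[1] > fit$mu[2]) {
    fit$mu <- rev(fit$mu); fit$sigma <- rev(fit$sigma)
    fit$a <- 1 - fit$a
  }
  fit
}

## observed-information standard errors on the natural scale
## (mu1, mu2, sigma1, sigma2, a_1..a_C)
gf_se <- function(tau, condition, fit, truncate, w) {
  ci <- as.integer(condition); C <- max(ci)
  nat_ll <- function(p) {
    mu <- p[1:2]; sigma <- p[3:4]; a <- p[4 + seq_len(C)]
    if (any(sigma <= 0) || any(a <= 0) || any(a >= 1)) return(-Inf)
    z <- if (truncate) stats::pnorm(0, mu, sigma, lower.tail = FALSE) else c(1, 1)
    tot <- (1 - a[ci]) * stats::dnorm(tau, mu[1], sigma[1]) / z[1] +
           a[ci] * stats::dnorm(tau, mu[2], sigma[2]) / z[2]
    tot[tot < 1e-300] <- 1e-300
    sum(w * log(tot))
  }
  p0 <- c(fit$mu, fit$sigma, fit$a)
  nm <- c("mu_compact", "mu_open", "sigma_compact", "sigma_open",
          paste0("a_", levels(condition)))
  se <- rep(NA_real_, length(p0))
  H <- try(stats::optimHess(p0, nat_ll), silent = TRUE)
  if (!inherits(H, "try-error")) {
    V <- try(solve(-H), silent = TRUE)
    if (!inherits(V, "try-error")) {
      dv <- diag(V)
      se[dv > 0] <- sqrt(dv[dv > 0])
    }
  }
  stats::setNames(se, nm)
}

## ---- methods ---------------------------------------------------------------

#' @export
print.fret_global_fit <- function(x, digits = 3, ...) {
  cat("Global two-state lifetime fit\n")
  cat(sprintf("  shared peaks: %.3g ns (compact), %.3g ns (open); widths %.3g / %.3g ns\n",
              x$mu[1], x$mu[2], x$sigma[1], x$sigma[2]))
  cat(sprintf("  %d condition(s), %d bunches, logLik %.2f\n",
              length(x$conditions), sum(x$n), x$loglik))
  amp <- format(round(100 * x$amplitude, 1))
  cat("  open-state amplitude (%):\n")
  for (i in seq_along(x$amplitude))
    cat(sprintf("    %-24s %s\n", x$conditions[i], amp[i]))
  invisible(x)
}

#' @export
coef.fret_global_fit <- function(object, ...) {
  stats::setNames(c(object$mu, object$sigma, object$amplitude),
                  names(object$se))
}

#' @export
logLik.fret_global_fit <- function(object, ...) {
  structure(object$loglik, df = 4 + length(object$amplitude),
            nobs = sum(object$n), class = "logLik")
}

#' @rdname fret_global_fit
#' @param object A fitted `fret_global_fit`.
#' @param calibration Optional [fret_calibration()]; adds distance
#'   conversions for the fitted peaks to the summary.
#' @export
summary.fret_global_fit <- function(object, calibration = NULL, ...) {
  cf <- coef(object)
  tab <- data.frame(estimate = cf, se = object$se)
  dist <- NULL
  if (!is.null(calibration)) dist <- lifetime_to_distance(object$mu, calibration)
  structure(list(coefficients = tab, distances = dist, loglik = object$loglik,
                 n = stats::setNames(object$n, object$conditions),
                 converged = object$converged),
            class = "summary.fret_global_fit")
}

#' @export
print.summary.fret_global_fit <- function(x, digits = 4, ...) {
  cat("Global two-state lifetime fit\n\nCoefficients:\n")
  print(round(x$coefficients, digits))
  if (!is.null(x$distances)) {
    cat("\nPeak distances:\n")
    print(round(x$distances, digits))
  }
  cat(sprintf("\nlogLik %.2f on %d bunches\n", x$loglik, sum(x$n)))
  invisible(x)
}

#' @rdname fret_global_fit
#' @param newdata Optional data frame with columns `lifetime_ns` and
#'   `condition` at which to evaluate.
#' @param type "density" for the fitted mixture density, "posterior" for the
#'   open-state posterior probability.
#' @export
predict.fret_global_fit <- function(object, newdata = NULL,
                                    type = c("density", "posterior"), ...) {
  type <- match.arg(type)
  if (is.null(newdata))
    newdata <- data.frame(lifetime_ns = object$data$lifetime_ns,
                          condition = object$data$condition)
  a <- object$amplitude[as.character(newdata$condition)]
  z <- if (object$truncated)
    stats::pnorm(0, object$mu, object$sigma, lower.tail = FALSE) else c(1, 1)
  d1 <- (1 - a) * stats::dnorm(newdata$lifetime_ns, object$mu[1], object$sigma[1]) / z[1]
  d2 <- a * stats::dnorm(newdata$lifetime_ns, object$mu[2], object$sigma[2]) / z[2]
  if (type == "density") unname(d1 + d2) else unname(d2 / (d1 + d2))
}

#' @rdname fret_global_fit
#' @param nsim Number of simulated replicates.
#' @param n_per_condition Bunches per condition in each replicate (defaults
#'   to the fitted counts).
#' @export
simulate.fret_global_fit <- function(object, nsim = 1, seed = 1,
                                     n_per_condition = NULL, ...) {
  n_pc <- n_per_condition %||% stats::setNames(object$n, object$conditions)
  n_pc <- rep_len(n_pc, length(object$conditions))
  out <- vector("list", nsim)
  for (s in seq_len(nsim)) {
    out[[s]] <- with_seed(child_seed(seed, stage_index("globalfit"), 100 + s), {
      do.call(rbind, lapply(seq_along(object$conditions), function(i) {
        n <- n_pc[i]
        open <- stats::rbinom(n, 1, object$amplitude[i]) + 1L
        tau <- stats::rnorm(n, object$mu[open], object$sigma[open])
        bad <- which(tau < 0.05)
        while (length(bad)) {
          tau[bad] <- stats::rnorm(length(bad), object$mu[open[bad]],
                                   object$sigma[open[bad]])
          bad <- bad[tau[bad] < 0.05]
        }
        data.frame(lifetime_ns = tau, condition = object$conditions[i],
                   state = c("compact", "open")[open],
                   stringsAsFactors = FALSE)
      }))
    })
  }
  if (nsim == 1) out[[1]] else out
}

#' @rdname fret_global_fit
#' @export
residuals.fret_global_fit <- function(object, ...) {
  out <- list()
  for (i in seq_along(object$conditions)) {
    cc <- object$conditions[i]
    tau <- object$data$lifetime_ns[object$data$condition == cc]
    nb <- sqrt_rule_bins(length(tau))
    edges <- seq(min(tau), max(tau), length.out = nb + 1)
    obs <- tabulate(pmin(pmax(findInterval(tau, edges), 1L), nb), nb)
    a <- object$amplitude[i]
    z <- if (object$truncated)
      stats::pnorm(0, object$mu, object$sigma, lower.tail = FALSE) else c(1, 1)
    pr <- (1 - a) * diff(stats::pnorm(edges, object$mu[1], object$sigma[1])) / z[1] +
          a * diff(stats::pnorm(edges, object$mu[2], object$sigma[2])) / z[2]
    exp_ <- length(tau) * pr
    out[[i]] <- data.frame(condition = cc,
                           mid = (edges[-1] + edges[-(nb + 1)]) / 2,
                           observed = obs, expected = exp_,
                           pearson = (obs - exp_) / sqrt(pmax(exp_, 1e-12)))
  }
  do.call(rbind, out)
}

#' @rdname fret_global_fit
#' @export
plot.fret_global_fit <- function(x, ...) {
  C <- length(x$conditions)
  op <- graphics::par(mfrow = grDevices::n2mfrow(C), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  for (i in seq_len(C)) {
    cc <- x$conditions[i]
    tau <- x$data$lifetime_ns[x$data$condition == cc]
    nb <- sqrt_rule_bins(length(tau))
    h <- graphics::hist(tau, breaks = seq(min(tau), max(tau), length.out = nb + 1),
                        plot = FALSE)
    bw <- diff(h$breaks[1:2])
    tg <- seq(max(0.01, min(tau) - 0.5), max(tau) + 0.5, length.out = 400)
    dens <- predict(x, data.frame(lifetime_ns = tg, condition = cc))
    graphics::plot(h, freq = TRUE, main = cc, xlab = "lifetime (ns)",
                   col = "grey85", border = "white")
    graphics::lines(tg, dens * length(tau) * bw, lwd = 2, col = "firebrick")
    graphics::abline(v = x$mu, lty = 3)
  }
  invisible(x)
}

#' Display-histogram bin count from the square-root rule
#'
#' Number of display bins for a lifetime histogram: the square root of the
#' number of photon bunches, rounded, with a floor of 5.
#'
#' @param n_bunches Number of bunch lifetimes.
#' @return Integer bin count.
#' @export
sqrt_rule_bins <- function(n_bunches) {
  max(5L, as.integer(round(sqrt(n_bunches))))
}

#' EGF-induced change in open-state amplitude
#'
#' Signed amplitude difference `a_EGF - a_noEGF` between two conditions of a
#' global fit, with the propagated standard error
#' `sqrt(se_EGF^2 + se_noEGF^2)`.
#'
#' @param result A [fret_global_fit()] object.
#' @param no_egf,egf Condition labels.
#' @return List with `delta`, `se`.
#' @export
open_amplitude_change <- function(result, no_egf, egf) {
  stopifnot(inherits(result, "fret_global_fit"))
  if (!all(c(no_egf, egf) %in% result$conditions))
    stop("both conditions must be present in the fit")
  d <- unname(result$amplitude[egf] - result$amplitude[no_egf])
  se <- sqrt(sum(result$se[paste0("a_", c(no_egf, egf))]^2))
  list(delta = d, se = unname(se))
}

#' One-way ANOVA comparison of lifetime groups
#'
#' Classical one-way analysis of variance (`F = MS_between / MS_within` on
#' `(k - 1, N - k)` degrees of freedom) across two or more groups, with the
#' significance call at `P <= 0.001`.
#'
#' @param groups List of numeric vectors (>= 2 groups of >= 2 values).
#' @param alpha Significance level (default 0.001).
#' @return List with `F`, `p`, `df` (length 2), `significant`, `flagged`
#'   (TRUE when F is undefined: zero variance within groups and equal means).
#' @export
anova_compare <- function(groups, alpha = 0.001) {
  if (!is.list(groups) || length(groups) < 2)
    stop("need >= 2 groups")
  if (any(vapply(groups, length, integer(1)) < 2))
    stop("each group needs >= 2 values")
  y <- unlist(groups)
  g <- factor(rep(seq_along(groups), vapply(groups, length, integer(1))))
  k <- length(groups); N <- length(y)
  ssw <- sum(unlist(lapply(groups, function(v) sum((v - mean(v))^2))))
  ssb <- sum(vapply(groups, function(v) length(v) * (mean(v) - mean(y))^2,
                    numeric(1)))
  if (ssw == 0 && ssb == 0)
    return(list(F = NA_real_, p = NA_real_, df = c(k - 1, N - k),
                significant = NA, flagged = TRUE))
  ow <- stats::oneway.test(y ~ g, var.equal = TRUE)
  list(F = unname(ow$statistic), p = unname(ow$p.value),
       df = unname(ow$parameter), significant = ow$p.value <= alpha,
       flagged = FALSE)
}
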