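#' Solve the WHAM equations for umbrella-sampled windows
#'
#' Iterates the weighted-histogram self-consistency equations over the
#' biased windows until the per-window free-energy offsets stabilize:
#' \deqn{P(x_b) \propto \sum_i n_i(x_b) \Big/ \sum_i N_i e^{f_i - u_i(x_b)},
#'       \qquad f_i = -\ln \sum_b P(x_b)\, e^{-u_i(x_b)},}
#' with harmonic biases `u_i(x) = k_i/2 (x - c_i)^2` in kT. Supports one- and
#' two-dimensional collective variables (samples as a vector or a two-column
#' matrix; `center`/`spring_k` of matching length). Returns the unbiased
#' probability and free-energy profile on the bin grid plus normalized
#' per-sample reweighting factors `w_j \propto exp(+u_i(x_j) - f_i)` for
#' computing unbiased averages of arbitrary per-frame metrics.
#'
#' @param windows List of `umbrella_window` objects (fields `center`,
#'   `spring_k`, `samples`), e.g. from [simulate_umbrella_windows()] or
#'   [read_umbrella_csv()].
#' @param n_bins Histogram bins per axis.
#' @param tol Convergence tolerance on `max |delta f_i|`.
#' @param max_iter Iteration cap.
#' @return An object of class `wham`: `free_energies` (per window, first
#'   window pinned to 0), `pmf` (data frame of bin centres and free energy
#'   in kT, minimum shifted to 0), `prob` (bin probabilities), `weights`
#'   (per-sample, normalized, in window order), `window_index` (window of
#'   each sample), `converged`, `iterations`.
#' @export
wham_solve <- function(windows, n_bins = 100, tol = 1e-8, max_iter = 1e5) {
  if (length(windows) < 1) stop("need >= 1 window")
  d <- length(windows[[1]]$center)
  X <- do.call(rbind, lapply(windows, function(w) cbind(matrix(w$samples, ncol = d))))
  widx <- rep(seq_along(windows), vapply(windows, function(w)
    length(w$samples) / d, numeric(1)))
  Ni <- as.numeric(table(widx))
  centers <- do.call(rbind, lapply(windows, function(w) rep_len(w$center, d)))
  springs <- do.call(rbind, lapply(windows, function(w) rep_len(w$spring_k, d)))

  converged <- TRUE
  if (d == 1 && length(windows) > 1) {
    ## adjacent windows (by centre) must have overlapping sample ranges
    o <- order(centers[, 1])
    rng <- t(vapply(windows, function(w) range(w$samples), numeric(2)))[o, , drop = FALSE]
    if (any(rng[-nrow(rng), 2] < rng[-1, 1])) {
      warning("non-overlapping adjacent windows; WHAM solution unreliable")
      converged <- FALSE
    }
  }

  ## bin grid (outer product over axes)
  edges <- lapply(seq_len(d), function(k)
    seq(min(X[, k]), max(X[, k]), length.out = n_bins + 1))
  mids <- lapply(edges, function(e) (e[-1] + e[-length(e)]) / 2)
  bin1 <- function(x, e) pmin(pmax(findInterval(x, e), 1L), length(e) - 1L)
  bidx <- bin1(X[, 1], edges[[1]])
  if (d == 2) bidx <- bidx + (bin1(X[, 2], edges[[2]]) - 1L) * n_bins
  nb_tot <- n_bins^d
  counts <- tabulate(bidx, nb_tot)

  grid <- if (d == 1) matrix(mids[[1]], ncol = 1) else
    as.matrix(expand.grid(mids[[1]], mids[[2]]))
  ## u[b, i]: bias of window i at grid point b, in kT
  u <- matrix(0, nb_tot, length(windows))
  for (i in seq_along(windows))
    u[, i] <- colSums(springs[i, ] / 2 * (t(grid) - centers[i, ])^2)

  f <- rep(0, length(windows))
  it <- 0L
  if (converged) {
    converged <- FALSE
    eu <- exp(-u)
    for (it in seq_len(max_iter)) {
      denom <- as.vector(eu %*% (Ni * exp(f)))
      P <- counts / denom
      P <- P / sum(P)
      f_new <- -log(as.vector(crossprod(eu, P)))
      f_new <- f_new - f_new[1]
      if (max(abs(f_new - f)) < tol) { f <- f_new; converged <- TRUE; break }
      f <- f_new
    }
  } else {
    denom <- as.vector(exp(-u) %*% (Ni * exp(f)))
    P <- counts / denom; P <- P / sum(P)
  }

  ## per-sample unbiased weights at the exact sample positions
  u_s <- colSums(t(springs[widx, , drop = FALSE] / 2) *
                   (t(X) - t(centers[widx, , drop = FALSE]))^2)
  logw <- u_s - f[widx]
  w <- exp(logw - max(logw)); w <- w / sum(w)

  pmf_val <- -log(pmax(P, 1e-300))
  pmf_val <- pmf_val - min(pmf_val[counts > 0])
  pmf <- if (d == 1) data.frame(cv = grid[, 1], free_energy = pmf_val)
         else data.frame(cv1 = grid[, 1], cv2 = grid[, 2], free_energy = pmf_val)
  structure(list(free_energies = f, pmf = pmf, prob = P, counts = counts,
                 weights = w, window_index = widx, converged = converged,
                 iterations = it, n_bins = n_bins, edges = edges),
            class = "wham")
}

#' @export
print.wham <- function(x, ...) {
  cat(sprintf("WHAM solution: %d windows, %d bins, %s after %d iterations\n",
              length(x$free_energies), length(x$prob),
              if (x$converged) "converged" else "NOT converged", x$iterations))
  invisible(x)
}

#' @export
plot.wham <- function(x, ...) {
  if (!"cv" %in% names(x$pmf)) stop("plot method covers 1-D profiles only")
  keep <- x$counts > 0
  graphics::plot(x$pmf$cv[keep], x$pmf$free_energy[keep], type = "l", lwd = 2,
                 xlab = "collective variable", ylab = "free energy (kT)", ...)
  invisible(x)
}

#' Bias-reweighted average of a per-frame metric
#'
#' Weighted mean of `metric_values` under the WHAM reweighting factors, with
#' a block-bootstrap statistical error (contiguous blocks, resampled with
#' replacement, weights renormalized per resample).
#'
#' @param metric_values One value per retained sample, in the same order as
#'   the samples handed to [wham_solve()].
#' @param wham A [wham_solve()] result.
#' @param n_blocks Number of contiguous blocks (default 50).
#' @param n_resamples Bootstrap resamples (default 200).
#' @param seed Integer seed for the bootstrap.
#' @return List with `mean` and `se`.
#' @export
reweighted_average <- function(metric_values, wham, n_blocks = 50,
                               n_resamples = 200, seed = 1) {
  stopifnot(inherits(wham, "wham"))
  if (length(metric_values) != length(wham$weights))
    stop("one metric value per retained sample required")
  w <- wham$weights
  est <- sum(w * metric_values)
  n <- length(w)
  n_blocks <- min(n_blocks, n)
  blocks <- split(seq_len(n), cut(seq_len(n), n_blocks, labels = FALSE))
  boots <- with_seed(seed, {
    vapply(seq_len(n_resamples), function(b) {
      idx <- unlist(blocks[sample.int(n_blocks, n_blocks, replace = TRUE)])
      wb <- w[idx] / sum(w[idx])
      sum(wb * metric_values[idx])
    }, numeric(1))
  })
  list(mean = est, se = stats::sd(boots))
}
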