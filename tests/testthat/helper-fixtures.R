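# shared fixtures, built in code

delta_instrument <- function(center = 0.5) {
  instrument_model(irf_fwhm_ns = 0, irf_center_ns = center)
}

# intensity trace from explicit per-bin counts
mk_intensity <- function(donor, acceptor = integer(length(donor)),
                         bin_width_s = 0.1) {
  structure(list(bin_width_s = bin_width_s, donor = as.integer(donor),
                 acceptor = as.integer(acceptor), n_bins = length(donor),
                 partial_last = FALSE, molecule_id = "fix"),
            class = "intensity_trace")
}

# segment table from per-segment rates and bin lengths
mk_segments <- function(rates, lens = rep(10, length(rates)),
                        channel = "donor") {
  ends <- cumsum(lens)
  data.frame(channel = channel, start_bin = c(0L, ends[-length(ends)]),
             end_bin = ends, mean_rate = rates)
}

mk_level <- function(n_photons, start = 0L, molecule_id = "fix") {
  structure(list(molecule_id = molecule_id, level_index = 1L,
                 photon_range = c(start, start + n_photons),
                 duration_s = n_photons / 1000, n_photons = n_photons),
            class = "fret_level")
}

# microtimes from the Gaussian-IRF decay model with uniform background
sim_microtimes <- function(n, tau, fwhm = 0.3, center = 0.5, b = 0,
                           window = 12.5) {
  nb <- stats::rbinom(1, n, b)
  sig <- fwhm / (2 * sqrt(2 * log(2)))
  irf <- if (fwhm > 0) stats::rnorm(n - nb, center, sig) else rep(center, n - nb)
  c((irf + stats::rexp(n - nb, 1 / tau)) %% window,
    stats::runif(nb, 0, window))
}

# per-bunch lifetimes drawn from the two-state peak model (0.05 ns floor)
draw_mixture <- function(n, amp_open, peaks = c(1.3, 2.7),
                         widths = c(0.35, 0.67)) {
  open <- stats::rbinom(n, 1, amp_open) + 1L
  tau <- stats::rnorm(n, peaks[open], widths[open])
  bad <- which(tau < 0.05)
  while (length(bad)) {
    tau[bad] <- stats::rnorm(length(bad), peaks[open[bad]], widths[open[bad]])
    bad <- bad[tau[bad] < 0.05]
  }
  list(tau = tau, state = c("compact", "open")[open])
}

mk_frame <- function(xyz, residue, group, box = NULL) {
  cg_frame(matrix(xyz, ncol = 3, byrow = TRUE), residue, group, box)
}

# minimal classed fit object for method-level tests
mk_fit_stub <- function(amplitude, se_a) {
  structure(list(mu = c(1.3, 2.7), sigma = c(0.35, 0.67),
                 amplitude = amplitude,
                 se = stats::setNames(c(0.01, 0.01, 0.01, 0.01, se_a),
                                      c("mu_compact", "mu_open",
                                        "sigma_compact", "sigma_open",
                                        paste0("a_", names(amplitude)))),
                 conditions = names(amplitude)),
            class = "fret_global_fit")
}
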