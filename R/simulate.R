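#' Photon trace container
#'
#' Per-molecule photon stream: arrival (macro) times in seconds, TCSPC delay
#' (micro) times in ns and a donor/acceptor channel label per photon.
#'
#' @param molecule_id Identifier.
#' @param macrotimes_s Strictly increasing arrival times, s.
#' @param microtimes_ns TCSPC delays in `[0, window_ns)`.
#' @param channels Character or factor vector of "donor"/"acceptor".
#' @param window_ns TCSPC window, ns.
#' @return An object of class `photon_trace`.
#' @export
photon_trace <- function(molecule_id, macrotimes_s, microtimes_ns, channels,
                         window_ns) {
  n <- length(macrotimes_s)
  if (length(microtimes_ns) != n || length(channels) != n)
    stop("macrotimes, microtimes and channels must have equal length")
  if (n > 1 && any(diff(macrotimes_s) <= 0))
    stop("macrotimes must be strictly increasing")
  if (n > 0 && (any(microtimes_ns < 0) || any(microtimes_ns >= window_ns)))
    stop("microtimes must lie in [0, window_ns)")
  channels <- as.character(channels)
  if (n > 0 && !all(channels %in% c("donor", "acceptor")))
    stop("channels must be 'donor' or 'acceptor'")
  structure(list(molecule_id = molecule_id,
                 macrotimes_s = as.numeric(macrotimes_s),
                 microtimes_ns = as.numeric(microtimes_ns),
                 channels = channels, window_ns = window_ns),
            class = "photon_trace")
}

#' @export
print.photon_trace <- function(x, ...) {
  cat(sprintf("Photon trace '%s': %d photons (%d donor / %d acceptor)",
              x$molecule_id, length(x$macrotimes_s),
              sum(x$channels == "donor"), sum(x$channels == "acceptor")))
  if (length(x$macrotimes_s))
    cat(sprintf(", span %.3g s", max(x$macrotimes_s)))
  cat("\n")
  invisible(x)
}

## homogeneous Poisson arrivals on [t0, t1)
rpois_arrivals <- function(rate, t0, t1) {
  len <- t1 - t0
  if (len <= 0 || rate <= 0) return(numeric(0))
  n <- stats::rpois(1, rate * len)
  sort(stats::runif(n, t0, t1))
}

## break exact macrotime ties left over from merging channels
untie <- function(x) {
  while (length(x) > 1 && any(diff(x) <= 0)) {
    i <- which(diff(x) <= 0)
    x[i + 1] <- x[i] + 1e-12
    x <- sort(x)
  }
  x
}

#' Simulate the photon stream of one immobilized molecule
#'
#' Emulates a TCSPC measurement of a surface-immobilized FRET pair recorded
#' until photobleaching. Arrivals follow a piecewise-constant-rate Poisson
#' process: before acceptor photobleaching the donor channel runs at
#' `donor_rate_hz * (1 - E)` with quenched lifetime `tau_DA` and the acceptor
#' channel at `donor_rate_hz * E`; after acceptor bleaching the donor
#' recovers the full rate and the donor-only lifetime; after donor bleaching
#' only background remains. Signal microtimes are an exponential decay
#' convolved with the IRF and folded into the TCSPC window (periodic
#' excitation); background microtimes are uniform. Acceptor photons carry
#' intensity information only (uniform microtimes): the analysis uses donor
#' microtimes exclusively.
#'
#' For rate bookkeeping the efficiency is clamped to `e_rate_bounds` so that
#' lifetimes drawn beyond the donor-only reference (possible under the
#' empirical Gaussian peak model) still yield finite, positive channel rates;
#' the microtime decay always uses the model's `tau_da_ns` exactly.
#'
#' @param model A [molecule_model()].
#' @param instrument An [instrument_model()].
#' @param duration_s Total recording time, s.
#' @param seed Integer seed; identical seeds give identical traces.
#' @param e_rate_bounds Clamp applied to the efficiency for channel-rate
#'   bookkeeping only.
#' @return A [photon_trace()].
#' @examples
#' tr <- simulate_molecule(molecule_model(distance_nm = 8.4),
#'                         instrument_model(), duration_s = 1, seed = 1)
#' tr
#' @export
simulate_molecule <- function(model, instrument, duration_s, seed,
                              e_rate_bounds = c(0.02, 0.98)) {
  stopifnot(inherits(model, "molecule_model"),
            inherits(instrument, "instrument_model"))
  check_scalar(duration_s, "duration_s", positive = TRUE)
  rates <- c(model$donor_rate_hz, model$background_rate_hz)
  if (any(!is.finite(rates))) stop("non-finite rates rejected")
  W <- instrument$tcspc_window_ns
  e_rate <- min(max(model$efficiency, e_rate_bounds[1]), e_rate_bounds[2])
  t_a <- min(model$acceptor_bleach_time_s, duration_s)
  t_d <- min(model$donor_bleach_time_s, duration_s)
  t_fret <- min(t_a, t_d)

  with_seed(seed, {
    ## donor signal while FRET is active
    d1 <- rpois_arrivals(model$donor_rate_hz * (1 - e_rate), 0, t_fret)
    ## donor signal after acceptor bleach, lifetime reverted to tau_D
    d2 <- if (t_d > t_a) rpois_arrivals(model$donor_rate_hz, t_a, t_d) else numeric(0)
    a1 <- rpois_arrivals(model$donor_rate_hz * e_rate, 0, t_fret)
    dbg <- rpois_arrivals(model$background_rate_hz, 0, duration_s)
    abg <- rpois_arrivals(model$background_rate_hz, 0, duration_s)

    mt <- c(d1, d2, a1, dbg, abg)
    ch <- rep(c("donor", "donor", "acceptor", "donor", "acceptor"),
              times = c(length(d1), length(d2), length(a1), length(dbg), length(abg)))
    micro <- c(
      (irf_draw(length(d1), instrument) + stats::rexp(length(d1), 1 / model$tau_da_ns)) %% W,
      (irf_draw(length(d2), instrument) +
         stats::rexp(length(d2), 1 / model$donor_only_lifetime_ns)) %% W,
      stats::runif(length(a1), 0, W),
      stats::runif(length(dbg), 0, W),
      stats::runif(length(abg), 0, W))

    o <- order(mt)
    mt <- untie(mt[o])
    photon_trace("mol", mt, micro[o], ch[o], W)
  })
}

#' Simulate a measurement condition as a two-state molecular ensemble
#'
#' Draws `n_molecules` molecules whose conformational state is Bernoulli with
#' probability `open_fraction` of being open, assigns each molecule an
#' expected donor lifetime from the corresponding Gaussian peak (truncated at
#' a 0.05 ns physical floor), and simulates the full photon stream of each
#' molecule with single-step acceptor then donor photobleaching.
#'
#' The default acceptor photobleach time is `target_donor_photons /
#' (donor_rate_hz * (1 - E))`, i.e. every molecule contributes the same
#' expected number of donor photons -- and hence of 1000-photon bunches --
#' before acceptor bleaching, regardless of state. This keeps the condition's
#' open-state amplitude identical at the molecule and at the bunch level,
#' which is what the downstream global fit estimates. Because the open-state
#' lifetime peak lies close to the donor-only reference, where the true FRET
#' efficiency -- and with it the acceptor count rate -- approaches zero, the
#' bookkeeping efficiency is floored at 0.25 so that every molecule's
#' acceptor intensity level clears the 3x-background acceptance threshold
#' and its photobleach step stays resolvable at the default rates; the
#' microtime decays are untouched by the floor.
#'
#' @param n_molecules Number of molecules.
#' @param open_fraction Probability that a molecule is in the open state.
#' @param peaks_ns Lifetime peak positions `(compact, open)`, ns.
#' @param widths_ns Gaussian peak widths `(compact, open)`, ns.
#' @param instrument An [instrument_model()].
#' @param seed Integer seed.
#' @param tau_d_ns Donor-only reference lifetime, ns.
#' @param donor_rate_hz,background_rate_hz Detection rates, photons/s.
#' @param target_donor_photons Expected donor photons per molecule before
#'   acceptor photobleaching.
#' @param post_bleach_s Donor survival time after acceptor bleaching, s.
#' @param tail_s Background-only recording tail after donor bleaching, s.
#' @param condition_id Label attached to the output.
#' @return A list of class `fret_condition` with elements `traces` (list of
#'   [photon_trace()]), `labels` (data frame `molecule_id`, `state`,
#'   `expected_lifetime_ns`), `condition_id` and `instrument`.
#' @export
simulate_condition <- function(n_molecules, open_fraction,
                               peaks_ns = c(1.3, 2.7),
                               widths_ns = c(0.35, 0.67),
                               instrument = instrument_model(), seed = 1,
                               tau_d_ns = 3.0, donor_rate_hz = 2000,
                               background_rate_hz = 200,
                               target_donor_photons = 3500,
                               post_bleach_s = 0.5, tail_s = 0.7,
                               condition_id = "condition") {
  check_scalar(n_molecules, "n_molecules", positive = TRUE)
  check_scalar(open_fraction, "open_fraction")
  if (open_fraction < 0 || open_fraction > 1)
    stop("open_fraction must be in [0, 1]")
  stopifnot(length(peaks_ns) == 2, length(widths_ns) == 2,
            all(peaks_ns > 0), all(widths_ns > 0))
  if (peaks_ns[1] >= peaks_ns[2])
    stop("compact peak must be below open peak")

  draws <- with_seed(seed, {
    state <- stats::rbinom(n_molecules, 1, open_fraction) + 1L  # 1 compact, 2 open
    tau <- stats::rnorm(n_molecules, peaks_ns[state], widths_ns[state])
    bad <- which(tau < 0.05)
    while (length(bad)) {  # truncated draw, 0.05 ns floor
      tau[bad] <- stats::rnorm(length(bad), peaks_ns[state[bad]], widths_ns[state[bad]])
      bad <- bad[tau[bad] < 0.05]
    }
    list(state = state, tau = tau)
  })

  traces <- vector("list", n_molecules)
  ids <- sprintf("%s_m%03d", condition_id, seq_len(n_molecules))
  e_clamp <- c(0.25, 0.98)
  for (i in seq_len(n_molecules)) {
    e_rate <- min(max(1 - draws$tau[i] / tau_d_ns, e_clamp[1]), e_clamp[2])
    ## equalize expected donor photons (signal + background) per molecule
    t_a <- target_donor_photons /
      (donor_rate_hz * (1 - e_rate) + background_rate_hz)
    mod <- molecule_model(tau_da_ns = draws$tau[i],
                          donor_only_lifetime_ns = tau_d_ns,
                          donor_rate_hz = donor_rate_hz,
                          background_rate_hz = background_rate_hz,
                          acceptor_bleach_time_s = t_a,
                          donor_bleach_time_s = t_a + post_bleach_s,
                          state = c("compact", "open")[draws$state[i]])
    traces[[i]] <- simulate_molecule(mod, instrument,
                                     duration_s = t_a + post_bleach_s + tail_s,
                                     seed = child_seed(seed, stage_index("simulate"), i),
                                     e_rate_bounds = e_clamp)
    traces[[i]]$molecule_id <- ids[i]
  }
  labels <- data.frame(molecule_id = ids,
                       state = c("compact", "open")[draws$state],
                       expected_lifetime_ns = draws$tau,
                       stringsAsFactors = FALSE)
  structure(list(traces = traces, labels = labels,
                 condition_id = condition_id, instrument = instrument,
                 tau_d_ns = tau_d_ns,
                 background_rate_hz = background_rate_hz,
                 donor_rate_hz = donor_rate_hz, seed = seed),
            class = "fret_condition")
}

#' @export
print.fret_condition <- function(x, ...) {
  cat(sprintf("Simulated condition '%s': %d molecules (%d open / %d compact)\n",
              x$condition_id, nrow(x$labels),
              sum(x$labels$state == "open"), sum(x$labels$state == "compact")))
  invisible(x)
}
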