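#' Instrument model for TCSPC detection
#'
#' Describes the timing side of the confocal TCSPC setup: the instrument
#' response function (IRF) and the excitation repetition rate, which sets the
#' microtime window. The IRF is either parametric (a Gaussian of given FWHM
#' centred at `irf_center_ns`) or tabulated as `(time_ns, weight)` pairs.
#'
#' @param irf_fwhm_ns Full width at half maximum of a Gaussian IRF, in ns.
#'   Use 0 for an ideal (delta) response.
#' @param irf_center_ns Centre of the Gaussian IRF within the window, ns.
#' @param irf_table Optional two-column matrix or data frame
#'   (`time_ns`, `weight`) giving a tabulated IRF; overrides the Gaussian
#'   parameters. Weights must be nonnegative and are normalized to sum to 1.
#' @param rep_rate_mhz Laser repetition rate in MHz (default 80).
#' @param tcspc_window_ns Microtime window in ns; defaults to
#'   `1000 / rep_rate_mhz`.
#' @return An object of class `instrument_model`.
#' @examples
#' instrument_model()                      # 80 MHz, Gaussian IRF 0.3 ns FWHM
#' instrument_model(irf_fwhm_ns = 0)      # ideal response
#' @export
instrument_model <- function(irf_fwhm_ns = 0.3, irf_center_ns = 0.5,
                             irf_table = NULL, rep_rate_mhz = 80,
                             tcspc_window_ns = 1000 / rep_rate_mhz) {
  check_scalar(rep_rate_mhz, "rep_rate_mhz", positive = TRUE)
  check_scalar(tcspc_window_ns, "tcspc_window_ns", positive = TRUE)
  if (is.null(irf_table)) {
    check_scalar(irf_fwhm_ns, "irf_fwhm_ns", nonneg = TRUE)
    check_scalar(irf_center_ns, "irf_center_ns")
  } else {
    irf_table <- as.data.frame(irf_table)
    names(irf_table)[1:2] <- c("time_ns", "weight")
    if (any(!is.finite(irf_table$time_ns)) || any(!is.finite(irf_table$weight)))
      stop("tabulated IRF must be finite")
    if (any(irf_table$weight < 0)) stop("tabulated IRF weights must be nonnegative")
    s <- sum(irf_table$weight)
    if (s <= 0) stop("tabulated IRF weights sum to zero")
    irf_table$weight <- irf_table$weight / s
    irf_table <- irf_table[order(irf_table$time_ns), ]
  }
  structure(list(irf_fwhm_ns = irf_fwhm_ns, irf_center_ns = irf_center_ns,
                 irf_table = irf_table, rep_rate_mhz = rep_rate_mhz,
                 tcspc_window_ns = tcspc_window_ns),
            class = "instrument_model")
}

#' @export
print.instrument_model <- function(x, ...) {
  cat("TCSPC instrument model\n")
  cat(sprintf("  repetition rate: %g MHz (window %.4g ns)\n",
              x$rep_rate_mhz, x$tcspc_window_ns))
  if (is.null(x$irf_table))
    cat(sprintf("  IRF: Gaussian, FWHM %.3g ns, centre %.3g ns\n",
                x$irf_fwhm_ns, x$irf_center_ns))
  else
    cat(sprintf("  IRF: tabulated, %d points\n", nrow(x$irf_table)))
  invisible(x)
}

irf_sigma <- function(instrument) instrument$irf_fwhm_ns / (2 * sqrt(2 * log(2)))

## Draw n IRF delays (ns) from the instrument response.
irf_draw <- function(n, instrument) {
  if (is.null(instrument$irf_table)) {
    if (instrument$irf_fwhm_ns <= 0) rep(instrument$irf_center_ns, n)
    else stats::rnorm(n, instrument$irf_center_ns, irf_sigma(instrument))
  } else {
    sample(instrument$irf_table$time_ns, n, replace = TRUE,
           prob = instrument$irf_table$weight)
  }
}

#' Single-molecule photophysical model
#'
#' Parameters for one immobilized donor/acceptor-labelled molecule. Either a
#' donor-acceptor distance (from which the FRET efficiency and the quenched
#' donor lifetime follow through the Forster relation) or the quenched
#' lifetime `tau_da_ns` itself may be given. While the acceptor is intact the
#' donor decays with lifetime `tau_D * (1 - E)`; after single-step acceptor
#' photobleaching it reverts to the donor-only lifetime, and after donor
#' photobleaching only background remains.
#'
#' @param distance_nm Donor-acceptor distance in nm (alternative to
#'   `tau_da_ns`).
#' @param tau_da_ns Donor lifetime in presence of the acceptor, ns
#'   (alternative to `distance_nm`).
#' @param forster_radius_nm Forster distance of the dye pair, nm.
#' @param donor_only_lifetime_ns Donor-only reference lifetime, ns.
#' @param donor_rate_hz Detected donor count rate in the absence of FRET
#'   (photons/s); the emitted donor rate is scaled by `1 - E`.
#' @param background_rate_hz Background count rate per channel (photons/s).
#' @param donor_bleach_time_s,acceptor_bleach_time_s Single-step photobleach
#'   times, s.
#' @param state Optional conformational state label ("compact" or "open").
#' @return An object of class `molecule_model` with derived fields
#'   `efficiency` and `tau_da_ns`.
#' @examples
#' m <- molecule_model(distance_nm = 8.4)   # at r0: E = 0.5
#' m$efficiency
#' @export
molecule_model <- function(distance_nm = NULL, tau_da_ns = NULL,
                           forster_radius_nm = 8.4,
                           donor_only_lifetime_ns = 3.0,
                           donor_rate_hz = 2000, background_rate_hz = 200,
                           donor_bleach_time_s = 5,
                           acceptor_bleach_time_s = 2,
                           state = NA_character_) {
  check_scalar(forster_radius_nm, "forster_radius_nm", positive = TRUE)
  check_scalar(donor_only_lifetime_ns, "donor_only_lifetime_ns", positive = TRUE)
  check_scalar(donor_rate_hz, "donor_rate_hz", positive = TRUE)
  check_scalar(background_rate_hz, "background_rate_hz", nonneg = TRUE)
  check_scalar(donor_bleach_time_s, "donor_bleach_time_s", nonneg = TRUE)
  check_scalar(acceptor_bleach_time_s, "acceptor_bleach_time_s", nonneg = TRUE)
  if (is.null(distance_nm) && is.null(tau_da_ns))
    stop("give either 'distance_nm' or 'tau_da_ns'")
  if (!is.null(distance_nm)) {
    check_scalar(distance_nm, "distance_nm", positive = TRUE)
    eff <- 1 / (1 + (distance_nm / forster_radius_nm)^6)
    tau_da_ns <- donor_only_lifetime_ns * (1 - eff)
  } else {
    check_scalar(tau_da_ns, "tau_da_ns", positive = TRUE)
    eff <- 1 - tau_da_ns / donor_only_lifetime_ns
    distance_nm <- if (eff > 0 && eff < 1)
      forster_radius_nm * ((1 - eff) / eff)^(1 / 6) else NA_real_
  }
  structure(list(distance_nm = distance_nm, tau_da_ns = tau_da_ns,
                 efficiency = eff,
                 forster_radius_nm = forster_radius_nm,
                 donor_only_lifetime_ns = donor_only_lifetime_ns,
                 donor_rate_hz = donor_rate_hz,
                 background_rate_hz = background_rate_hz,
                 donor_bleach_time_s = donor_bleach_time_s,
                 acceptor_bleach_time_s = acceptor_bleach_time_s,
                 state = state),
            class = "molecule_model")
}

#' @export
print.molecule_model <- function(x, ...) {
  cat("Single-molecule model\n")
  cat(sprintf("  tau_DA = %.3g ns (E = %.3g, r = %.3g nm, r0 = %.3g nm)\n",
              x$tau_da_ns, x$efficiency, x$distance_nm, x$forster_radius_nm))
  cat(sprintf("  donor rate %g /s, background %g /s; bleach D %.3g s / A %.3g s\n",
              x$donor_rate_hz, x$background_rate_hz,
              x$donor_bleach_time_s, x$acceptor_bleach_time_s))
  invisible(x)
}
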