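#' Pipeline configuration
#'
#' Assembles every stage parameter with defaults at the standard analysis
#' values: 100-ms intensity binning, 1000-photon bunches, lifetime bounds
#' 0.05-10 ns, background threshold 3x, Forster distances 8.4/7.5 nm,
#' 16 Angstrom contact cutoff and the P <= 0.001 significance level used in
#' condition comparisons.
#'
#' @param conditions List of per-condition specs; each a list with
#'   `condition_id`, and either `open_fraction` (+ optional `n_molecules`)
#'   for simulation or `photon_csv` for measured input. Optional per-condition
#'   `r0_nm`, `tau_d_ns`, `lipid_label`, `egf`.
#' @param instrument An [instrument_model()].
#' @param seed Master seed; stage and molecule seeds are split
#'   deterministically from it (see [child_seed()] scheme in the sources).
#' @param bin_width_s,bunch_size,penalty,bounds,threshold_factor Stage
#'   parameters (see the stage functions).
#' @param peaks_ns,widths_ns Generator peak model for simulated conditions.
#' @param donor_rate_hz,background_rate_hz Generator rates.
#' @param n_molecules Default molecules per simulated condition.
#' @param n_starts Global-fit EM starts.
#' @param r0_nm,tau_d_ns Default FRET calibration.
#' @param md Optional MD inputs: a list with any of `windows` (umbrella
#'   windows), `metric_values` (per-sample metric to reweight), `frames`
#'   (list of [cg_frame()]), `contact_def` (a [contact_definition()]).
#' @param out_dir Optional output directory for CSV/JSON artifacts.
#' @return A list of class `run_config`.
#' @export
run_config <- function(conditions, instrument = instrument_model(), seed = 1,
                       bin_width_s = 0.1, bunch_size = 1000, penalty = NULL,
                       bounds = c(0.05, 10), threshold_factor = 3,
                       peaks_ns = c(1.3, 2.7), widths_ns = c(0.35, 0.67),
                       donor_rate_hz = 2000, background_rate_hz = 200,
                       n_molecules = 100, n_starts = 10,
                       r0_nm = 8.4, tau_d_ns = 3.0, md = NULL,
                       out_dir = NULL) {
  structure(list(conditions = conditions, instrument = instrument, seed = seed,
                 bin_width_s = bin_width_s, bunch_size = bunch_size,
                 penalty = penalty, bounds = bounds,
                 threshold_factor = threshold_factor, peaks_ns = peaks_ns,
                 widths_ns = widths_ns, donor_rate_hz = donor_rate_hz,
                 background_rate_hz = background_rate_hz,
                 n_molecules = n_molecules, n_starts = n_starts,
                 r0_nm = r0_nm, tau_d_ns = tau_d_ns, md = md,
                 out_dir = out_dir),
            class = "run_config")
}

#' Bundled demonstration configuration
#'
#' Two simulated conditions at the physiological anionic-lipid composition
#' (30% POPS) without and with EGF, at open-state amplitudes 0.74 and 0.96.
#'
#' @param seed Master seed.
#' @param n_molecules Molecules per condition.
#' @return A [run_config()].
#' @export
demo_config <- function(seed = 1, n_molecules = 150) {
  run_config(conditions = list(
    list(condition_id = "POPS30_noEGF", open_fraction = 0.74,
         lipid_label = "30% POPS", egf = FALSE),
    list(condition_id = "POPS30_EGF", open_fraction = 0.96,
         lipid_label = "30% POPS", egf = TRUE)),
    n_molecules = n_molecules, seed = seed)
}

#' Run the full conformational-analysis pipeline
#'
#' Executes simulate (for conditions given as ensembles) -> intensity
#' binning -> change-point segmentation -> single-bleach filtering -> FRET
#' level assignment -> per-bunch lifetime MLE -> global two-state fit ->
#' distance conversion, plus WHAM reweighting and contact metrics when MD
#' inputs are present. Each molecule's randomness is seeded in isolation
#' from the master seed, so a rerun with the same configuration reproduces
#' every number.
#'
#' @param config A [run_config()].
#' @return A list of class `run_report`: per-condition acceptance counts and
#'   reject reasons, per-bunch lifetime table, the [fret_global_fit()]
#'   object, peak distance conversions, optional MD results, `config_hash`
#'   and `seed`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  t0 <- Sys.time()
  bg_per_bin <- config$background_rate_hz * config$bin_width_s

  all_bunches <- list()
  cond_stats <- list()
  for (ci in seq_along(config$conditions)) {
    spec <- config$conditions[[ci]]
    cid <- spec$condition_id %||% sprintf("condition_%d", ci)
    if (!is.null(spec$photon_csv)) {
      traces <- read_photon_csv(spec$photon_csv,
                                window_ns = config$instrument$tcspc_window_ns)
    } else {
      sim <- simulate_condition(
        n_molecules = spec$n_molecules %||% config$n_molecules,
        open_fraction = spec$open_fraction,
        peaks_ns = config$peaks_ns, widths_ns = config$widths_ns,
        instrument = config$instrument,
        seed = child_seed(config$seed, stage_index("simulate"), ci),
        tau_d_ns = spec$tau_d_ns %||% config$tau_d_ns,
        donor_rate_hz = config$donor_rate_hz,
        background_rate_hz = config$background_rate_hz,
        condition_id = cid)
      traces <- sim$traces
    }

    reasons <- character(0)
    bunches <- list()
    for (tr in traces) {
      it <- bin_trace(tr, config$bin_width_s)
      ## the flagged partial last bin is excluded from segmentation
      if (it$partial_last && it$n_bins > 1) {
        it$donor <- it$donor[-it$n_bins]
        it$acceptor <- it$acceptor[-it$n_bins]
        it$n_bins <- it$n_bins - 1L
      }
      if (it$n_bins < 2) { reasons <- c(reasons, "too_short"); next }
      dseg <- detect_change_points(it, "donor", config$penalty)
      aseg <- detect_change_points(it, "acceptor", config$penalty)
      dec <- filter_single_bleach(dseg, aseg, background_per_bin = bg_per_bin,
                                  threshold_factor = config$threshold_factor)
      reasons <- c(reasons, dec$reason)
      if (!dec$accepted) next
      levels <- assign_fret_levels(tr, dseg, dec$acceptor_bleach_bin,
                                   donor_bleach_bin = dec$donor_bleach_bin,
                                   bin_width_s = config$bin_width_s)
      if (length(levels) == 0) next
      ## background fraction from the post-donor-bleach segment rate
      bg_rate <- dseg$mean_rate[nrow(dseg)]
      for (lev in levels) {
        seg_rate <- max(lev$n_photons / (lev$duration_s / config$bin_width_s),
                        bg_rate + 1e-9)
        bf <- min(bg_rate / seg_rate, 0.5)
        est <- fit_trace_lifetimes(tr, list(lev), config$instrument,
                                   background_fraction = bf,
                                   bunch_size = config$bunch_size,
                                   bounds = config$bounds)
        if (nrow(est)) bunches[[length(bunches) + 1L]] <- est
      }
    }
    bunch_df <- if (length(bunches)) do.call(rbind, bunches) else
      data.frame(molecule_id = character(0), level_index = integer(0),
                 bunch_index = integer(0), n_photons = integer(0),
                 lifetime_ns = numeric(0), flagged = logical(0))
    bunch_df$condition <- cid
    all_bunches[[ci]] <- bunch_df
    cond_stats[[ci]] <- list(
      condition_id = cid,
      n_traces = length(traces),
      n_accepted = sum(reasons == "ok"),
      n_rejected = sum(reasons != "ok"),
      reject_reasons = table(reasons[reasons != "ok"]),
      n_bunches = nrow(bunch_df), n_flagged = sum(bunch_df$flagged),
      r0_nm = spec$r0_nm %||% config$r0_nm,
      tau_d_ns = spec$tau_d_ns %||% config$tau_d_ns)
  }

  bunch_all <- do.call(rbind, all_bunches)
  clean <- bunch_all[!bunch_all$flagged, ]
  fit <- fret_global_fit(clean$lifetime_ns, condition = clean$condition,
                         n_starts = config$n_starts,
                         seed = child_seed(config$seed, stage_index("globalfit")))

  distances <- do.call(rbind, lapply(cond_stats, function(cs) {
    cal <- fret_calibration(cs$r0_nm, cs$tau_d_ns)
    ok <- x <- NULL
    ok <- fit$mu < cs$tau_d_ns
    d <- rep(NA_real_, 2)
    if (any(ok)) d[ok] <- lifetime_to_distance(fit$mu[ok], cal)$distance_nm
    data.frame(condition = cs$condition_id,
               state = c("compact", "open"), peak_ns = fit$mu,
               distance_nm = round(d, 1), distance_round_nm = round(d))
  }))

  md_out <- NULL
  md_skipped <- is.null(config$md)
  if (!md_skipped) {
    md_out <- list()
    if (!is.null(config$md$windows)) {
      md_out$wham <- wham_solve(config$md$windows)
      if (!is.null(config$md$metric_values))
        md_out$reweighted <- reweighted_average(
          config$md$metric_values, md_out$wham,
          seed = child_seed(config$seed, stage_index("wham")))
    }
    if (!is.null(config$md$frames)) {
      cdef <- config$md$contact_def %||% contact_definition()
      md_out$contact_numbers <- vapply(config$md$frames, contact_number,
                                       numeric(1), definition = cdef)
    }
  }

  report <- structure(list(
    config_hash = config_hash(unclass(config)), seed = config$seed,
    conditions = cond_stats, bunches = bunch_all, fit = fit,
    distances = distances, md = md_out,
    md_stages_skipped = md_skipped,
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))),
    class = "run_report")

  if (!is.null(config$out_dir)) write_run_report(report, config$out_dir)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("Pipeline run %s (seed %s, %.1f s)\n", x$config_hash,
              format(x$seed), x$elapsed_s))
  for (cs in x$conditions)
    cat(sprintf("  %-20s traces %3d  accepted %3d  rejected %3d  bunches %4d\n",
                cs$condition_id, cs$n_traces, cs$n_accepted, cs$n_rejected,
                cs$n_bunches))
  print(x$fit)
  cat("Peak distances (nm):\n")
  print(x$distances, row.names = FALSE)
  if (x$md_stages_skipped) cat("MD stages skipped (no MD inputs).\n")
  invisible(x)
}

#' Write pipeline artifacts
#'
#' Writes the per-bunch lifetime CSV, per-condition display-histogram CSV
#' and a JSON fit report into `out_dir`.
#'
#' @param report A `run_report` from [run_pipeline()].
#' @param out_dir Output directory (created if missing).
#' @return `out_dir`, invisibly.
#' @export
write_run_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_bunches_csv(report$bunches, file.path(out_dir, "bunch_lifetimes.csv"))
  fit <- report$fit
  hists <- do.call(rbind, lapply(fit$conditions, function(cc) {
    tau <- fit$data$lifetime_ns[fit$data$condition == cc]
    nb <- sqrt_rule_bins(length(tau))
    edges <- seq(min(tau), max(tau), length.out = nb + 1)
    data.frame(condition = cc, bin_mid = (edges[-1] + edges[-(nb + 1)]) / 2,
               count = tabulate(pmin(pmax(findInterval(tau, edges), 1L), nb), nb))
  }))
  utils::write.csv(hists, file.path(out_dir, "lifetime_histograms.csv"),
                   row.names = FALSE)
  json <- list(config_hash = report$config_hash, seed = report$seed,
               shared = list(mu_ns = fit$mu, sigma_ns = fit$sigma),
               amplitudes = as.list(fit$amplitude),
               standard_errors = as.list(fit$se),
               distances = report$distances,
               conditions = lapply(report$conditions, function(cs)
                 cs[c("condition_id", "n_traces", "n_accepted", "n_rejected",
                      "n_bunches")]))
  jsonlite::write_json(json, file.path(out_dir, "fit_report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
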