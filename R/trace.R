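#' Bin a photon trace into an intensity time trace
#'
#' Counts donor- and acceptor-channel photons in consecutive bins of
#' `bin_width_s` (default 100 ms, the standard resolution for intensity
#' traces of immobilized molecules). Bin k covers `[k w, (k+1) w)`; the last,
#' generally partial, bin is retained and flagged.
#'
#' @param trace A [photon_trace()].
#' @param bin_width_s Bin width in seconds.
#' @return An object of class `intensity_trace` with integer count vectors
#'   `donor` and `acceptor`, `bin_width_s`, `n_bins` and `partial_last`.
#' @export
bin_trace <- function(trace, bin_width_s = 0.1) {
  stopifnot(inherits(trace, "photon_trace"))
  check_scalar(bin_width_s, "bin_width_s", positive = TRUE)
  mt <- trace$macrotimes_s
  if (length(mt) == 0) {
    return(structure(list(bin_width_s = bin_width_s, donor = integer(0),
                          acceptor = integer(0), n_bins = 0L,
                          partial_last = FALSE, molecule_id = trace$molecule_id),
                     class = "intensity_trace"))
  }
  n_bins <- floor(max(mt) / bin_width_s) + 1L
  idx <- pmin(floor(mt / bin_width_s), n_bins - 1L) + 1L
  donor <- tabulate(idx[trace$channels == "donor"], n_bins)
  acceptor <- tabulate(idx[trace$channels == "acceptor"], n_bins)
  structure(list(bin_width_s = bin_width_s, donor = donor, acceptor = acceptor,
                 n_bins = n_bins,
                 partial_last = (n_bins * bin_width_s) > max(mt),
                 molecule_id = trace$molecule_id),
            class = "intensity_trace")
}

#' @export
print.intensity_trace <- function(x, ...) {
  cat(sprintf("Intensity trace: %d bins of %g s (donor %d, acceptor %d photons)\n",
              x$n_bins, x$bin_width_s, sum(x$donor), sum(x$acceptor)))
  invisible(x)
}

## Poisson profile log-likelihood of a segment: S log(S/n) (the -S term
## cancels in likelihood-ratio statistics).
seg_ll <- function(S, n) ifelse(S > 0, S * log(S / n), 0)

## best split of counts x: returns (position after which to split, 2*dlogL)
best_split <- function(x) {
  n <- length(x)
  cs <- cumsum(x); S <- cs[n]
  k <- seq_len(n - 1)
  stat <- 2 * (seg_ll(cs[k], k) + seg_ll(S - cs[k], n - k) - seg_ll(S, n))
  j <- which.max(stat)  # ties resolved toward the earliest bin
  c(j, stat[j])
}

#' Detect intensity change points by recursive binary segmentation
#'
#' Segments one channel of a binned intensity trace into regions of constant
#' mean rate. At each step the Poisson likelihood-ratio statistic
#' `2 dlogL` is maximized over candidate split points and the split is
#' accepted when it exceeds `penalty` (default `2 ln(n_bins)`, a BIC-type
#' penalty for the two extra parameters of a change point); accepted splits
#' are recursed into. Segment rates are the maximum-likelihood segment means.
#'
#' @param intensity An [bin_trace()] result.
#' @param channel "donor" or "acceptor".
#' @param penalty Acceptance threshold for `2 dlogL`.
#' @return Data frame with columns `channel`, `start_bin`, `end_bin`
#'   (half-open, 0-based) and `mean_rate` (counts/bin); segments tile the
#'   trace.
#' @export
detect_change_points <- function(intensity, channel = c("donor", "acceptor"),
                                 penalty = NULL) {
  stopifnot(inherits(intensity, "intensity_trace"))
  channel <- match.arg(channel)
  x <- intensity[[channel]]
  n <- length(x)
  if (n == 0)
    return(data.frame(channel = character(0), start_bin = integer(0),
                      end_bin = integer(0), mean_rate = numeric(0)))
  penalty <- penalty %||% (2 * log(max(n, 2)))
  check_scalar(penalty, "penalty", positive = TRUE)

  breaks <- integer(0)
  recurse <- function(lo, hi) {  # half-open [lo, hi), 0-based
    if (hi - lo < 2) return(invisible())
    bs <- best_split(x[(lo + 1):hi])
    if (bs[2] > penalty) {
      cut <- lo + bs[1]
      breaks <<- c(breaks, cut)
      recurse(lo, cut)
      recurse(cut, hi)
    }
    invisible()
  }
  recurse(0L, n)
  b <- sort(unique(c(0L, breaks, n)))
  starts <- b[-length(b)]; ends <- b[-1]
  data.frame(channel = channel, start_bin = starts, end_bin = ends,
             mean_rate = vapply(seq_along(starts), function(i)
               mean(x[(starts[i] + 1):ends[i]]), numeric(1)))
}

## Absorb single-bin "transitional" segments -- a boundary bin containing a
## mid-bin rate change, whose rate falls monotonically between its
## neighbours' -- into the following segment. Only length-1 segments are
## touched, so genuine intermediate intensity levels are preserved.
merge_transitional <- function(seg) {
  repeat {
    r <- seg$mean_rate; k <- length(r)
    if (k < 3) return(seg)
    len1 <- (seg$end_bin - seg$start_bin) == 1
    i <- which(len1[-c(1, k)]) + 1L
    i <- i[(r[i] - r[i - 1]) * (r[i + 1] - r[i]) > 0]  # monotone between neighbours
    if (length(i) == 0) return(seg)
    i <- i[1]
    seg$start_bin[i + 1] <- seg$start_bin[i]
    seg <- seg[-i, , drop = FALSE]
    rownames(seg) <- NULL
  }
}

#' Select traces with a single donor and acceptor photobleaching step
#'
#' A channel is accepted when its final segment sits at the background level
#' (mean rate at or below `threshold` counts/bin, default 3x the expected
#' background counts per bin) and exactly one downward rate transition --
#' the photobleaching step -- exists. Intensity rises are permitted both
#' before the step (e.g. donor de-quenching at acceptor photobleach) and,
#' within the background band, after it. Single-bin transitional segments
#' produced by a rate change inside one bin are absorbed before the check.
#'
#' @param donor_segments,acceptor_segments Segment tables from
#'   [detect_change_points()] for the two channels of one trace.
#' @param background_per_bin Expected background counts per bin.
#' @param threshold_factor Multiple of the background defining "bleached".
#' @param threshold Absolute threshold in counts/bin; overrides the factor.
#' @return A list with `accepted` (logical), `reason` ("ok" or a reject
#'   code: "no_donor_bleach", "multi_step_donor", "no_acceptor_bleach",
#'   "multi_step_acceptor"), `donor_bleach_bin`, `acceptor_bleach_bin`
#'   (0-based first bin after the bleaching step, NA on reject).
#' @export
filter_single_bleach <- function(donor_segments, acceptor_segments,
                                 background_per_bin = 0,
                                 threshold_factor = 3, threshold = NULL) {
  threshold <- threshold %||% (threshold_factor * background_per_bin)
  check_one <- function(seg, lab) {
    seg <- merge_transitional(seg)
    r <- seg$mean_rate
    k <- length(r)
    if (k == 0 || r[k] > threshold)
      return(list(ok = FALSE, reason = paste0("no_", lab, "_bleach"), bin = NA))
    below <- r <= threshold
    ## terminal background region = maximal trailing run at/below threshold
    j <- k
    while (j > 1 && below[j - 1]) j <- j - 1
    if (j == 1)  # never rose above background: no bleaching step visible
      return(list(ok = FALSE, reason = paste0("no_", lab, "_bleach"), bin = NA))
    pre_above <- which(!below[seq_len(j - 1)])
    ## a dark interlude between bright segments, or a second drop between
    ## bright levels before the terminal region, is a multi-step trace
    if (length(pre_above) && any(below[seq_len(j - 1)][seq(min(pre_above), j - 1)]))
      return(list(ok = FALSE, reason = paste0("multi_step_", lab), bin = NA))
    if (length(pre_above) > 1 && any(diff(r[pre_above]) < 0))
      return(list(ok = FALSE, reason = paste0("multi_step_", lab), bin = NA))
    list(ok = TRUE, reason = "ok", bin = seg$start_bin[j])
  }
  d <- check_one(donor_segments, "donor")
  if (!d$ok)
    return(list(accepted = FALSE, reason = d$reason,
                donor_bleach_bin = NA, acceptor_bleach_bin = NA))
  a <- check_one(acceptor_segments, "acceptor")
  if (!a$ok)
    return(list(accepted = FALSE, reason = a$reason,
                donor_bleach_bin = NA, acceptor_bleach_bin = NA))
  list(accepted = TRUE, reason = "ok",
       donor_bleach_bin = d$bin, acceptor_bleach_bin = a$bin)
}

#' Assign donor FRET levels up to acceptor photobleaching
#'
#' Each donor segment lying wholly before the acceptor bleach bin becomes one
#' FRET level; a segment straddling the bleach bin is truncated at it.
#' Levels map back to 0-based indices into the trace's donor photon list for
#' lifetime fitting.
#'
#' @param trace A [photon_trace()].
#' @param donor_segments Donor segment table from [detect_change_points()].
#' @param acceptor_bleach_bin 0-based acceptor bleach bin.
#' @param donor_bleach_bin Optional 0-based donor bleach bin; segments at or
#'   beyond it are dropped.
#' @param bin_width_s Bin width used for the segmentation, s.
#' @return List of `fret_level` objects with fields `molecule_id`,
#'   `level_index`, `photon_range` (0-based half-open into the donor photon
#'   list), `duration_s`, `n_photons`.
#' @export
assign_fret_levels <- function(trace, donor_segments, acceptor_bleach_bin,
                               donor_bleach_bin = Inf, bin_width_s = 0.1) {
  stopifnot(inherits(trace, "photon_trace"))
  donor_t <- trace$macrotimes_s[trace$channels == "donor"]
  levels <- list()
  li <- 0L
  for (i in seq_len(nrow(donor_segments))) {
    s <- donor_segments$start_bin[i]
    e <- min(donor_segments$end_bin[i], acceptor_bleach_bin, donor_bleach_bin)
    if (e <= s) next
    lo <- s * bin_width_s; hi <- e * bin_width_s
    idx <- which(donor_t >= lo & donor_t < hi)
    if (length(idx) == 0) next
    li <- li + 1L
    levels[[li]] <- structure(
      list(molecule_id = trace$molecule_id, level_index = li,
           photon_range = c(idx[1] - 1L, idx[length(idx)]),
           duration_s = hi - lo, n_photons = length(idx)),
      class = "fret_level")
  }
  levels
}
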