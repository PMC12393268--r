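test_that("intensity binning covers the trace and conserves photons", {
  tr <- photon_trace("m", c(seq(0.05, 0.95, by = 0.1), 0.999),
                     rep(1, 11), rep("donor", 11), 12.5)
  it <- bin_trace(tr, 0.1)
  expect_equal(it$n_bins, 10L)

  tr2 <- photon_trace("m", c(0.05, 0.15, 0.151), rep(1, 3),
                      rep("donor", 3), 12.5)
  expect_equal(bin_trace(tr2, 0.1)$donor, c(1L, 2L))

  m <- molecule_model(distance_nm = 8.4, donor_bleach_time_s = 1,
                      acceptor_bleach_time_s = 0.5)
  tr3 <- simulate_molecule(m, instrument_model(), 1.5, seed = 8)
  it3 <- bin_trace(tr3)
  expect_equal(sum(it3$donor), sum(tr3$channels == "donor"))
  expect_equal(sum(it3$acceptor), sum(tr3$channels == "acceptor"))

  empty <- photon_trace("m", numeric(0), numeric(0), character(0), 12.5)
  expect_equal(bin_trace(empty)$n_bins, 0L)
})

test_that("a noiseless intensity step is split exactly at the true break", {
  it <- mk_intensity(c(rep(100L, 50), rep(20L, 50)))
  seg <- detect_change_points(it, "donor")
  expect_equal(seg$start_bin, c(0L, 50L))
  expect_equal(seg$mean_rate, c(100, 20))

  zero <- detect_change_points(mk_intensity(rep(0L, 30)), "donor")
  expect_equal(nrow(zero), 1L)
  expect_equal(zero$mean_rate, 0)
})

test_that("constant-rate traces are rarely split and Poisson steps localize", {
  n_fp <- 0; n_loc <- 0
  for (r in 1:100) {
    x <- fretstates:::with_seed(3000 + r, stats::rpois(100, 50))
    n_fp <- n_fp + (nrow(detect_change_points(mk_intensity(x), "donor")) > 1)
    y <- fretstates:::with_seed(4000 + r,
                                c(stats::rpois(50, 100), stats::rpois(50, 20)))
    seg <- detect_change_points(mk_intensity(y), "donor")
    n_loc <- n_loc + any(abs(seg$start_bin[-1] - 50) <= 2)
  }
  expect_lte(n_fp, 8)     # false-split rate near the BIC-penalty design point
  expect_gte(n_loc, 95)
})

test_that("segmentation shifts with prepended background bins", {
  y <- fretstates:::with_seed(21, c(stats::rpois(50, 100), stats::rpois(50, 20)))
  cuts <- detect_change_points(mk_intensity(y), "donor")$start_bin[-1]
  y2 <- c(rep(0L, 10), y)
  cuts2 <- detect_change_points(mk_intensity(y2), "donor")$start_bin[-1]
  expect_true(all((cuts + 10) %in% cuts2))
})

test_that("single-bleach filtering accepts one step down to background only", {
  d <- mk_segments(c(100, 2), lens = c(40, 10))
  a <- mk_segments(c(80, 2), lens = c(30, 20), channel = "acceptor")
  dec <- filter_single_bleach(d, a, threshold = 6)
  expect_true(dec$accepted)
  expect_equal(dec$donor_bleach_bin, 40L)
  expect_equal(dec$acceptor_bleach_bin, 30L)

  multi <- filter_single_bleach(mk_segments(c(100, 60, 2), c(20, 20, 10)), a,
                                threshold = 6)
  expect_false(multi$accepted)
  expect_equal(multi$reason, "multi_step_donor")

  nob <- filter_single_bleach(mk_segments(c(100, 60), c(20, 20)), a,
                              threshold = 6)
  expect_false(nob$accepted)
  expect_equal(nob$reason, "no_donor_bleach")

  noa <- filter_single_bleach(d, mk_segments(c(80, 70), c(20, 20), "acceptor"),
                              threshold = 6)
  expect_equal(noa$reason, "no_acceptor_bleach")
})

test_that("transitional single-bin segments and background-band splits are tolerated", {
  ## one bin straddling the bleach: rate between the neighbours'
  d <- mk_segments(c(100, 55, 2), lens = c(30, 1, 9))
  a <- mk_segments(c(80, 2), lens = c(25, 15), channel = "acceptor")
  dec <- filter_single_bleach(d, a, threshold = 6)
  expect_true(dec$accepted)
  expect_equal(dec$donor_bleach_bin, 30L)

  ## spurious split inside the background band after the step
  d2 <- mk_segments(c(100, 1.5, 3), lens = c(30, 6, 6))
  expect_true(filter_single_bleach(d2, a, threshold = 6)$accepted)

  ## a dark interlude between bright levels is still a multi-step trace
  d3 <- mk_segments(c(100, 2, 100, 2), lens = c(10, 10, 10, 10))
  expect_equal(filter_single_bleach(d3, a, threshold = 6)$reason,
               "multi_step_donor")
})

test_that("FRET levels end at acceptor photobleaching", {
  n <- 1200
  tr <- photon_trace("m", seq(0, 11.999, length.out = n), rep(1, n),
                     rep("donor", n), 12.5)
  segs <- data.frame(channel = "donor", start_bin = c(0L, 50L),
                     end_bin = c(50L, 120L), mean_rate = c(10, 10))
  lev <- assign_fret_levels(tr, segs, acceptor_bleach_bin = 120)
  expect_length(lev, 2)
  expect_equal(sum(vapply(lev, `[[`, numeric(1), "n_photons")), n)

  lev2 <- assign_fret_levels(tr, segs, acceptor_bleach_bin = 80)
  expect_length(lev2, 2)
  expect_equal(lev2[[2]]$duration_s, 3, tolerance = 1e-9)

  expect_length(assign_fret_levels(tr, segs, acceptor_bleach_bin = 0), 0)

  ## no donor photon index is used twice and all lie before the bleach
  idx <- unlist(lapply(lev2, function(l)
    seq(l$photon_range[1], l$photon_range[2] - 1)))
  expect_false(any(duplicated(idx)))
  donor_t <- tr$macrotimes_s[tr$channels == "donor"]
  expect_true(all(donor_t[idx + 1] < 80 * 0.1))
})

test_that("detected donor bleach bins track the true bleach times", {
  hits <- 0; n_mol <- 150
  for (i in seq_len(n_mol)) {
    m <- molecule_model(distance_nm = 8.4, donor_bleach_time_s = 1.5,
                        acceptor_bleach_time_s = 1.0)
    tr <- simulate_molecule(m, instrument_model(), duration_s = 2.1,
                            seed = 5000 + i)
    it <- bin_trace(tr)
    if (it$partial_last && it$n_bins > 1) {
      it$donor <- it$donor[-it$n_bins]; it$acceptor <- it$acceptor[-it$n_bins]
      it$n_bins <- it$n_bins - 1L
    }
    dec <- filter_single_bleach(detect_change_points(it, "donor"),
                                detect_change_points(it, "acceptor"),
                                background_per_bin = 20)
    if (isTRUE(dec$accepted) && abs(dec$donor_bleach_bin - 15) <= 2)
      hits <- hits + 1
  }
  expect_gte(hits / n_mol, 0.9)
})
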