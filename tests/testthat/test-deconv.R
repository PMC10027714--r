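test_that("direct DDA linking returns the scan at the highest elution intensity", {
  # one isolated chemical: its single spectrum is returned
  one <- make_chems(mz = 350, rt = 200, apex = 1e6)
  run <- run_acquisition(one, controller_topn())
  linked <- link_dda_ground_truth(run, one)
  expect_named(linked, "X1")
  expect_equal(linked$X1$provenance, "direct-dda")

  # the chosen scan is the targeting scan closest to the apex
  scan_rts <- run$rt[vapply(run$ground_truth_links, function(l)
    !is.null(l) && 1L %in% l, logical(1L))]
  elut <- vapply(scan_rts, function(t)
    chromatogram_intensity(one, t, floor = 0), numeric(1L))
  expect_equal(run$rt[linked$X1$scan_id], scan_rts[which.max(elut)])

  # a chemical below the Top-N intensity threshold is never linked
  weak <- make_chems(mz = c(350, 500), rt = c(200, 200), apex = c(1e6, 4000))
  run2 <- run_acquisition(weak, controller_topn())
  linked2 <- link_dda_ground_truth(run2, weak)
  expect_false("X2" %in% names(linked2))

  # runs without a sidecar are rejected
  run3 <- run2
  run3$ground_truth_links <- NULL
  expect_error(link_dda_ground_truth(run3, weak), "links")
})

test_that("scan-to-feature assignment respects bounding boxes and intensity", {
  feat <- data.frame(feature_id = "F1", mz = 150.3, rt = 100,
                     intensity = 1e6, mz_lo = 150.2, mz_hi = 150.4,
                     rt_lo = 90, rt_hi = 110, stringsAsFactors = FALSE)
  class(feat) <- c("feature_table", "data.frame")
  mk_ms2 <- function(id, rt, win, pint) msacquisim:::new_scan(
    id, 2L, rt, cbind(mz = c(80, 90, 95), intensity = c(1, 2, 3) * pint),
    isolation_window = win, precursor_mz = mean(win),
    precursor_intensity = pint)

  inside <- mk_ms2(1L, 100, c(150.0, 150.7), 1e5)
  expect_named(assign_dda_scans_to_features(list(inside), feat), "F1")

  outside_rt <- mk_ms2(2L, 130, c(150.0, 150.7), 1e5)
  expect_length(assign_dda_scans_to_features(list(outside_rt), feat), 0)

  outside_mz <- mk_ms2(3L, 100, c(151.0, 151.7), 1e5)
  expect_length(assign_dda_scans_to_features(list(outside_mz), feat), 0)

  stronger <- mk_ms2(4L, 105, c(150.0, 150.7), 5e5)
  got <- assign_dda_scans_to_features(list(inside, stronger), feat)
  expect_equal(got$F1$scan_id, 4L)
  expect_equal(got$F1$provenance, "assigned-dda")
})

test_that("chemical-feature matching picks the closest m/z within tolerance", {
  ch <- make_chems(mz = 500, rt = 200, apex = 1e6)
  mkfeat <- function(mz, rt) {
    f <- data.frame(feature_id = paste0("F", seq_along(mz)), mz = mz, rt = rt,
                    intensity = 1, mz_lo = mz, mz_hi = mz,
                    rt_lo = rt, rt_hi = rt, stringsAsFactors = FALSE)
    class(f) <- c("feature_table", "data.frame")
    f
  }
  exact <- match_chemicals_to_features(ch, mkfeat(500, 200))
  expect_equal(exact$feature_id, "F1")

  two <- mkfeat(c(500 * (1 + 2e-6), 500 * (1 - 4e-6)), c(205, 195))
  got <- match_chemicals_to_features(ch, two)
  expect_equal(got$feature_id, "F1")  # +2 ppm beats -4 ppm

  far <- mkfeat(500 * (1 + 6e-6), 200)
  expect_equal(nrow(match_chemicals_to_features(ch, far)), 0)
})

test_that("an isolated chemical is recovered perfectly by EIC deconvolution", {
  one <- make_chems(mz = 350, rt = 200, apex = 1e6)
  run <- run_acquisition(one, controller_swath())
  dec <- deconvolve_dia(run, ground_truth_features(one))
  expect_equal(dec$X1$provenance, "deconvolved-dia")
  expect_gt(dec$X1$quality, 0.9)
  m <- cosine_similarity(dec$X1$peaks, one$ms2_peaks[[1]])
  expect_true(m$matched)
  expect_gte(m$cosine, 0.999)
})

test_that("separated chemicals deconvolve apart; perfect co-elution merges", {
  # same SWATH window (both in [270,370)), apexes 30 s apart at sigma 5 s
  apart <- make_chems(mz = c(300, 350), rt = c(150, 180),
                      apex = c(1e6, 2e6))
  run <- run_acquisition(apart, controller_swath())
  dec <- deconvolve_dia(run, ground_truth_features(apart))
  for (i in 1:2) {
    own <- apart$ms2_peaks[[i]][, "mz"]
    other <- apart$ms2_peaks[[3 - i]][, "mz"]
    got <- dec[[apart$id[i]]]$peaks[, "mz"]
    expect_true(all(vapply(got, function(m)
      any(abs(own - m) < 0.02), logical(1L))))  # only own fragments
    expect_false(any(vapply(got, function(m)
      any(abs(other - m) < 0.005), logical(1L))))  # zero cross-contamination
  }

  # perfectly co-eluting pair: correlation cannot separate them
  merged <- make_chems(mz = c(300, 350), rt = c(150, 150),
                       apex = c(1e6, 2e6))
  run2 <- run_acquisition(merged, controller_swath())
  dec2 <- deconvolve_dia(run2, ground_truth_features(merged))
  for (i in 1:2) {
    got <- dec2[[merged$id[i]]]$peaks[, "mz"]
    both <- c(merged$ms2_peaks[[1]][, "mz"], merged$ms2_peaks[[2]][, "mz"])
    expect_true(all(vapply(both, function(m)
      any(abs(got - m) < 0.02), logical(1L))))  # both spectra merged
  }
})

test_that("features with too few covering scans yield empty spectra of quality 0", {
  one <- make_chems(mz = 350, rt = 200, apex = 1e6)
  run <- run_acquisition(one, controller_swath(), rt_range = c(0, 100))
  feat <- ground_truth_features(one)  # apex at 200 s: outside the run
  dec <- deconvolve_dia(run, feat)
  expect_equal(nrow(dec$X1$peaks), 0)
  expect_equal(dec$X1$quality, 0)
})
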