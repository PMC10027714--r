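mk_scan <- function(mz, intensity, rt = 100) {
  msacquisim:::new_scan(1L, 1L, rt, cbind(mz = mz, intensity = intensity))
}

test_that("top-n schedules the most intense unexcluded peaks above threshold", {
  cfg <- controller_topn()
  emptyx <- cbind(mz = numeric(0), expiry = numeric(0))

  s <- mk_scan(numeric(0), numeric(0))
  out <- topn_schedule(s, emptyx, cfg)
  expect_length(out$requests, 1)
  expect_equal(out$requests[[1]]$ms_level, 1L)

  s <- mk_scan(c(200, 300, 400, 500), c(6e3, 9e3, 7e3, 100))
  out <- topn_schedule(s, emptyx, cfg)
  ms2 <- out$requests[seq_len(length(out$requests) - 1L)]
  expect_length(ms2, 3)  # the 100-count peak is below min_intensity
  expect_equal(vapply(ms2, `[[`, numeric(1L), "precursor_mz"),
               c(300, 400, 200))  # descending intensity
  expect_equal(out$requests[[4]]$ms_level, 1L)
  # isolation windows are centred with the configured width
  expect_equal(ms2[[1]]$isolation_window, c(300 - 0.35, 300 + 0.35))

  # brute-force oracle over random survey scans
  set.seed(42)
  for (i in 1:200) {
    k <- sample(0:30, 1)
    mz <- runif(k, 70, 1000); int <- 10^runif(k, 2, 7)
    s <- mk_scan(mz, int)
    got <- topn_schedule(s, emptyx, cfg)$requests
    got_mz <- vapply(got[-length(got)], `[[`, numeric(1L), "precursor_mz")
    keep <- int >= cfg$min_intensity
    o <- order(-int[keep], mz[keep])
    want <- mz[keep][o][seq_len(min(cfg$N, sum(keep)))]
    expect_equal(got_mz, want)
  }
})

test_that("dynamic exclusion blocks re-selection until the window expires", {
  cfg <- controller_topn(dew = 15)
  emptyx <- cbind(mz = numeric(0), expiry = numeric(0))
  s100 <- mk_scan(250, 1e5, rt = 100)
  out <- topn_schedule(s100, emptyx, cfg)
  expect_equal(out$requests[[1]]$precursor_mz, 250)
  excl <- out$exclusion
  expect_equal(unname(excl[, "expiry"]), 115)

  s110 <- mk_scan(250, 1e5, rt = 110)
  out110 <- topn_schedule(s110, excl, cfg)
  expect_length(out110$requests, 1)  # still excluded: MS1 only

  s116 <- mk_scan(250, 1e5, rt = 116)
  out116 <- topn_schedule(s116, excl, cfg)
  expect_equal(out116$requests[[1]]$precursor_mz, 250)  # eligible again
})

test_that("swath windows tile the scan range exactly", {
  win <- swath_windows(controller_swath())
  expect_equal(nrow(win), 10)
  expect_equal(win[, "lo"], seq(70, 970, by = 100))
  expect_equal(win[, "hi"], seq(170, 1070, by = 100))

  expect_equal(nrow(swath_windows(controller_swath(window_width = 25))), 38)
  expect_equal(nrow(swath_windows(controller_swath(window_width = 2000))), 1)
  expect_error(controller_swath(window_width = 10, overlap = 10), "overlap")

  # partition property: every m/z in range falls in exactly one window
  set.seed(1)
  mz <- runif(500, 70, 999.999)
  hits <- vapply(mz, function(m) sum(m >= win[, "lo"] & m < win[, "hi"]),
                 numeric(1L))
  expect_true(all(hits == 1))
})

test_that("aif alternates a survey scan with one full-range fragmentation scan", {
  cyc <- msacquisim:::dia_cycle(controller_aif())
  expect_length(cyc, 2)
  expect_equal(cyc[[1]]$ms_level, 1L)
  expect_equal(cyc[[2]]$ms_level, 2L)
  expect_equal(cyc[[2]]$isolation_window, c(70, 1000))

  run <- run_acquisition(make_chems(300, 200, 1e6), controller_aif())
  expect_lte(abs(sum(run$ms_level == 1L) - sum(run$ms_level == 2L)), 1)

  empty_run <- run_acquisition(make_chems(numeric(0), numeric(0), numeric(0)),
                               controller_aif())
  ms2 <- which(empty_run$ms_level == 2L)
  expect_true(all(vapply(ms2, function(i)
    nrow(empty_run$scans[[i]]$peaks), integer(1L)) == 0))
})

test_that("DIA schedules are independent of the sample content", {
  a <- run_acquisition(sample_chemicals(20, seed = 1), controller_swath())
  b <- run_acquisition(sample_chemicals(20, seed = 99), controller_swath())
  expect_equal(a$rt, b$rt)
  expect_equal(a$ms_level, b$ms_level)
  wa <- lapply(a$scans, `[[`, "isolation_window")
  wb <- lapply(b$scans, `[[`, "isolation_window")
  expect_equal(wa, wb)
})

test_that("top-n cycles never exceed N MS2 scans nor target sub-threshold peaks", {
  chems <- sample_chemicals(200, seed = 13)
  run <- run_acquisition(chems, controller_topn())
  lvl <- run$ms_level
  # count MS2 scans between consecutive MS1 scans
  cyc <- rle(lvl)
  expect_true(all(cyc$lengths[cyc$values == 2L] <= 10))
  ms2 <- which(lvl == 2L)
  pint <- vapply(ms2, function(i) run$scans[[i]]$precursor_intensity,
                 numeric(1L))
  expect_true(all(pint >= 5000))
})
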