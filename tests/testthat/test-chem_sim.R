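test_that("generated chemicals respect every stated range", {
  chems <- sample_chemicals(10000, seed = 7)
  expect_equal(nrow(chems), 10000)
  expect_true(all(chems$monoisotopic_mass >= 100 &
                  chems$monoisotopic_mass <= 1000))
  expect_true(all(chems$rt_apex >= 0 & chems$rt_apex <= 400))
  expect_true(all(chems$apex_intensity >= 1e4 & chems$apex_intensity <= 1e7))
  expect_equal(chems$mz, chems$monoisotopic_mass + 1.00728)
  for (i in seq_len(nrow(chems))) {
    p <- chems$ms2_peaks[[i]]
    if (nrow(p) == 0L) next
    expect_true(all(p[, "mz"] >= 70 & p[, "mz"] <= chems$monoisotopic_mass[i]))
    prop <- p[, "intensity"] / chems$apex_intensity[i]
    expect_true(all(prop >= 0.1 & prop <= 0.8))
  }
  # fragment counts are Poisson with mean 10: moment check within 3 SE
  k <- vapply(chems$ms2_peaks, nrow, integer(1L))
  expect_lt(abs(mean(k) - 10), 3 * sqrt(10 / length(k)))
  # retention times are uniform on [0, 400]
  ks <- suppressWarnings(ks.test(chems$rt_apex, "punif", 0, 400))
  expect_gt(ks$p.value, 0.001)
})

test_that("generation is deterministic and degenerate inputs are rejected", {
  a <- sample_chemicals(50, seed = 3)
  b <- sample_chemicals(50, seed = 3)
  expect_identical(a, b)
  expect_equal(nrow(sample_chemicals(0, seed = 1)), 0)
  expect_error(sample_chemicals(-1, seed = 1), "count")
  expect_error(sample_chemicals(5, mass_table = c(10, 50), seed = 1),
               "empty")
})

test_that("sample sets share m/z and RT across samples but groups differ in intensity", {
  ss <- build_sample_set(10, seed = 11)
  expect_length(ss$samples, 10)
  expect_equal(ss$group, rep(c("case", "control"), each = 5))
  ref <- ss$samples[[1]]
  for (s in ss$samples) {
    expect_identical(s$mz, ref$mz)
    expect_identical(s$rt_apex, ref$rt_apex)
  }
  expect_false(any(ss$samples[[6]]$apex_intensity ==
                   ss$samples[[1]]$apex_intensity))
  # intensity ratios equal the per-chemical fold change, bounded by the range
  fold <- ss$samples[[6]]$apex_intensity / ss$samples[[1]]$apex_intensity
  expect_true(all(fold >= 0.2 & fold <= 5))

  empty <- build_sample_set(0, seed = 1)
  expect_true(all(vapply(empty$samples, nrow, integer(1L)) == 0))

  # seed independence: different seeds give different chemicals (masses may
  # rarely coincide when drawn from the same finite table; RTs are continuous)
  a <- build_sample_set(100, seed = 21)
  b <- build_sample_set(100, seed = 22)
  expect_length(intersect(a$samples[[1]]$rt_apex, b$samples[[1]]$rt_apex), 0)
  expect_lt(length(intersect(a$samples[[1]]$mz, b$samples[[1]]$mz)), 10)
})

test_that("chromatogram follows the Gaussian closed form with a detection floor", {
  ch <- make_chems(mz = 300, rt = 200, apex = 1e6)
  expect_equal(chromatogram_intensity(ch, 200), 1e6)
  expect_equal(chromatogram_intensity(ch, 205), 1e6 * exp(-0.5))
  expect_equal(chromatogram_intensity(ch, 250), 0)  # 10 sigma: below floor
  # oracle: direct formula at random offsets with no floor
  off <- seq(-12, 12, by = 1.7)
  got <- vapply(off, function(d) chromatogram_intensity(ch, 200 + d, floor = 0),
                numeric(1L))
  expect_equal(got, 1e6 * exp(-off^2 / (2 * 25)))
})

test_that("ground-truth JSON round-trips a sample set", {
  ss <- build_sample_set(5, seed = 9)
  path <- tempfile(fileext = ".json")
  write_ground_truth(ss, path)
  back <- read_ground_truth(path)
  expect_length(back$samples, 10)
  expect_equal(back$samples[[1]]$mz, ss$samples[[1]]$mz)
  expect_equal(back$samples[[6]]$apex_intensity,
               ss$samples[[6]]$apex_intensity)
  expect_equal(back$samples[[3]]$ms2_peaks[[2]],
               ss$samples[[3]]$ms2_peaks[[2]])
})

test_that("mass tables are read from one- and two-column TSVs", {
  p1 <- tempfile(); writeLines(c("monoisotopic_mass", "150.5", "900.1"), p1)
  expect_equal(read_mass_table(p1), c(150.5, 900.1))
  p2 <- tempfile(); writeLines(c("C6H12O6\t180.06339", "C5H5N5\t135.05450"), p2)
  expect_equal(read_mass_table(p2), c(180.06339, 135.05450))
  expect_gte(length(default_mass_table()), 5000)
})
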