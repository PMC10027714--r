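# Hand-built chemical sets for precise acquisition scenarios. Fragment lists
# default to four distinct peaks per chemical so cosine matching has enough
# shared bins.

make_chems <- function(mz, rt, apex, sigma = 5, frags = NULL) {
  n <- length(mz)
  if (is.null(frags))
    frags <- lapply(seq_len(n), function(i) {
      fmz <- c(80, 120, 160, 200) + 3 * i
      cbind(mz = fmz, intensity = c(0.2, 0.5, 0.3, 0.7) * apex[i])
    })
  out <- data.frame(id = paste0("X", seq_len(n), recycle0 = TRUE),
                    monoisotopic_mass = mz - 1.00728,
                    mz = mz, rt_apex = rt, apex_intensity = apex,
                    chrom_sigma = rep(sigma, n), stringsAsFactors = FALSE)
  out$ms2_peaks <- frags
  class(out) <- c("chemical_set", "data.frame")
  out
}

# Random centroid spectrum over an m/z range.
random_spectrum <- function(k, mz_range = c(70, 500)) {
  mz <- sort(runif(k, mz_range[1], mz_range[2]))
  cbind(mz = mz, intensity = runif(k, 1e3, 1e6))
}

# Independent brute-force binned cosine: builds dense vectors over the union
# bin grid with tapply, unlike the implementation's sparse intersect/match.
brute_force_cosine <- function(a, b, bin_width = 0.05, min_match = 3) {
  if (nrow(a) == 0 || nrow(b) == 0) return(NA_real_)
  ba <- floor(a[, "mz"] / bin_width)
  bb <- floor(b[, "mz"] / bin_width)
  grid <- sort(unique(c(ba, bb)))
  va <- vb <- numeric(length(grid))
  for (i in seq_along(ba)) {
    j <- which(grid == ba[i]); va[j] <- va[j] + a[i, "intensity"]
  }
  for (i in seq_along(bb)) {
    j <- which(grid == bb[i]); vb[j] <- vb[j] + b[i, "intensity"]
  }
  if (sum(va > 0 & vb > 0) < min_match) return(NA_real_)
  sum(va * vb) / sqrt(sum(va^2) * sum(vb^2))
}

# Per-chemical best cosine against own truth for one acquired+linked sample.
score_sample <- function(chems, controller, deconv = FALSE, ...) {
  run <- run_acquisition(chems, controller, ...)
  spectra <- if (deconv)
    deconvolve_dia(run, ground_truth_features(chems))
  else link_dda_ground_truth(run, chems)
  score_against_truth(spectra, chems)
}
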