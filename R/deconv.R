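# Attaching a fragmentation spectrum to each feature or chemical:
#  - DDA on simulated data: direct ground-truth link lookup.
#  - DDA on external mzML: isolation-window / RT-overlap assignment.
#  - DIA: elution-profile (EIC) correlation deconvolution in the spirit of
#    MS2Dec -- fragments whose extracted ion chromatogram tracks the
#    precursor's chromatogram inside the feature's RT bounds are retained.

deconvoluted_spectrum <- function(feature_id, peaks, provenance,
                                  quality = NA_real_, scan_id = NA_integer_) {
  structure(list(feature_id = feature_id, peaks = peaks,
                 provenance = provenance, quality = quality,
                 scan_id = scan_id),
            class = "deconvoluted_spectrum")
}

#' Default deconvolution parameters
#'
#' @param min_corr Minimum Pearson correlation between a fragment EIC and the
#'   precursor EIC for the fragment to be retained (default 0.8).
#' @param min_scans Minimum number of covering MS2 scans for deconvolution
#'   (default 3); features with fewer get an empty spectrum with quality 0.
#' @param eic_bin Fragment m/z bin width in Da used to build EICs
#'   (default 0.01).
#' @return Named list of parameters.
#' @export
deconv_params <- function(min_corr = 0.8, min_scans = 3L, eic_bin = 0.01) {
  list(min_corr = min_corr, min_scans = as.integer(min_scans),
       eic_bin = eic_bin)
}

#' Ground-truth feature table for a simulated sample
#'
#' Converts a `chemical_set` into the feature representation used by the
#' deconvolution and matching functions, emulating perfect peak picking: one
#' feature per chemical at its precursor m/z and RT apex, with an RT bounding
#' box of +/- `sigma_mult` chromatographic standard deviations and an m/z box
#' of +/- `mz_ppm` ppm.
#'
#' @param chemicals A `chemical_set`.
#' @param sigma_mult Half-width of the RT bounding box in units of the
#'   chromatographic sigma (default 3).
#' @param mz_ppm Half-width of the m/z bounding box in ppm (default 10).
#' @return A `feature_table` data frame with columns `feature_id`, `mz`,
#'   `rt`, `intensity`, `mz_lo`, `mz_hi`, `rt_lo`, `rt_hi`.
#' @export
ground_truth_features <- function(chemicals, sigma_mult = 3, mz_ppm = 10) {
  tab <- data.frame(feature_id = chemicals$id,
                    mz = chemicals$mz,
                    rt = chemicals$rt_apex,
                    intensity = chemicals$apex_intensity,
                    mz_lo = chemicals$mz * (1 - mz_ppm * 1e-6),
                    mz_hi = chemicals$mz * (1 + mz_ppm * 1e-6),
                    rt_lo = chemicals$rt_apex -
                      sigma_mult * chemicals$chrom_sigma,
                    rt_hi = chemicals$rt_apex +
                      sigma_mult * chemicals$chrom_sigma,
                    stringsAsFactors = FALSE)
  class(tab) <- c("feature_table", "data.frame")
  tab
}

#' Link DDA MS2 scans to chemicals from the simulation state
#'
#' For each chemical that was targeted by at least one MS2 scan (its
#' precursor m/z inside the scan's isolation window while eluting), returns
#' the spectrum of the scan acquired at the chemical's highest
#' chromatographic intensity. Chemicals never fragmented are absent from the
#' result.
#'
#' @param run An `acquisition_run` from a DDA controller (must carry
#'   ground-truth links).
#' @param chemicals The `chemical_set` the run was produced from.
#' @return Named list (by chemical id) of `deconvoluted_spectrum` objects
#'   with provenance `"direct-dda"`.
#' @export
link_dda_ground_truth <- function(run, chemicals) {
  if (is.null(run$ground_truth_links))
    stop("acquisition run carries no ground-truth links sidecar")
  ms2 <- which(run$ms_level == 2L)
  chem_scans <- vector("list", nrow(chemicals))
  for (i in ms2) {
    for (ci in run$ground_truth_links[[i]])
      chem_scans[[ci]] <- c(chem_scans[[ci]], i)
  }
  out <- list()
  for (ci in seq_len(nrow(chemicals))) {
    sc <- chem_scans[[ci]]
    if (is.null(sc)) next
    elut <- vapply(run$rt[sc], function(t)
      chromatogram_intensity(chemicals[ci, , drop = FALSE], t, floor = 0),
      numeric(1L))
    best <- sc[which.max(elut)]
    out[[chemicals$id[ci]]] <-
      deconvoluted_spectrum(chemicals$id[ci], run$scans[[best]]$peaks,
                            "direct-dda", scan_id = best)
  }
  out
}

#' Assign DDA MS2 scans to features by isolation window and RT overlap
#'
#' An MS2 scan is assigned to a feature when its isolation window intersects
#' the feature's m/z bounds and its RT lies inside the feature's RT bounds.
#' When several scans qualify, the scan fragmented at the highest precursor
#' intensity is chosen.
#'
#' @param ms2_scans List of MS2 `ms_scan` objects (e.g. from [read_mzml()]).
#' @param features A `feature_table`.
#' @return Named list (by feature id) of `deconvoluted_spectrum` objects
#'   with provenance `"assigned-dda"`.
#' @export
assign_dda_scans_to_features <- function(ms2_scans, features) {
  ms2_scans <- Filter(function(s) s$ms_level == 2L, ms2_scans)
  if (length(ms2_scans) == 0L) return(list())
  rt <- vapply(ms2_scans, `[[`, numeric(1L), "rt")
  win <- t(vapply(ms2_scans, function(s) s$isolation_window, numeric(2L)))
  pint <- vapply(ms2_scans, function(s)
    if (is.null(s$precursor_intensity)) 0 else s$precursor_intensity,
    numeric(1L))
  out <- list()
  for (f in seq_len(nrow(features))) {
    hit <- which(win[, 1L] <= features$mz_hi[f] &
                 win[, 2L] >= features$mz_lo[f] &
                 rt >= features$rt_lo[f] & rt <= features$rt_hi[f])
    if (length(hit) == 0L) next
    best <- hit[which.max(pint[hit])]
    out[[features$feature_id[f]]] <-
      deconvoluted_spectrum(features$feature_id[f],
                            ms2_scans[[best]]$peaks, "assigned-dda",
                            scan_id = ms2_scans[[best]]$scan_id)
  }
  out
}

#' Match simulated chemicals to detected features
#'
#' Pairs chemicals and features within an m/z tolerance (ppm) and an RT
#' tolerance (seconds); when several features qualify for a chemical, the
#' feature closest in m/z is chosen.
#'
#' @param chemicals A `chemical_set`.
#' @param features A `feature_table`.
#' @param mz_ppm m/z tolerance in ppm (default 5).
#' @param rt_tol RT tolerance in seconds (default 10).
#' @return Data frame with columns `chem_id`, `feature_id`.
#' @export
match_chemicals_to_features <- function(chemicals, features, mz_ppm = 5,
                                        rt_tol = 10) {
  stopifnot(mz_ppm > 0, rt_tol > 0)
  chem_id <- character(0); feature_id <- character(0)
  for (i in seq_len(nrow(chemicals))) {
    dmz <- abs(features$mz - chemicals$mz[i])
    ok <- dmz <= chemicals$mz[i] * mz_ppm * 1e-6 &
      abs(features$rt - chemicals$rt_apex[i]) <= rt_tol
    if (!any(ok)) next
    j <- which(ok)[which.min(dmz[ok])]
    chem_id <- c(chem_id, chemicals$id[i])
    feature_id <- c(feature_id, features$feature_id[j])
  }
  data.frame(chem_id = chem_id, feature_id = feature_id,
             stringsAsFactors = FALSE)
}

# Build per-isolation-window sparse EIC matrices (bins x scans) for a run.
dia_index <- function(run, eic_bin) {
  ms1 <- which(run$ms_level == 1L)
  ms2 <- which(run$ms_level == 2L)
  wkey <- vapply(ms2, function(i) {
    w <- run$scans[[i]]$isolation_window
    paste0(w[1L], "_", w[2L])
  }, character(1L))
  groups <- split(ms2, wkey)
  make_group <- function(scan_ids) {
    bins <- list(); ints <- list(); cols <- list(); mzs <- list()
    for (k in seq_along(scan_ids)) {
      p <- run$scans[[scan_ids[k]]]$peaks
      if (nrow(p) == 0L) next
      # nearest-bin-centre assignment: robust to centroid m/z jitter at edges
      b <- as.integer(round(p[, "mz"] / eic_bin))
      bins[[k]] <- b; ints[[k]] <- p[, "intensity"]
      mzs[[k]] <- p[, "mz"]
      cols[[k]] <- rep.int(k, nrow(p))
    }
    b <- as.integer(unlist(bins)); v <- as.numeric(unlist(ints))
    cl <- as.integer(unlist(cols)); mzv <- as.numeric(unlist(mzs))
    ub <- sort(unique(b))
    ri <- match(b, ub)
    m <- Matrix::sparseMatrix(i = ri, j = cl, x = v,
                              dims = c(length(ub), length(scan_ids)))
    # representative m/z per bin: that of the most intense contribution
    if (length(ub)) {
      o2 <- order(ri, -v)
      bin_mz <- mzv[o2][!duplicated(ri[o2])]
    } else bin_mz <- numeric(0)
    list(scan_ids = scan_ids, rts = run$rt[scan_ids],
         bins = ub, mat = m, bin_mz = bin_mz)
  }
  win_lo <- vapply(groups, function(g)
    run$scans[[g[1L]]]$isolation_window[1L], numeric(1L))
  win_hi <- vapply(groups, function(g)
    run$scans[[g[1L]]]$isolation_window[2L], numeric(1L))
  list(ms1_ids = ms1, ms1_rts = run$rt[ms1],
       groups = lapply(groups, make_group),
       win_lo = win_lo, win_hi = win_hi)
}

# Precursor EIC of one feature over the MS1 scans inside its RT bounds.
precursor_eic <- function(run, idx, feature, eic_bin) {
  sel <- idx$ms1_ids[idx$ms1_rts >= feature$rt_lo &
                     idx$ms1_rts <= feature$rt_hi]
  rts <- run$rt[sel]
  v <- vapply(sel, function(i) {
    p <- run$scans[[i]]$peaks
    if (nrow(p) == 0L) return(0)
    hit <- p[, "mz"] >= feature$mz_lo & p[, "mz"] <= feature$mz_hi
    sum(p[hit, "intensity"])
  }, numeric(1L))
  list(rts = rts, intensity = v)
}

#' EIC-correlation deconvolution of DIA data
#'
#' For each feature: MS2 scans whose isolation window contains the feature
#' m/z and whose RT lies inside the feature's RT bounds are gathered;
#' per-fragment-m/z extracted ion chromatograms (binned at `eic_bin`) are
#' built across those scans; fragments whose EIC has a Pearson correlation of
#' at least `min_corr` with the feature's precursor EIC (from the interleaved
#' MS1 scans, interpolated to the MS2 scan times) are retained. The fragment
#' intensity is the EIC value at the covering scan closest to the feature
#' apex, and the spectrum quality is the mean correlation of the retained
#' fragments. Features with fewer than `min_scans` covering MS2 scans (or no
#' usable precursor trace) receive an empty spectrum with quality 0.
#'
#' @param run An `acquisition_run` from a DIA controller (SWATH or AIF).
#' @param features A `feature_table` (ground truth in simulation, or an
#'   external table from [read_feature_table()]).
#' @param params A [deconv_params()] list.
#' @return Named list (by feature id) of `deconvoluted_spectrum` objects
#'   with provenance `"deconvolved-dia"` and a `quality` score in [0, 1].
#' @export
deconvolve_dia <- function(run, features, params = deconv_params()) {
  idx <- dia_index(run, params$eic_bin)
  empty <- function(fid) deconvoluted_spectrum(
    fid, cbind(mz = numeric(0), intensity = numeric(0)),
    "deconvolved-dia", quality = 0)
  out <- vector("list", nrow(features))
  names(out) <- features$feature_id
  for (f in seq_len(nrow(features))) {
    fid <- features$feature_id[f]
    gsel <- which(idx$win_lo <= features$mz[f] & features$mz[f] < idx$win_hi)
    if (length(gsel) == 0L) { out[[f]] <- empty(fid); next }
    # covering scans across all matching window groups
    cov_rts <- numeric(0); cov_cols <- list(); cov_grp <- integer(0)
    for (g in gsel) {
      grp <- idx$groups[[g]]
      keep <- which(grp$rts >= features$rt_lo[f] & grp$rts <= features$rt_hi[f])
      cov_cols[[length(cov_cols) + 1L]] <- keep
      cov_rts <- c(cov_rts, grp$rts[keep])
      cov_grp <- c(cov_grp, rep.int(g, length(keep)))
    }
    if (length(cov_rts) < params$min_scans) { out[[f]] <- empty(fid); next }
    pe <- precursor_eic(run, idx, features[f, ], params$eic_bin)
    if (length(pe$rts) < 2L || all(pe$intensity == 0)) {
      out[[f]] <- empty(fid); next
    }
    p_interp <- stats::approx(pe$rts, pe$intensity, xout = cov_rts,
                              yleft = 0, yright = 0)$y
    if (stats::sd(p_interp) == 0) { out[[f]] <- empty(fid); next }
    # assemble the fragment EIC matrix over the covering scans
    mats <- list(); mz_rep <- list()
    for (k in seq_along(gsel)) {
      grp <- idx$groups[[gsel[k]]]
      keep <- cov_cols[[k]]
      if (length(keep) == 0L) next
      sub <- as.matrix(grp$mat[, keep, drop = FALSE])
      mats[[k]] <- sub
      mz_rep[[k]] <- grp$bin_mz
    }
    if (length(gsel) == 1L) {
      X <- mats[[1L]]
      mzs <- mz_rep[[1L]]
    } else {
      # align bins across groups on the union of bin ids
      allbins <- sort(unique(unlist(lapply(idx$groups[gsel], `[[`, "bins"))))
      X <- matrix(0, length(allbins), length(cov_rts))
      mzs <- rep(NA_real_, length(allbins))
      col0 <- 0L
      for (k in seq_along(gsel)) {
        grp <- idx$groups[[gsel[k]]]
        nc <- length(cov_cols[[k]])
        if (nc == 0L) next
        ri <- match(grp$bins, allbins)
        X[ri, col0 + seq_len(nc)] <- mats[[k]]
        mzs[ri] <- grp$bin_mz
        col0 <- col0 + nc
      }
    }
    o <- order(cov_rts)
    X <- X[, o, drop = FALSE]
    p_interp <- p_interp[o]
    cov_rts_o <- cov_rts[o]
    nz <- which(rowSums(X) > 0)
    if (length(nz) == 0L) { out[[f]] <- empty(fid); next }
    X <- X[nz, , drop = FALSE]
    mzs <- mzs[nz]
    rs <- rowSums(X); n_sc <- ncol(X)
    rmean <- rs / n_sc
    rsd <- sqrt(pmax(0, rowSums(X^2) / n_sc - rmean^2))
    pc <- p_interp - mean(p_interp)
    psd <- sqrt(sum(pc^2) / n_sc)
    covar <- as.numeric(X %*% pc) / n_sc
    corr <- covar / (rsd * psd)
    corr[!is.finite(corr)] <- 0
    apex_col <- which.min(abs(cov_rts_o - features$rt[f]))
    keep <- corr >= params$min_corr & X[, apex_col] > 0
    if (!any(keep)) { out[[f]] <- empty(fid); next }
    peaks <- cbind(mz = mzs[keep], intensity = X[keep, apex_col])
    o2 <- order(peaks[, "mz"])
    out[[f]] <- deconvoluted_spectrum(fid, peaks[o2, , drop = FALSE],
                                      "deconvolved-dia",
                                      quality = mean(corr[keep]))
  }
  out
}
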