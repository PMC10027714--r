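# The simulated-environment event loop: a clock advances by scan durations,
# scans are generated from whichever chemicals elute at the current retention
# time, and completed scans are dispatched back to the controller, which
# schedules the next requests.

#' Scan timing configuration
#'
#' @param ms1,ms2 Scan durations in seconds. Defaults (0.4 s MS1, 0.2 s MS2)
#'   are consistent with Orbitrap resolutions of 120,000 and 7,500.
#' @return Named numeric vector of durations.
#' @export
timing_config <- function(ms1 = 0.4, ms2 = 0.2) {
  stopifnot(ms1 > 0, ms2 > 0)
  c(ms1 = ms1, ms2 = ms2)
}

# Sum centroid peaks closer than `tol` Da; the representative m/z is that of
# the most intense merged peak (keeps m/z values exact for isolated peaks).
merge_centroid_peaks <- function(mz, intensity, tol = 0.001) {
  if (length(mz) == 0L)
    return(cbind(mz = numeric(0), intensity = numeric(0)))
  o <- order(mz)
  mz <- mz[o]; intensity <- intensity[o]
  grp <- cumsum(c(TRUE, diff(mz) > tol))
  ints <- rowsum(intensity, grp)[, 1L]
  o2 <- order(grp, -intensity)
  mzs <- mz[o2][!duplicated(grp[o2])]
  cbind(mz = mzs, intensity = ints)
}

# Index of chemicals for fast elution lookups.
elution_index <- function(chemicals, floor) {
  above <- chemicals$apex_intensity >= floor
  delta <- rep(0, nrow(chemicals))
  delta[above] <- chemicals$chrom_sigma[above] *
    sqrt(2 * log(chemicals$apex_intensity[above] / floor))
  ord <- order(chemicals$rt_apex)
  list(ord = ord, rts = chemicals$rt_apex[ord],
       max_delta = if (length(delta)) max(delta) else 0)
}

# Indices of chemicals eluting at `rt` (chromatographic intensity >= floor),
# together with those intensities.
eluting_at <- function(chemicals, idx, rt, floor) {
  lo <- findInterval(rt - idx$max_delta, idx$rts) + 1L
  hi <- findInterval(rt + idx$max_delta, idx$rts)
  if (hi < lo) return(list(idx = integer(0), intensity = numeric(0)))
  cand <- idx$ord[lo:hi]
  v <- chromatogram_intensity(chemicals[cand, , drop = FALSE], rt, floor)
  keep <- v > 0
  list(idx = cand[keep], intensity = v[keep])
}

new_scan <- function(scan_id, ms_level, rt, peaks, isolation_window = NULL,
                     precursor_mz = NULL, precursor_intensity = NULL,
                     duration = NA_real_) {
  structure(list(scan_id = scan_id, ms_level = ms_level, rt = rt,
                 peaks = peaks, isolation_window = isolation_window,
                 precursor_mz = precursor_mz,
                 precursor_intensity = precursor_intensity,
                 duration = duration),
            class = "ms_scan")
}

#' Generate a single MS1 scan
#'
#' One centroid peak per chemical eluting above the detection floor at `rt`,
#' at its precursor m/z with its current chromatographic intensity; peaks
#' closer than `merge_tol` are summed.
#'
#' @param chemicals A `chemical_set`.
#' @param rt Retention time in seconds.
#' @param floor Detection floor in counts.
#' @param merge_tol Centroid merge tolerance in Da.
#' @return An `ms_scan` with peaks sorted by m/z.
#' @export
generate_ms1_scan <- function(chemicals, rt, floor = 100, merge_tol = 0.001) {
  idx <- elution_index(chemicals, floor)
  el <- eluting_at(chemicals, idx, rt, floor)
  peaks <- merge_centroid_peaks(chemicals$mz[el$idx], el$intensity, merge_tol)
  new_scan(NA_integer_, 1L, rt, peaks)
}

# Core MS2 generation, returning the contributing chemical indices too.
ms2_peaks_at <- function(chemicals, idx, rt, isolation_window, floor,
                         merge_tol) {
  el <- eluting_at(chemicals, idx, rt, floor)
  mzv <- chemicals$mz[el$idx]
  inwin <- mzv >= isolation_window[1L] & mzv < isolation_window[2L]
  sel <- el$idx[inwin]
  scale <- el$intensity[inwin] / chemicals$apex_intensity[sel]
  if (length(sel)) {
    frag <- chemicals$ms2_peaks[sel]
    mz <- unlist(lapply(frag, function(p) p[, "mz"]), use.names = FALSE)
    int <- unlist(lapply(seq_along(frag), function(i)
      frag[[i]][, "intensity"] * scale[i]), use.names = FALSE)
    peaks <- merge_centroid_peaks(mz, int, merge_tol)
  } else {
    peaks <- cbind(mz = numeric(0), intensity = numeric(0))
  }
  list(peaks = peaks, chem_idx = sel)
}

#' Generate a single MS2 scan
#'
#' The union of the fragment peaks of every chemical whose precursor m/z lies
#' inside the half-open isolation window `[lo, hi)` and which elutes above
#' the detection floor at `rt`. Each fragment intensity is the stored
#' fragment intensity scaled by the chemical's current chromatographic
#' intensity relative to its apex; peaks within `merge_tol` are summed.
#'
#' @inheritParams generate_ms1_scan
#' @param isolation_window Numeric `c(lo, hi)` in Da.
#' @return An `ms_scan`.
#' @export
generate_ms2_scan <- function(chemicals, rt, isolation_window, floor = 100,
                              merge_tol = 0.001) {
  idx <- elution_index(chemicals, floor)
  g <- ms2_peaks_at(chemicals, idx, rt, isolation_window, floor, merge_tol)
  new_scan(NA_integer_, 2L, rt, g$peaks, isolation_window = isolation_window)
}

#' Run a simulated acquisition
#'
#' Drives the virtual instrument: starting at `rt_range[1]`, scan requests
#' from the controller are executed in order, each scan is generated from the
#' chemicals eluting at the current clock time, the clock advances by the
#' scan's duration, and completed scans are handed back to the controller to
#' schedule the next requests. The run terminates once the clock passes
#' `rt_range[2]`. Every MS2 scan records the ground-truth set of chemicals
#' that contributed to it (precursor inside the isolation window and eluting
#' above the detection floor).
#'
#' @param chemicals A `chemical_set` (one simulated sample).
#' @param controller A controller object, e.g. [controller_topn()].
#' @param timing A [timing_config()].
#' @param rt_range Acquisition time range in seconds.
#' @param floor Detection floor in counts.
#' @param merge_tol Centroid merge tolerance in Da.
#' @return An `acquisition_run`: list with `scans` (list of `ms_scan`),
#'   `ground_truth_links` (per-scan integer vectors of chemical row indices,
#'   `NULL` for MS1), `rt` and `ms_level` vectors, and `config`.
#' @export
run_acquisition <- function(chemicals, controller,
                            timing = timing_config(),
                            rt_range = c(0, 400),
                            floor = 100, merge_tol = 0.001) {
  stopifnot(rt_range[1L] < rt_range[2L], all(timing > 0))
  idx <- elution_index(chemicals, floor)
  queue <- initial_requests(controller)
  scans <- vector("list", 4096L)
  links <- vector("list", 4096L)
  n <- 0L
  rt <- rt_range[1L]
  rt_end <- rt_range[2L] - 1e-9  # guard against accumulated clock error
  while (rt < rt_end) {
    if (length(queue) == 0L) {
      queue <- refill_requests(controller)
      if (length(queue) == 0L) break
    }
    req <- queue[[1L]]
    queue <- queue[-1L]
    if (!inherits(req, "scan_request"))
      stop("controller returned a malformed scan request: ",
           paste(utils::capture.output(utils::str(req)), collapse = " "))
    n <- n + 1L
    if (n > length(scans)) {
      length(scans) <- 2L * length(scans)
      length(links) <- length(scans)
    }
    if (req$ms_level == 1L) {
      el <- eluting_at(chemicals, idx, rt, floor)
      peaks <- merge_centroid_peaks(chemicals$mz[el$idx], el$intensity,
                                    merge_tol)
      scan <- new_scan(n, 1L, rt, peaks, duration = timing[["ms1"]])
    } else {
      g <- ms2_peaks_at(chemicals, idx, rt, req$isolation_window, floor,
                        merge_tol)
      scan <- new_scan(n, 2L, rt, g$peaks,
                       isolation_window = req$isolation_window,
                       precursor_mz = req$precursor_mz,
                       precursor_intensity = req$precursor_intensity,
                       duration = timing[["ms2"]])
      links[[n]] <- g$chem_idx
    }
    scans[[n]] <- scan
    rt <- rt + scan$duration
    res <- next_requests(controller, scan)
    controller <- res$controller
    if (length(res$requests)) queue <- c(queue, res$requests)
  }
  scans <- scans[seq_len(n)]
  links <- links[seq_len(n)]
  structure(list(scans = scans,
                 ground_truth_links = links,
                 rt = vapply(scans, `[[`, numeric(1L), "rt"),
                 ms_level = vapply(scans, `[[`, integer(1L), "ms_level"),
                 config = list(controller = class(controller)[1L],
                               controller_params = unclass(controller),
                               timing = timing, rt_range = rt_range,
                               floor = floor, merge_tol = merge_tol)),
            class = "acquisition_run")
}

#' @exportS3Method base::print
print.acquisition_run <- function(x, ...) {
  cat("<acquisition_run>", x$config$controller, "\n",
      sum(x$ms_level == 1L), "MS1 scans,", sum(x$ms_level == 2L),
      "MS2 scans, rt", sprintf("%.1f-%.1f s", min(x$rt), max(x$rt)), "\n")
  invisible(x)
}
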