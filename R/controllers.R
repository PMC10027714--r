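# Acquisition strategies as interchangeable policy objects. A controller is
# asked for its opening requests (`initial_requests`) and then, after every
# completed scan, for follow-up requests (`next_requests`). DDA controllers
# keep declared state (the dynamic exclusion list); DIA controllers are
# stateless cycles whose schedule never depends on the data.

scan_request <- function(ms_level, isolation_window = NULL,
                         precursor_mz = NULL, precursor_intensity = NULL,
                         collision_label = NULL) {
  if (ms_level == 2L && is.null(isolation_window))
    stop("an MS2 scan request requires an isolation window")
  if (!is.null(isolation_window) && isolation_window[1L] >= isolation_window[2L])
    stop("malformed scan request: isolation window lo must be < hi")
  structure(list(ms_level = as.integer(ms_level),
                 isolation_window = unname(isolation_window),
                 precursor_mz = unname(precursor_mz),
                 precursor_intensity = unname(precursor_intensity),
                 collision_label = collision_label),
            class = "scan_request")
}

ms1_request <- function() scan_request(1L)

#' Fullscan (MS1-only) controller
#' @return A controller object for [run_acquisition()].
#' @export
controller_fullscan <- function() {
  structure(list(), class = c("fullscan_controller", "ms_controller"))
}

#' Top-N DDA controller
#'
#' After each MS1 survey scan the `N` most intense peaks that are above
#' `min_intensity` and not on the dynamic exclusion list are fragmented in
#' descending intensity order (ties broken by lower m/z), each isolated in a
#' window of `isolation_width` centred on the precursor; the batch is
#' followed by the next survey scan. Selected precursors are excluded for
#' `dew` seconds; a peak matches an exclusion entry within `exclusion_ppm`.
#'
#' @param N Maximum MS2 scans per cycle (default 10).
#' @param dew Dynamic exclusion window in seconds (default 15).
#' @param min_intensity Minimum precursor intensity in counts (default 5000).
#' @param isolation_width Isolation width in Da (default 0.7).
#' @param exclusion_ppm m/z tolerance for exclusion matching (default 10 ppm).
#' @return A controller object for [run_acquisition()].
#' @export
controller_topn <- function(N = 10L, dew = 15, min_intensity = 5000,
                            isolation_width = 0.7, exclusion_ppm = 10) {
  stopifnot(N >= 1L, dew >= 0, isolation_width > 0)
  structure(list(N = as.integer(N), dew = dew,
                 min_intensity = min_intensity,
                 isolation_width = isolation_width,
                 exclusion_ppm = exclusion_ppm,
                 exclusion = cbind(mz = numeric(0), expiry = numeric(0))),
            class = c("topn_controller", "ms_controller"))
}

#' SWATH DIA controller
#'
#' Cycles one MS1 survey scan followed by a fixed series of MS2 scans whose
#' half-open isolation windows `[lo, hi)` tile the scan range with the given
#' width and overlap. The schedule is independent of the data.
#'
#' @param window_width Isolation window width in Da (default 100).
#' @param overlap Overlap between consecutive windows in Da (default 0).
#' @param scan_range Precursor m/z range covered, default c(70, 1000).
#' @return A controller object for [run_acquisition()].
#' @export
controller_swath <- function(window_width = 100, overlap = 0,
                             scan_range = c(70, 1000)) {
  if (window_width <= overlap)
    stop("SWATH window_width must exceed the overlap")
  stopifnot(overlap >= 0, scan_range[1L] < scan_range[2L])
  structure(list(window_width = window_width, overlap = overlap,
                 scan_range = scan_range),
            class = c("swath_controller", "ms_controller"))
}

#' All-Ion Fragmentation (AIF) controller
#'
#' Alternates one MS1 survey scan with one MS2 scan fragmenting the entire
#' scan range (source CID).
#'
#' @param scan_range Precursor m/z range, default c(70, 1000).
#' @param collision_label Free-text collision annotation.
#' @return A controller object for [run_acquisition()].
#' @export
controller_aif <- function(scan_range = c(70, 1000),
                           collision_label = "source CID 25%") {
  stopifnot(scan_range[1L] < scan_range[2L])
  structure(list(scan_range = scan_range, collision_label = collision_label),
            class = c("aif_controller", "ms_controller"))
}

#' SWATH isolation windows
#'
#' Computes the half-open isolation windows `[lo, hi)` for a SWATH
#' configuration: `ceil((hi - lo) / (width - overlap))` windows whose union
#' covers the scan range exactly, each of the configured width.
#'
#' @param controller A [controller_swath()] object.
#' @return Two-column matrix (`lo`, `hi`) of window bounds in Da.
#' @export
swath_windows <- function(controller) {
  lo <- controller$scan_range[1L]; hi <- controller$scan_range[2L]
  step <- controller$window_width - controller$overlap
  starts <- seq(lo, by = step, length.out = ceiling((hi - lo) / step))
  cbind(lo = starts, hi = starts + controller$window_width)
}

#' Top-N MS2 scheduling for one survey scan
#'
#' Pure scheduling step of the Top-N policy: given the peaks of the last MS1
#' scan and the current exclusion list, returns the MS2 requests (descending
#' intensity, ties to lower m/z) followed by one MS1 request, plus the
#' updated exclusion list.
#'
#' @param scan An MS1 `ms_scan`.
#' @param exclusion Matrix with columns `mz`, `expiry`.
#' @param controller A [controller_topn()] object.
#' @return List with `requests` (list of scan requests) and `exclusion`.
#' @export
topn_schedule <- function(scan, exclusion, controller) {
  peaks <- scan$peaks
  rt <- scan$rt
  exclusion <- exclusion[exclusion[, "expiry"] >= rt, , drop = FALSE]
  requests <- list()
  if (nrow(peaks)) {
    keep <- peaks[, "intensity"] >= controller$min_intensity
    if (nrow(exclusion) && any(keep)) {
      mz <- peaks[keep, "mz"]
      tol <- controller$exclusion_ppm * 1e-6
      excluded <- vapply(mz, function(m)
        any(abs(exclusion[, "mz"] - m) <= m * tol), logical(1L))
      keep[keep] <- !excluded
    }
    if (any(keep)) {
      cand <- peaks[keep, , drop = FALSE]
      o <- order(-cand[, "intensity"], cand[, "mz"])
      cand <- cand[o[seq_len(min(controller$N, nrow(cand)))], , drop = FALSE]
      half <- controller$isolation_width / 2
      requests <- lapply(seq_len(nrow(cand)), function(i)
        scan_request(2L,
                     isolation_window = c(cand[i, "mz"] - half,
                                          cand[i, "mz"] + half),
                     precursor_mz = cand[i, "mz"],
                     precursor_intensity = cand[i, "intensity"],
                     collision_label = "HCD 25%"))
      exclusion <- rbind(exclusion,
                         cbind(mz = cand[, "mz"],
                               expiry = rt + controller$dew))
    }
  }
  requests[[length(requests) + 1L]] <- ms1_request()
  list(requests = requests, exclusion = exclusion)
}

dia_cycle <- function(controller) UseMethod("dia_cycle")

#' @export
dia_cycle.swath_controller <- function(controller) {
  win <- swath_windows(controller)
  reqs <- list(ms1_request())
  for (i in seq_len(nrow(win)))
    reqs[[i + 1L]] <- scan_request(2L, isolation_window = win[i, ],
                                   collision_label = "HCD 25%")
  reqs
}

#' @export
dia_cycle.aif_controller <- function(controller) {
  list(ms1_request(),
       scan_request(2L, isolation_window = controller$scan_range,
                    collision_label = controller$collision_label))
}

# -- controller event interface used by run_acquisition() ---------------------

initial_requests <- function(controller) UseMethod("initial_requests")
#' @export
initial_requests.fullscan_controller <- function(controller) list(ms1_request())
#' @export
initial_requests.topn_controller <- function(controller) list(ms1_request())
#' @export
initial_requests.swath_controller <- function(controller) dia_cycle(controller)
#' @export
initial_requests.aif_controller <- function(controller) dia_cycle(controller)

# Returns list(requests=..., controller=...) after a completed scan.
next_requests <- function(controller, scan) UseMethod("next_requests")

#' @export
next_requests.fullscan_controller <- function(controller, scan) {
  if (scan$ms_level == 1L)
    list(requests = list(ms1_request()), controller = controller)
  else list(requests = list(), controller = controller)
}

#' @export
next_requests.topn_controller <- function(controller, scan) {
  if (scan$ms_level != 1L) return(list(requests = list(), controller = controller))
  sched <- topn_schedule(scan, controller$exclusion, controller)
  controller$exclusion <- sched$exclusion
  list(requests = sched$requests, controller = controller)
}

#' @export
next_requests.swath_controller <- function(controller, scan) {
  list(requests = list(), controller = controller)
}

#' @export
next_requests.aif_controller <- function(controller, scan) {
  list(requests = list(), controller = controller)
}

# DIA controllers refill their queue with a fresh cycle when it empties.
refill_requests <- function(controller) UseMethod("refill_requests")
#' @export
refill_requests.default <- function(controller) list()
#' @export
refill_requests.swath_controller <- function(controller) dia_cycle(controller)
#' @export
refill_requests.aif_controller <- function(controller) dia_cycle(controller)
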