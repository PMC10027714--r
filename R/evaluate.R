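# Spectral matching and benchmarking: binned cosine similarity against the
# true spectral library, annotation-rate tables across chemical counts and
# score thresholds, pairwise-similarity distributions, and annotation-overlap
# set algebra.

bin_spectrum <- function(peaks, bin_width) {
  if (is.null(peaks) || nrow(peaks) == 0L)
    return(list(bins = integer(0), intensity = numeric(0)))
  b <- as.integer(floor(peaks[, "mz"] / bin_width))
  v <- rowsum(peaks[, "intensity"], b)[, 1L]
  list(bins = sort(unique(b)), intensity = v)
}

#' Binned cosine similarity of two spectra
#'
#' Both spectra are binned onto a fixed grid anchored at zero (bin index =
#' `floor(mz / bin_width)`, intensities within a bin summed) and scored with
#' the cosine of the binned intensity vectors. A match requires at least
#' `min_match` bins that are non-empty in both spectra; otherwise (or when
#' either spectrum is empty) a no-match is returned.
#'
#' @param query,reference Two-column peak matrices (`mz`, `intensity`).
#' @param bin_width Bin width in Da (default 0.05).
#' @param min_match Minimum number of shared non-empty bins (default 3).
#' @return A `spectral_match`: list with `cosine` (NA when no-match),
#'   `n_matched_peaks`, and `matched` (logical).
#' @export
cosine_similarity <- function(query, reference, bin_width = 0.05,
                              min_match = 3L) {
  stopifnot(bin_width > 0, min_match >= 1L)
  q <- bin_spectrum(query, bin_width)
  r <- bin_spectrum(reference, bin_width)
  shared <- intersect(q$bins, r$bins)
  if (length(shared) < min_match)
    return(structure(list(cosine = NA_real_,
                          n_matched_peaks = length(shared),
                          matched = FALSE), class = "spectral_match"))
  qi <- q$intensity[match(shared, q$bins)]
  ri <- r$intensity[match(shared, r$bins)]
  score <- sum(qi * ri) /
    (sqrt(sum(q$intensity^2)) * sqrt(sum(r$intensity^2)))
  structure(list(cosine = score, n_matched_peaks = length(shared),
                 matched = TRUE), class = "spectral_match")
}

# Sparse bins x spectra matrix for batch cosine computations.
spectra_bin_matrix <- function(spectra, bin_width) {
  binned <- lapply(spectra, bin_spectrum, bin_width = bin_width)
  allbins <- sort(unique(unlist(lapply(binned, `[[`, "bins"))))
  i <- unlist(lapply(binned, function(b) match(b$bins, allbins)))
  j <- rep.int(seq_along(binned),
               vapply(binned, function(b) length(b$bins), integer(1L)))
  x <- unlist(lapply(binned, `[[`, "intensity"))
  Matrix::sparseMatrix(i = if (is.null(i)) integer(0) else i, j = j, x = x,
                       dims = c(length(allbins), length(spectra)))
}

# All-pairs binned cosine of a list of spectra; no-match pairs score 0.
# Returns the full symmetric matrix.
pairwise_cosine_matrix <- function(spectra, bin_width = 0.05, min_match = 3L) {
  M <- spectra_bin_matrix(spectra, bin_width)
  nrm <- sqrt(Matrix::colSums(M^2))
  nrm[nrm == 0] <- 1
  Mn <- M %*% Matrix::Diagonal(x = 1 / nrm)
  cos <- as.matrix(Matrix::crossprod(Mn))
  shared <- as.matrix(Matrix::crossprod(M > 0))
  cos[shared < min_match] <- 0
  cos
}

#' Pairwise similarity distribution of a spectrum set
#'
#' Computes the binned cosine similarity over all unordered pairs of spectra
#' (no-match pairs, with fewer than `min_match` shared bins, score 0) and
#' summarises the distribution.
#'
#' @param spectra List of at least two peak matrices.
#' @param bin_width Bin width in Da.
#' @param min_match Minimum shared non-empty bins for a valid match.
#' @return List with `median`, `q25`, `q75`, `n_pairs`, and `histogram`
#'   (counts over [0,1] in 0.05 steps).
#' @export
pairwise_similarity_distribution <- function(spectra, bin_width = 0.05,
                                             min_match = 3L) {
  if (length(spectra) < 2L) stop("need at least two spectra")
  cos <- pairwise_cosine_matrix(spectra, bin_width, min_match)
  scores <- cos[upper.tri(cos)]
  qs <- stats::quantile(scores, c(0.25, 0.5, 0.75), names = FALSE)
  h <- graphics::hist(scores, breaks = seq(0, 1, by = 0.05), plot = FALSE)
  list(median = qs[2L], q25 = qs[1L], q75 = qs[3L],
       n_pairs = length(scores), histogram = h$counts)
}

#' Annotation rates across replicates
#'
#' For each similarity threshold, the annotated fraction of a replicate is
#' the number of unique chemicals whose best match to their own true
#' spectrum reaches the threshold, divided by the number of chemicals.
#' Fractions are aggregated as mean with a normal-theory 95% confidence
#' interval across replicates.
#'
#' @param scores_by_replicate List (one element per replicate) of numeric
#'   vectors of per-chemical best cosine scores (NA = never matched).
#' @param thresholds Similarity thresholds, default `c(0.2, 0.4, 0.6, 0.8)`.
#' @param n_chemicals Size of the chemical universe (denominator).
#' @return List with `table` (replicate-level fractions) and `summary`
#'   (mean, `ci_lo`, `ci_hi` per threshold).
#' @export
annotation_rates <- function(scores_by_replicate,
                             thresholds = c(0.2, 0.4, 0.6, 0.8),
                             n_chemicals) {
  stopifnot(all(thresholds > 0), all(thresholds <= 1))
  rows <- list()
  for (r in seq_along(scores_by_replicate)) {
    s <- scores_by_replicate[[r]]
    for (th in thresholds) {
      rows[[length(rows) + 1L]] <- data.frame(
        replicate = r, threshold = th,
        fraction = sum(!is.na(s) & s >= th) / n_chemicals)
    }
  }
  tab <- do.call(rbind, rows)
  agg <- do.call(rbind, lapply(split(tab, tab$threshold), function(d) {
    m <- mean(d$fraction)
    se <- if (nrow(d) > 1L) stats::sd(d$fraction) / sqrt(nrow(d)) else 0
    data.frame(threshold = d$threshold[1L], mean = m,
               ci_lo = max(0, m - 1.96 * se), ci_hi = min(1, m + 1.96 * se),
               n_replicates = nrow(d))
  }))
  rownames(agg) <- NULL
  list(table = tab, summary = agg)
}

#' Three-set annotation overlap (Venn regions)
#'
#' @param sets Named list of exactly three id vectors over a common universe.
#' @return List with per-set totals and the seven Venn region counts.
#' @export
annotation_overlap <- function(sets) {
  stopifnot(length(sets) == 3L)
  a <- unique(sets[[1L]]); b <- unique(sets[[2L]]); c_ <- unique(sets[[3L]])
  nm <- names(sets)
  if (is.null(nm)) nm <- c("A", "B", "C")
  regions <- list(
    only_1 = setdiff(a, union(b, c_)),
    only_2 = setdiff(b, union(a, c_)),
    only_3 = setdiff(c_, union(a, b)),
    only_12 = setdiff(intersect(a, b), c_),
    only_13 = setdiff(intersect(a, c_), b),
    only_23 = setdiff(intersect(b, c_), a),
    all_123 = intersect(intersect(a, b), c_))
  list(set_names = nm,
       totals = stats::setNames(c(length(a), length(b), length(c_)), nm),
       regions = lapply(regions, length),
       region_ids = regions)
}

#' Score attached spectra against each chemical's true spectrum
#'
#' Computes the binned cosine of the fragmentation spectrum attached to each
#' chemical (by DDA linking or DIA deconvolution) against that chemical's
#' true MS2 spectrum.
#'
#' @param spectra Named list (by chemical id) of spectra as returned by
#'   [link_dda_ground_truth()] or [deconvolve_dia()] keyed by ground-truth
#'   feature ids.
#' @param chemicals The `chemical_set` holding the true spectra.
#' @param bin_width,min_match Cosine matching parameters.
#' @return Named numeric vector, one score per chemical (NA when the
#'   chemical has no attached spectrum or the match fails the minimum
#'   matched-peak requirement).
#' @export
score_against_truth <- function(spectra, chemicals, bin_width = 0.05,
                                min_match = 3L) {
  scores <- rep(NA_real_, nrow(chemicals))
  names(scores) <- chemicals$id
  for (id in names(spectra)) {
    i <- match(id, chemicals$id)
    if (is.na(i)) next
    m <- cosine_similarity(spectra[[id]]$peaks, chemicals$ms2_peaks[[i]],
                           bin_width, min_match)
    if (m$matched) scores[i] <- m$cosine
  }
  scores
}

make_controller <- function(name, config) {
  switch(name,
         fullscan = controller_fullscan(),
         topn = do.call(controller_topn, config$topn %||% list()),
         swath = do.call(controller_swath, config$swath %||% list()),
         aif = do.call(controller_aif, config$aif %||% list()),
         stop("unknown controller: ", name))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Acquire + attach spectra + score one sample against the truth.
score_one_sample <- function(chems, controller_name, config) {
  ctl <- make_controller(controller_name, config)
  run <- run_acquisition(chems, ctl, timing = config$timing,
                         rt_range = config$rt_range, floor = config$floor)
  spectra <- if (controller_name %in% c("swath", "aif")) {
    deconvolve_dia(run, ground_truth_features(chems),
                   params = config$deconv)
  } else {
    link_dda_ground_truth(run, chems)
  }
  score_against_truth(spectra, chems, config$bin_width, config$min_match)
}

#' Benchmark configuration
#'
#' @param n_chemicals Vector of chemical counts to simulate.
#' @param controllers Character vector among `"topn"`, `"swath"`, `"aif"`.
#' @param replicates Number of replicate sample sets per condition.
#' @param thresholds Similarity thresholds for annotation counting.
#' @param seed Base integer seed; every replicate's seed derives from it.
#' @param bin_width,min_match Cosine matching parameters.
#' @param timing,rt_range,floor Acquisition parameters.
#' @param topn,swath,aif Per-controller parameter overrides (lists).
#' @param deconv DIA deconvolution parameters ([deconv_params()]).
#' @param mass_table Monoisotopic mass table for chemical sampling.
#' @return A config list for [run_benchmark()].
#' @export
benchmark_config <- function(n_chemicals = c(100),
                             controllers = c("topn", "swath", "aif"),
                             replicates = 5L,
                             thresholds = c(0.2, 0.4, 0.6, 0.8),
                             seed = 1L,
                             bin_width = 0.05, min_match = 3L,
                             timing = timing_config(),
                             rt_range = c(0, 400), floor = 100,
                             topn = list(), swath = list(), aif = list(),
                             deconv = deconv_params(),
                             mass_table = default_mass_table()) {
  list(n_chemicals = n_chemicals, controllers = controllers,
       replicates = as.integer(replicates), thresholds = thresholds,
       seed = as.integer(seed), bin_width = bin_width,
       min_match = as.integer(min_match), timing = timing,
       rt_range = rt_range, floor = floor,
       topn = topn, swath = swath, aif = aif, deconv = deconv,
       mass_table = mass_table)
}

#' Run the simulated acquisition benchmark
#'
#' For every combination of chemical count, replicate and controller:
#' generate a case-vs-control sample set, acquire each distinct sample
#' profile, attach fragmentation spectra (direct ground-truth links for DDA,
#' EIC-correlation deconvolution for DIA), score every chemical's best
#' spectrum against its own true spectrum, and tabulate annotated fractions
#' at each threshold. Within a sample set the five samples of a group share
#' one intensity profile, so one acquisition per group determines the whole
#' group (acquisition is deterministic).
#'
#' @param config A [benchmark_config()].
#' @return List with `rates` (one [annotation_rates()] result per
#'   controller x n_chemicals), `scores` (per-chemical best cosine vectors
#'   per run), and `median_cosine` (median matched score per run).
#' @export
run_benchmark <- function(config = benchmark_config()) {
  rates <- list(); scores <- list(); med <- list()
  for (n in config$n_chemicals) {
    for (ctl in config$controllers) {
      key <- paste0(ctl, "_n", n)
      per_rep <- vector("list", config$replicates)
      for (r in seq_len(config$replicates)) {
        seed_r <- config$seed + 7919L * r + as.integer(n) %% 7919L
        ss <- build_sample_set(n, replicate = r, seed = seed_r,
                               mass_table = config$mass_table)
        grp <- !duplicated(ss$group)
        best <- rep(NA_real_, n)
        for (s in which(grp)) {
          sc <- score_one_sample(ss$samples[[s]], ctl, config)
          best <- pmax(best, sc, na.rm = TRUE)
        }
        names(best) <- if (n > 0) ss$samples[[1L]]$id else character(0)
        per_rep[[r]] <- best
        scores[[paste0(key, "_rep", r)]] <- best
        med[[paste0(key, "_rep", r)]] <-
          stats::median(best[!is.na(best)])
      }
      rates[[key]] <- annotation_rates(per_rep, config$thresholds, n)
    }
  }
  list(rates = rates, scores = scores, median_cosine = med,
       config = config[setdiff(names(config), "mass_table")])
}
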