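# Proton mass used for the singly-protonated precursor ion ([M+H]+, z = 1).
PROTON_MASS <- 1.00728

#' Read a table of monoisotopic masses
#'
#' Reads a one- or two-column TSV of candidate formula masses. When two
#' columns are present the first is taken as an (optional) formula string and
#' the second as the monoisotopic mass; a single column is read as masses.
#'
#' @param path Path to a TSV file. A header line is detected automatically.
#' @return Numeric vector of monoisotopic masses (Da).
#' @export
read_mass_table <- function(path) {
  tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) > 2L) stop("mass table must have one or two columns")
  col <- tab[[ncol(tab)]]
  if (is.character(col) && suppressWarnings(is.na(as.numeric(col[1L])))) {
    col <- col[-1L]  # header line
  }
  masses <- suppressWarnings(as.numeric(col))
  if (anyNA(masses)) stop("non-numeric entries in mass column of ", path)
  masses
}

#' Bundled synthetic CHNOPS mass table
#'
#' Returns the package's bundled table of 5,000 monoisotopic masses generated
#' once from chemically plausible CHNOPS formulas (100-1,000 Da). It stands in
#' for a metabolite-database mass list so that no external download is needed;
#' any user-supplied table can be passed to [sample_chemicals()] instead.
#'
#' @return Numeric vector of 5,000 monoisotopic masses (Da).
#' @export
default_mass_table <- function() {
  read_mass_table(system.file("extdata", "synthetic_chnops_masses.tsv",
                              package = "msacquisim", mustWork = TRUE))
}

# Run code under a local RNG seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Generate ground-truth synthetic chemicals
#'
#' Draws `n` synthetic analytes with known ground truth: a monoisotopic mass
#' chosen from a mass table (restricted to 100-1,000 Da), a retention-time
#' apex uniform on `rt_range` seconds, a chromatographic apex intensity
#' uniform on `intensity_range` counts, a Gaussian elution profile with
#' standard deviation `sigma` seconds, and a true MS2 spectrum with a
#' Poisson(`mean_fragments`) number of fragment peaks whose m/z are uniform
#' between 70 Da and the neutral exact mass and whose intensities are a
#' uniform 0.1-0.8 proportion of the apex intensity. Precursors are modelled
#' as singly protonated ([M+H]+), one ion species per chemical.
#'
#' @param n Number of chemicals (>= 0).
#' @param mass_table Numeric vector of candidate monoisotopic masses; defaults
#'   to the bundled synthetic CHNOPS table.
#' @param seed Integer seed; generation is bit-identical for a fixed seed.
#' @param rt_range,intensity_range,sigma,mean_fragments,fragment_mz_min,
#'   fragment_prop_range Generative parameters; defaults are the simulated
#'   study conditions.
#' @return A `chemical_set`: a data frame with columns `id`,
#'   `monoisotopic_mass`, `mz`, `rt_apex`, `apex_intensity`, `chrom_sigma`
#'   and a list column `ms2_peaks` of two-column matrices (mz, intensity).
#' @export
sample_chemicals <- function(n, mass_table = default_mass_table(), seed = 1L,
                             rt_range = c(0, 400),
                             intensity_range = c(1e4, 1e7),
                             sigma = 5,
                             mean_fragments = 10,
                             fragment_mz_min = 70,
                             fragment_prop_range = c(0.1, 0.8)) {
  if (length(n) != 1L || is.na(n) || n < 0) stop("n must be a single count >= 0")
  n <- as.integer(n)
  mass_table <- mass_table[mass_table >= 100 & mass_table <= 1000]
  if (length(mass_table) == 0L)
    stop("mass table is empty after restricting to 100-1000 Da")
  with_seed(seed, {
    mass <- sample(mass_table, n, replace = TRUE)
    rt <- stats::runif(n, rt_range[1L], rt_range[2L])
    apex <- stats::runif(n, intensity_range[1L], intensity_range[2L])
    nfrag <- stats::rpois(n, mean_fragments)
    ms2 <- vector("list", n)
    for (i in seq_len(n)) {
      k <- nfrag[i]
      fmz <- stats::runif(k, fragment_mz_min, mass[i])
      fint <- stats::runif(k, fragment_prop_range[1L],
                           fragment_prop_range[2L]) * apex[i]
      o <- order(fmz)
      ms2[[i]] <- cbind(mz = fmz[o], intensity = fint[o])
    }
    out <- data.frame(id = sprintf("chem_%04d_%05d", seed %% 10000L, seq_len(n)),
                      monoisotopic_mass = mass,
                      mz = mass + PROTON_MASS,
                      rt_apex = rt,
                      apex_intensity = apex,
                      chrom_sigma = rep(sigma, n),
                      stringsAsFactors = FALSE)
    out$ms2_peaks <- ms2
    class(out) <- c("chemical_set", "data.frame")
    out
  })
}

#' Build a case-vs-control sample set
#'
#' Generates one replicate of the simulated study design: the same `n`
#' chemicals observed in 5 case and 5 control samples. A chemical keeps an
#' identical m/z and RT apex in all 10 samples; its apex intensity differs
#' between the groups through a per-chemical fold change drawn log-uniform on
#' `fold_range` and applied to the control group.
#'
#' @param n Number of chemicals per sample.
#' @param replicate Replicate index (bookkeeping only).
#' @param seed Integer seed.
#' @param fold_range Control/case fold-change range (log-uniform).
#' @param ... Passed to [sample_chemicals()].
#' @return A `sample_set`: list with `samples` (10 `chemical_set`s), `group`
#'   (5 "case" then 5 "control"), `n_chemicals`, `replicate_index`, `seed`.
#' @export
build_sample_set <- function(n, replicate = 1L, seed = 1L,
                             fold_range = c(0.2, 5), ...) {
  case <- sample_chemicals(n, seed = seed, ...)
  fold <- with_seed(seed + 500009L,
                    exp(stats::runif(nrow(case), log(fold_range[1L]),
                                     log(fold_range[2L]))))
  control <- case
  control$apex_intensity <- case$apex_intensity * fold
  for (i in seq_len(nrow(control)))
    control$ms2_peaks[[i]][, "intensity"] <-
      control$ms2_peaks[[i]][, "intensity"] * fold[i]
  samples <- c(rep(list(case), 5L), rep(list(control), 5L))
  structure(list(samples = samples,
                 group = rep(c("case", "control"), each = 5L),
                 n_chemicals = as.integer(n),
                 replicate_index = as.integer(replicate),
                 seed = as.integer(seed)),
            class = "sample_set")
}

#' Gaussian chromatographic intensity
#'
#' Evaluates the elution profile `apex * exp(-(rt - rt_apex)^2 / (2 sigma^2))`
#' for each chemical at a single retention time. Values below `floor` are
#' reported as 0 (not eluting).
#'
#' @param chemicals A `chemical_set` (any number of rows).
#' @param rt Retention time in seconds (scalar).
#' @param floor Detection floor in counts; default 100.
#' @return Numeric vector of intensities, one per chemical.
#' @export
chromatogram_intensity <- function(chemicals, rt, floor = 100) {
  z <- (rt - chemicals$rt_apex) / chemicals$chrom_sigma
  v <- chemicals$apex_intensity * exp(-0.5 * z^2)
  v[v < floor] <- 0
  v
}

#' Serialise a sample set to a ground-truth JSON file
#'
#' Writes one record per chemical per sample (sample index, group, chemical
#' id, m/z, RT apex, apex intensity, true MS2 peaks) so that evaluation can
#' run without re-simulation.
#'
#' @param sample_set A `sample_set`.
#' @param path Output path.
#' @export
write_ground_truth <- function(sample_set, path) {
  recs <- list()
  for (s in seq_along(sample_set$samples)) {
    chems <- sample_set$samples[[s]]
    for (i in seq_len(nrow(chems))) {
      recs[[length(recs) + 1L]] <- list(
        sample = s, group = sample_set$group[s], id = chems$id[i],
        mz = chems$mz[i], rt_apex = chems$rt_apex[i],
        apex_intensity = chems$apex_intensity[i],
        chrom_sigma = chems$chrom_sigma[i],
        ms2_mz = chems$ms2_peaks[[i]][, "mz"],
        ms2_intensity = chems$ms2_peaks[[i]][, "intensity"])
    }
  }
  jsonlite::write_json(list(n_chemicals = sample_set$n_chemicals,
                            replicate_index = sample_set$replicate_index,
                            records = recs),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a ground-truth JSON file back into a sample set
#'
#' Inverse of [write_ground_truth()].
#'
#' @param path Path to a ground-truth JSON file.
#' @return A `sample_set`.
#' @export
read_ground_truth <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  recs <- doc$records
  sample_ids <- vapply(recs, function(r) r$sample, numeric(1L))
  groups <- vapply(recs, function(r) r$group, character(1L))
  samples <- lapply(sort(unique(sample_ids)), function(s) {
    rs <- recs[sample_ids == s]
    out <- data.frame(
      id = vapply(rs, function(r) r$id, character(1L)),
      monoisotopic_mass = vapply(rs, function(r) r$mz, numeric(1L)) -
        PROTON_MASS,
      mz = vapply(rs, function(r) r$mz, numeric(1L)),
      rt_apex = vapply(rs, function(r) r$rt_apex, numeric(1L)),
      apex_intensity = vapply(rs, function(r) r$apex_intensity, numeric(1L)),
      chrom_sigma = vapply(rs, function(r) r$chrom_sigma, numeric(1L)),
      stringsAsFactors = FALSE)
    out$ms2_peaks <- lapply(rs, function(r)
      cbind(mz = unlist(r$ms2_mz), intensity = unlist(r$ms2_intensity)))
    class(out) <- c("chemical_set", "data.frame")
    out
  })
  structure(list(samples = samples,
                 group = vapply(sort(unique(sample_ids)), function(s)
                   groups[sample_ids == s][1L], character(1L)),
                 n_chemicals = doc$n_chemicals,
                 replicate_index = doc$replicate_index,
                 seed = NA_integer_),
            class = "sample_set")
}
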