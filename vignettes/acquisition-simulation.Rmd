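---
title: "Simulating and benchmarking LC-MS/MS acquisition strategies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and benchmarking LC-MS/MS acquisition strategies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msacquisim)
```

## The problem

In untargeted LC-MS/MS metabolomics, fragmentation (MS2) spectra are acquired
either *data-dependently* (DDA: after each MS1 survey scan the instrument
picks a handful of intense precursor ions and fragments each in a narrow
isolation window) or *data-independently* (DIA: fixed, wide isolation windows
are fragmented regardless of what elutes, either tiled across the m/z range —
SWATH — or covering it in one shot — AIF). DDA yields clean, nearly
single-analyte spectra but limited and stochastic coverage; DIA fragments
everything but mixes the fragments of all co-isolated precursors, and a
deconvolution step must un-mix them. Which strategy annotates more compounds
depends on how crowded the elution profile is — a quantity impossible to
control in a real sample. This package implements a desk-scale digital twin
of the instrument so the comparison can be made against a known ground truth:
synthetic chemical mixtures of any size are "injected", acquired by
interchangeable controller policies, deconvoluted, and scored against their
own true spectra.

## The generative model

Each synthetic chemical is defined by:

* a **monoisotopic mass** drawn from a mass table restricted to 100–1,000 Da.
  The bundled table (`default_mass_table()`) holds 5,000 masses generated
  once from chemically plausible CHNOPS formulas (ring-and-double-bond
  equivalents constrained, low masses weighted as in metabolite databases);
  it is a synthetic stand-in for a metabolite-database mass list and any
  user table can replace it. The precursor ion is the protonated molecule
  ([M+H]^+^, +1.00728 Da, charge 1); isotopes and adducts are deliberately
  not modelled.
* a **retention-time apex** uniform on 0–400 s — a deliberately narrow
  gradient so that large mixtures produce dense co-elution everywhere;
* a **Gaussian elution profile** with σ = 5 s and an apex intensity uniform
  on 10^4^–10^7^ counts; intensities below a detection floor (default 100
  counts) are treated as not eluting, which keeps the Gaussian finite;
* a **true MS2 spectrum**: a Poisson(10) number of fragments, each with m/z
  uniform between 70 Da and the neutral exact mass and intensity a uniform
  0.1–0.8 proportion of the apex intensity. The spectrum is sampled once per
  chemical; at acquisition time fragment intensities scale with the
  chemical's current chromatographic intensity relative to its apex, so a
  precursor fragmented on its elution edge yields a proportionally weaker
  copy of the same spectrum.

A *sample set* (`build_sample_set()`) is one replicate of a case-vs-control
design: 5 case and 5 control samples observing the same chemicals with
identical m/z and RT everywhere, while control-group intensities are
multiplied by a per-chemical fold change drawn log-uniformly from [1/5, 5].
The fold-change distribution is a package choice (only the fact that
intensities differ between groups is fixed by the design); it is symmetric
on the log scale and configurable. Within a group the five samples share one
intensity profile, so a noiseless acquisition of one sample determines the
whole group — the benchmark driver exploits this and acquires each distinct
profile once.

## The virtual instrument and the controllers

`run_acquisition()` drives an event loop: the controller requests scans, the
virtual MS generates each scan from whichever chemicals elute at the current
clock time, the clock advances by the scan duration, and the completed scan
is handed back to the controller. Scan durations default to 0.4 s (MS1) and
0.2 s (MS2), consistent with Orbitrap resolutions of 120,000 and 7,500; they
are configurable and all reported numbers use the defaults. Scans are
centroid-only; coincident peaks (closer than 0.001 Da) are summed, with the
m/z of the most intense contribution used as the representative — an exact
choice that avoids floating-point drift for isolated peaks. No electronic or
chemical noise is added by default.

Four controllers are provided:

* **Fullscan** — MS1 only.
* **Top-N DDA** (`controller_topn()`): after each survey scan, the N = 10
  most intense peaks above 5,000 counts and not on the dynamic exclusion
  list are fragmented in 0.7 Da windows, most intense first (ties to lower
  m/z), then the next survey scan follows. Fragmented precursors are
  excluded for 15 s, matched at 10 ppm. The m/z tie-break and the exclusion
  tolerance are package choices.
* **SWATH** (`controller_swath()`): one survey scan followed by a fixed
  cycle of MS2 scans whose half-open windows `[lo, hi)` tile 70–1,000 m/z in
  100 Da steps (width and overlap configurable; presets for 25 and 50 Da
  windows ship with the benchmark configs). Half-open windows make adjacent
  windows partition the range exactly.
* **AIF** (`controller_aif()`): alternating survey and full-range
  fragmentation scans.

DIA schedules never depend on the data; every MS2 scan records the
ground-truth set of chemicals that contributed to it (precursor inside the
isolation window while eluting above the floor), which the DDA evaluation
reads directly instead of re-deriving associations from the files.

## DIA deconvolution

Real studies delegate DIA deconvolution to external software; this package
implements its own elution-profile–correlation deconvolution so the whole
pipeline runs self-contained. For each feature (in simulation, features are
taken from the ground truth — perfect peak picking, one feature per chemical
with an RT bounding box of ±3σ and an m/z box of ±10 ppm): the MS2 scans
whose window contains the feature m/z and whose RT lies inside the bounding
box are collected; per-fragment extracted ion chromatograms are built on
0.01 Da bins (nearest-bin-centre assignment); and a fragment is attributed
to the feature when its EIC has a Pearson correlation of at least 0.8 with
the feature's precursor EIC (taken from the interleaved MS1 scans and
interpolated to the MS2 scan times). The fragment intensity is its EIC value
at the covering scan nearest the apex; the spectrum's quality score is the
mean retained correlation. Features with fewer than 3 covering scans, or
with no usable precursor trace, receive an empty spectrum with quality 0.

Defaults (`deconv_params()`: minimum correlation 0.8, minimum 3 scans,
0.01 Da EIC bins) are package choices; external studies' deconvolution
settings live in software we do not reproduce. The method's failure mode is
intrinsic and intended: two precursors that co-elute perfectly in the same
window have proportional fragment EICs, correlation cannot separate them,
and both features receive the merged spectrum. This is precisely the
mechanism by which DIA degrades as mixtures grow — the benchmark exists to
quantify it.

For external data, `read_mzml()` loads any centroid mzML (the package writes
standard indexed mzML 1.1 via mzR), `read_feature_table()` accepts a CSV
feature list, `assign_dda_scans_to_features()` attaches DDA scans to feature
bounding boxes (highest precursor intensity wins), and
`match_chemicals_to_features()` pairs chemicals with detected features at
5 ppm / 10 s, nearest m/z first.

## Scoring and the benchmark

Spectra are compared by binned cosine similarity (`cosine_similarity()`):
intensities are summed onto a fixed grid anchored at zero (bin index =
`floor(mz / bin_width)`, default 0.05 Da) and a match requires at least
three bins non-empty in both spectra. The fixed anchored grid is
deterministic and symmetric; supplementary bin widths of 0.005 and 0.50 Da
are a config away.

`run_benchmark()` ties everything together: for each mixture size,
replicate, and controller it generates a sample set, acquires each distinct
sample profile, attaches spectra (direct links for DDA, deconvolution for
DIA), scores every chemical's best spectrum against its own true spectrum,
and reports the fraction of chemicals annotated at thresholds 0.2–0.8 with
a mean ± 1.96 SE confidence interval across replicates. A chemical counts
once however many samples annotate it, and fractions are computed per
replicate before averaging.

```{r benchmark, eval = FALSE}
bench <- run_benchmark(benchmark_config(
  n_chemicals = 100, controllers = c("topn", "swath", "aif"),
  replicates = 5, seed = 1))
bench$rates$topn_n100$summary
```

## What the simulation does and does not show

The generator reproduces the statistical structure of the simulated study —
co-elution density, intensity dynamic range, fragment sparsity — but not
several features of real data: isotope envelopes and adduct networks (which
compete for DDA slots and co-isolate in DIA windows), chemical noise peaks,
retention-time drift between samples, and imperfect peak picking (features
here are ground truth by design). Annotation rates from this simulator are
therefore ceilings for the DDA path in particular: with perfect linking and
no competing ion species, Top-N annotates nearly every chemical whenever
MS2 capacity exceeds the mixture size, whereas pipelines that detect
features and pick precursors among isotopes and adducts lose a roughly
size-independent fraction. The DIA results are dominated by the
deconvolution step itself and transfer more directly. Qualitative
conclusions — DDA's advantage growing with mixture size, SWATH sitting
between Top-N and AIF, deconvolved spectra growing mutually similar as
windows crowd — are the robust outputs; tests assert them across mixture
sizes of 100–5,000.

## Numerical choices and problem sizes

Reproducibility is strict: every stochastic step derives from an integer
seed, regeneration is bit-identical, and per-replicate seeds are offset by a
fixed prime stride so replicates are independent but recoverable. The test
suite exercises mixtures up to 5,000 chemicals for DDA and up to 2,000 for
DIA deconvolution, with two to five replicates per condition — sizes chosen
so the whole suite completes in minutes on one core while still reaching the
capacity-limited DDA regime and the deconvolution-limited DIA regime. The
acceptance script (`scripts/acceptance.R`) re-runs the full generative
benchmark at 100–5,000 chemicals (five replicates up to 500, two at 5,000)
in under a minute.

Degenerate inputs are defined, not accidental: zero-chemical samples
acquire empty scans on a fixed clock; empty isolation windows yield empty
MS2 scans that survive mzML round trips; spectra with fewer than three
shared bins are no-matches rather than zero-scores in annotation (but count
as 0 in pairwise distributions); and features whose bounding box leaves the
acquired RT range deconvolve to empty spectra with quality 0.
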