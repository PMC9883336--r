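#' Simulation parameters for synthetic MS2 spectra
#'
#' Controls for [simulate_spectrum()]. The intensity hierarchy mirrors what
#' clean FuFA-TAG spectra look like: the `[FCO]+` ion is the base peak
#' (relative height 1), diacyl ions are prominent, the furan core and
#' McLafferty ions are minor, and the surviving precursor is weak. Ranges
#' are sampled uniformly per peak. Conventional acylium ions are included at
#' a low fixed height (they play no role in identification). Decoy peaks are
#' placed uniformly over `decoy_mz_range` below all diagnostic heights.
#'
#' @param mass_error_ppm Gaussian m/z error, 1 sigma in ppm (default 1.0,
#'   a typical Orbitrap calibration spread; 0 gives exact positions)
#' @param fco relative height of the `[FCO]+` base peak
#' @param diacyl,core,mclafferty relative height ranges `c(lo, hi)`
#' @param precursor,acylium fixed relative heights
#' @param n_decoys number of decoy peaks
#' @param decoy_mz_range m/z range for decoy peaks
#' @param decoy_intensity relative height range for decoy peaks
#' @param base_intensity absolute counts corresponding to relative height 1
#' @param seed optional integer; fixes the whole output stream
#' @return object of class `sim_params`
#' @export
sim_params <- function(mass_error_ppm = 1.0, fco = 1.0,
                       diacyl = c(0.2, 0.6), core = c(0.05, 0.2),
                       mclafferty = c(0.05, 0.2), precursor = 0.1,
                       acylium = 0.05, n_decoys = 20,
                       decoy_mz_range = c(50, 1000),
                       decoy_intensity = c(0.005, 0.05),
                       base_intensity = 1000, seed = NULL) {
  stopifnot(mass_error_ppm >= 0, fco > 0, all(diacyl > 0), all(core > 0),
            all(mclafferty > 0), precursor > 0, n_decoys >= 0)
  structure(list(mass_error_ppm = mass_error_ppm, fco = fco, diacyl = diacyl,
                 core = core, mclafferty = mclafferty, precursor = precursor,
                 acylium = acylium, n_decoys = n_decoys,
                 decoy_mz_range = decoy_mz_range,
                 decoy_intensity = decoy_intensity,
                 base_intensity = base_intensity, seed = seed),
            class = "sim_params")
}

.runif1 <- function(range) if (length(range) == 2) stats::runif(1, range[1], range[2]) else range

#' Simulate the MS2 spectrum of a TAG
#'
#' Places a peak at every predicted diagnostic m/z of the TAG, perturbed by
#' Gaussian ppm error, with intensities drawn from the model in
#' [sim_params()], plus uniformly placed decoy peaks. Deterministic under a
#' fixed seed.
#'
#' @param tag a `tag_composition`
#' @param params a `sim_params`
#' @param seed overrides `params$seed` when given
#' @param id spectrum identifier
#' @return an `ms2_spectrum` whose precursor is the (noisy) protonated
#'   precursor m/z
#' @examples
#' s <- simulate_spectrum(build_tag("L", "L", "9D5"), sim_params(seed = 1))
#' @export
simulate_spectrum <- function(tag, params = sim_params(), seed = NULL,
                              id = paste0("sim_", tag$name)) {
  stopifnot(inherits(tag, "tag_composition"), inherits(params, "sim_params"))
  if (is.null(seed)) seed <- params$seed
  if (!is.null(seed)) set.seed(seed)
  fs <- fragment_set(tag)
  mz <- c(fs$precursor_h)
  height <- c(params$precursor)
  for (r in seq_len(nrow(fs$diacyl))) {
    mz <- c(mz, fs$diacyl$mz[r]); height <- c(height, .runif1(params$diacyl))
  }
  for (r in seq_len(nrow(fs$acylium))) {
    mz <- c(mz, fs$acylium$mz[r])
    height <- c(height, if (fs$acylium$is_fufa[r]) params$fco else params$acylium)
  }
  for (r in seq_len(nrow(fs$core))) {
    mz <- c(mz, fs$core$mz[r]); height <- c(height, .runif1(params$core))
  }
  for (r in seq_len(nrow(fs$mclafferty))) {
    mz <- c(mz, fs$mclafferty$mz[r]); height <- c(height, .runif1(params$mclafferty))
  }
  if (params$n_decoys > 0) {
    mz <- c(mz, stats::runif(params$n_decoys, params$decoy_mz_range[1],
                             params$decoy_mz_range[2]))
    height <- c(height, stats::runif(params$n_decoys,
                                     params$decoy_intensity[1],
                                     params$decoy_intensity[2]))
  }
  if (params$mass_error_ppm > 0)
    mz <- mz * (1 + stats::rnorm(length(mz), 0, params$mass_error_ppm) * 1e-6)
  prec_obs <- fs$precursor_h
  if (params$mass_error_ppm > 0)
    prec_obs <- prec_obs * (1 + stats::rnorm(1, 0, params$mass_error_ppm) * 1e-6)
  ms2_spectrum(mz, height * params$base_intensity, precursor_mz = prec_obs,
               id = id, source = "simulation")
}

#' Simulate a decoy-only spectrum
#'
#' A spectrum containing nothing but decoy peaks: a uniformly drawn
#' precursor in `precursor_range` and `n_decoys` uniform peaks. Used as a
#' negative control — screening decoy spectra must yield no annotations.
#'
#' @param params a `sim_params`
#' @param seed overrides `params$seed` when given
#' @param precursor_range m/z range for the random precursor
#' @param id spectrum identifier
#' @return an `ms2_spectrum`
#' @export
decoy_spectrum <- function(params = sim_params(), seed = NULL,
                           precursor_range = c(850, 1050),
                           id = "decoy") {
  if (is.null(seed)) seed <- params$seed
  if (!is.null(seed)) set.seed(seed)
  n <- max(params$n_decoys, 1)
  mz <- stats::runif(n, params$decoy_mz_range[1], params$decoy_mz_range[2])
  height <- stats::runif(n, params$decoy_intensity[1], params$decoy_intensity[2])
  ms2_spectrum(mz, height * params$base_intensity,
               precursor_mz = stats::runif(1, precursor_range[1], precursor_range[2]),
               id = id, source = "simulation")
}

# exact isobaric offsets: CH4 - O and H8O - C2
.isobar_offset <- function(class) {
  switch(class,
    O_vs_CH4 = monoisotopic_mass("CH4") - monoisotopic_mass("O"),
    C2_vs_H8O = -(monoisotopic_mass("H8O") - monoisotopic_mass(c(C = 2L))),
    stop("unknown interference class: ", class, call. = FALSE))
}

#' Simulate a spectrum with nominal-isobar interference
#'
#' Adds interfering peaks offset by the exact isobaric mass difference from
#' the precursor and the `[FCO]+` ion: +0.0364 Da for the "O vs CH4" class
#' (a FuFA-TAG ion is lighter than its conventional isobar) and -0.0575 Da
#' for the "C2 vs H8O" class (the polyunsaturated isobar is lighter). At a
#' 4 ppm tolerance these interferences are tens of ppm away and must never
#' be matched.
#'
#' @param tag a `tag_composition`
#' @param interference_class `"O_vs_CH4"` or `"C2_vs_H8O"`
#' @param params a `sim_params`
#' @param seed overrides `params$seed` when given
#' @return an `ms2_spectrum`
#' @examples
#' s <- isobar_challenge(build_tag("O", "O", "9D5"), "C2_vs_H8O",
#'                       sim_params(seed = 1))
#' @export
isobar_challenge <- function(tag,
                             interference_class = c("O_vs_CH4", "C2_vs_H8O"),
                             params = sim_params(), seed = NULL) {
  interference_class <- match.arg(interference_class)
  s <- simulate_spectrum(tag, params, seed = seed,
                         id = paste0("isobar_", tag$name))
  off <- .isobar_offset(interference_class)
  fs <- fragment_set(tag)
  extra_mz <- c(fs$precursor_h + off,
                fs$acylium$mz[fs$acylium$is_fufa] + off)
  extra_int <- rep(0.8 * params$base_intensity, length(extra_mz))
  ms2_spectrum(c(s$peaks$mz, extra_mz), c(s$peaks$intensity, extra_int),
               precursor_mz = s$precursor_mz, id = s$id, rt = s$rt,
               source = "simulation")
}
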