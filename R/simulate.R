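#' Simulation configuration for synthetic MALDI-ToF spectra
#'
#' The defaults describe a linear-mode protein spectrum in the biotyping
#' range: a 1 Da grid over 1.5-20 kDa, Gaussian peak profiles of sigma 5 Da,
#' a smooth exponentially decaying low-mass baseline hump, additive detector
#' noise, ~0.02% relative mass jitter per individual (linear-mode mass
#' accuracy scale) and a 30% coefficient of variation on peak heights.
#'
#' @param mass_range numeric length-2, m/z range in Da.
#' @param grid_step grid spacing in Da.
#' @param peak_width Gaussian sigma of a peak profile, Da.
#' @param baseline_amplitude baseline intensity at the low-mass end.
#' @param baseline_decay baseline decay rate, 1/Da.
#' @param noise_sd standard deviation of additive Gaussian noise
#'   (truncated at zero so intensities stay physical).
#' @param mass_jitter_rel per-individual relative m/z perturbation (sd).
#' @param intensity_cv coefficient of variation of realized peak heights
#'   (log-normal, mean equal to the fingerprint mean intensity).
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(mass_range = c(1500, 20000), grid_step = 1,
                       peak_width = 5, baseline_amplitude = 20,
                       baseline_decay = 1 / 2500, noise_sd = 1,
                       mass_jitter_rel = 2e-4, intensity_cv = 0.3) {
  cfg <- list(mass_range = as.numeric(mass_range), grid_step = grid_step,
              peak_width = peak_width, baseline_amplitude = baseline_amplitude,
              baseline_decay = baseline_decay, noise_sd = noise_sd,
              mass_jitter_rel = mass_jitter_rel, intensity_cv = intensity_cv)
  if (length(cfg$mass_range) != 2L || cfg$mass_range[1] >= cfg$mass_range[2])
    stop_msg("mass_range must be [low, high] with low < high")
  if (grid_step <= 0) stop_msg("grid_step must be positive")
  if (peak_width <= 0) stop_msg("peak_width must be positive")
  if (noise_sd < 0 || intensity_cv < 0 || mass_jitter_rel < 0 ||
      baseline_amplitude < 0 || baseline_decay < 0)
    stop_msg("noise_sd, intensity_cv, mass_jitter_rel, baseline parameters must be >= 0")
  structure(cfg, class = "sim_config")
}

#' Construct a species fingerprint
#'
#' The ground-truth peak model of one synthetic species: peak masses, mean
#' intensities, and per-peak occurrence probabilities (reproducible peaks
#' have probability near 1; peaks vary between individuals).
#'
#' @param species_label species name.
#' @param peak_masses strictly increasing m/z values, Da.
#' @param peak_mean_intensities positive mean apex intensities.
#' @param peak_occurrence_probs per-peak Bernoulli occurrence probability.
#' @param config a [sim_config()] (masses must lie strictly inside its range).
#' @return an object of class `species_fingerprint`.
#' @export
species_fingerprint <- function(species_label, peak_masses,
                                peak_mean_intensities,
                                peak_occurrence_probs = rep(1, length(peak_masses)),
                                config = sim_config()) {
  n <- length(peak_masses)
  if (length(peak_mean_intensities) != n || length(peak_occurrence_probs) != n)
    stop_msg("fingerprint fields must have equal length")
  if (n < 1L) stop_msg("a fingerprint needs at least one peak")
  if (any(diff(peak_masses) <= 0)) stop_msg("peak masses must be strictly increasing")
  if (any(peak_masses <= config$mass_range[1]) || any(peak_masses >= config$mass_range[2]))
    stop_msg("peak masses must lie strictly inside the mass range")
  if (any(peak_mean_intensities <= 0)) stop_msg("mean intensities must be positive")
  if (any(peak_occurrence_probs < 0 | peak_occurrence_probs > 1))
    stop_msg("occurrence probabilities must be in [0, 1]")
  structure(list(species_label = as.character(species_label),
                 peak_masses = as.numeric(peak_masses),
                 peak_mean_intensities = as.numeric(peak_mean_intensities),
                 peak_occurrence_probs = as.numeric(peak_occurrence_probs)),
            class = "species_fingerprint")
}

#' @export
print.species_fingerprint <- function(x, ...) {
  cat(sprintf("<species_fingerprint> %s: %d peaks, %.0f-%.0f Da\n",
              x$species_label, length(x$peak_masses),
              min(x$peak_masses), max(x$peak_masses)))
  invisible(x)
}

# shared-peak fraction between two mass sets under a relative tolerance,
# by greedy pairwise matching in mass order
shared_peak_fraction <- function(m1, m2, tolerance_rel) {
  used <- logical(length(m2))
  shared <- 0L
  for (m in m1) {
    j <- which(!used & abs(m2 - m) / ((m2 + m) / 2) <= tolerance_rel)
    if (length(j)) {
      used[j[1L]] <- TRUE
      shared <- shared + 1L
    }
  }
  shared / min(length(m1), length(m2))
}

#' Generate distinct species fingerprints
#'
#' Peak masses are drawn uniformly over the mass range with a minimum
#' within-species separation (default 8 Gaussian sigmas, so neighboring
#' peaks stay resolvable by a half-window-7 detector on a 1 Da grid); mean
#' intensities are log-normal around `intensity_meanlog`; occurrence
#' probabilities are uniform over `occurrence_range`. Species are redrawn
#' until no pair shares more than `max_overlap` of its peaks within the
#' binning tolerance, so fingerprints stay pairwise distinct.
#'
#' @param n_species number of species.
#' @param n_peaks_range integer length-2, min/max peaks per species.
#' @param config a [sim_config()].
#' @param seed integer seed; the generator is deterministic given it.
#' @param max_overlap maximum allowed shared-peak fraction between species.
#' @param tolerance_rel relative mass tolerance defining "shared".
#' @param min_separation minimum within-species peak spacing, Da.
#' @param occurrence_range range of per-peak occurrence probabilities.
#' @param intensity_meanlog,intensity_sdlog log-normal parameters for the
#'   species mean peak intensities.
#' @return list of [species_fingerprint()] objects.
#' @export
generate_fingerprints <- function(n_species, n_peaks_range = c(5, 30),
                                  config = sim_config(), seed = 1L,
                                  max_overlap = 0.2, tolerance_rel = 0.001,
                                  min_separation = 8 * config$peak_width,
                                  occurrence_range = c(0.7, 1),
                                  intensity_meanlog = log(80),
                                  intensity_sdlog = 0.4) {
  if (n_species < 1L) stop_msg("n_species must be >= 1")
  if (n_peaks_range[1] < 1L || n_peaks_range[2] < n_peaks_range[1])
    stop_msg("invalid n_peaks_range")
  lo <- config$mass_range[1] + 2 * config$peak_width
  hi <- config$mass_range[2] - 2 * config$peak_width
  if (n_peaks_range[2] * min_separation > (hi - lo))
    stop_msg("infeasible: %d peaks at separation %.0f Da do not fit in %.0f Da",
             n_peaks_range[2], min_separation, hi - lo)
  with_seed(seed, {
    fps <- vector("list", n_species)
    for (sp in seq_len(n_species)) {
      ok <- FALSE
      for (attempt in 1:200) {
        k <- if (n_peaks_range[1] == n_peaks_range[2]) n_peaks_range[1] else
          sample(seq(n_peaks_range[1], n_peaks_range[2]), 1L)
        masses <- sort(runif(k, lo, hi))
        if (k > 1L && any(diff(masses) < min_separation)) next
        overlaps <- vapply(fps[seq_len(sp - 1L)], function(f)
          shared_peak_fraction(masses, f$peak_masses, tolerance_rel), 0)
        if (all(overlaps <= max_overlap)) { ok <- TRUE; break }
      }
      if (!ok) stop_msg("could not draw a fingerprint for species %d under the overlap cap", sp)
      fps[[sp]] <- species_fingerprint(
        species_label = sprintf("sp%02d", sp),
        peak_masses = masses,
        peak_mean_intensities = rlnorm(k, intensity_meanlog, intensity_sdlog),
        peak_occurrence_probs = runif(k, occurrence_range[1], occurrence_range[2]),
        config = config)
    }
    fps
  })
}

#' Simulate one raw spectrum from a species fingerprint
#'
#' intensity = baseline + sum of present Gaussian peak profiles + truncated
#' Gaussian noise. Peak presence is Bernoulli per occurrence probability,
#' realized height is log-normal with the configured CV around the
#' fingerprint mean, and each peak mass is jittered by a relative Gaussian
#' perturbation. The realized (jittered, present) peak masses are recorded in
#' `meta$true_peaks` so detection performance can be scored.
#'
#' @param fp a [species_fingerprint()].
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @param id spectrum identifier stored in metadata.
#' @return a [raw_spectrum()] with `meta$label`, `meta$true_peaks`,
#'   `meta$true_heights`.
#' @export
simulate_spectrum <- function(fp, config = sim_config(), seed = 1L,
                              id = fp$species_label) {
  stopifnot(inherits(fp, "species_fingerprint"), inherits(config, "sim_config"))
  mass <- seq(config$mass_range[1], config$mass_range[2], by = config$grid_step)
  with_seed(seed, {
    intensity <- config$baseline_amplitude *
      exp(-config$baseline_decay * (mass - config$mass_range[1]))
    k <- length(fp$peak_masses)
    present <- rbinom(k, 1L, fp$peak_occurrence_probs) == 1L
    # log-normal with E = mean and the configured CV
    sdlog <- sqrt(log(1 + config$intensity_cv^2))
    heights <- rlnorm(k, log(fp$peak_mean_intensities) - sdlog^2 / 2, sdlog)
    mus <- fp$peak_masses * (1 + rnorm(k, 0, config$mass_jitter_rel))
    sig <- config$peak_width
    for (j in which(present)) {
      idx <- which(mass >= mus[j] - 6 * sig & mass <= mus[j] + 6 * sig)
      if (length(idx))
        intensity[idx] <- intensity[idx] +
          heights[j] * exp(-(mass[idx] - mus[j])^2 / (2 * sig^2))
    }
    if (config$noise_sd > 0)
      intensity <- intensity + rnorm(length(mass), 0, config$noise_sd)
    intensity <- pmax(intensity, 0)
    raw_spectrum(mass, intensity,
                 meta = list(label = fp$species_label, id = id, seed = seed,
                             true_peaks = mus[present],
                             true_heights = heights[present]))
  })
}

#' Simulate a labeled dataset of spectra
#'
#' @param fps list of [species_fingerprint()] objects.
#' @param n_per_species integer vector of spectra per species (recycled if
#'   scalar).
#' @param config a [sim_config()].
#' @param seed integer seed; per-spectrum seeds are derived from it.
#' @return list of [raw_spectrum()] objects, `sum(n_per_species)` long.
#' @export
simulate_dataset <- function(fps, n_per_species, config = sim_config(), seed = 1L) {
  if (length(n_per_species) == 1L) n_per_species <- rep(n_per_species, length(fps))
  if (length(n_per_species) != length(fps))
    stop_msg("n_per_species length (%d) must match fps length (%d)",
             length(n_per_species), length(fps))
  if (any(n_per_species < 1L)) stop_msg("n_per_species must be >= 1")
  out <- vector("list", sum(n_per_species))
  pos <- 0L
  for (i in seq_along(fps)) {
    for (r in seq_len(n_per_species[i])) {
      pos <- pos + 1L
      out[[pos]] <- simulate_spectrum(
        fps[[i]], config,
        seed = derive_seed(seed, sprintf("spec-%d-%d", i, r)),
        id = sprintf("%s_%02d", fps[[i]]$species_label, r))
    }
  }
  out
}

#' Write a simulated dataset as ASCII spectra plus a manifest
#'
#' @param spectra list of [raw_spectrum()] objects with `meta$label`.
#' @param dir output directory (created if missing).
#' @return the manifest path, invisibly.
#' @export
write_spectra <- function(spectra, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(seq_along(spectra), function(i) {
    s <- spectra[[i]]
    fn <- sprintf("%s.txt", if (!is.null(s$meta$id)) s$meta$id else sprintf("spectrum_%03d", i))
    write_spectrum(s, file.path(dir, fn))
    data.frame(filename = fn,
               species_label = if (!is.null(s$meta$label)) s$meta$label else NA,
               seed = if (!is.null(s$meta$seed)) s$meta$seed else NA)
  })
  mf <- do.call(rbind, rows)
  path <- file.path(dir, "manifest.csv")
  write.csv(mf, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
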