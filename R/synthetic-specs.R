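# Specification objects for the synthetic-data generators. Each constructor
# validates its arguments once; the generators are then pure functions of the
# spec (seed included), so identical specs give bit-identical output.

PATTERN_CLASSES <- c("unipolar", "bipolar_asymmetric", "bipolar_symmetric",
                     "diffuse")

#' Specification of a synthetic snapshot population
#'
#' Describes a field of non-overlapping, axis-aligned rod cells (rectangles
#' with semicircular caps) with cytoplasmic background fluorescence and 0-2
#' polar clusters per cell. The pattern mixture and per-class asymmetry-index
#' target ranges define the ground truth against which the snapshot
#' quantification pipeline is scored.
#'
#' Default geometry (40 x 9 px cells) and intensities (cytoplasm 100 +/- 8)
#' are typical of epifluorescence images of *M. xanthus* at ~0.06 um/px after
#' background subtraction. Asymmetry targets for the bipolar classes default
#' to the interior of their class intervals so that the intended class is
#' unambiguous; unipolar cells carry a single cluster (asymmetry exactly 1).
#'
#' @param n_cells number of cells to place.
#' @param pattern_mixture named probabilities over
#'   `c("unipolar", "bipolar_asymmetric", "bipolar_symmetric", "diffuse")`;
#'   must sum to 1. Missing classes get probability 0.
#' @param cell_length_px,cell_width_px rod dimensions in pixels.
#' @param cytoplasm_mean,cytoplasm_sd cytoplasmic intensity distribution.
#' @param cluster_intensity_factor multiplier (>= 1) on `cytoplasm_mean` for
#'   cluster pixels; must satisfy
#'   `cluster_intensity_factor * cytoplasm_mean > cytoplasm_mean + 2 * cytoplasm_sd`
#'   so that intended clusters are detectable by construction.
#' @param cluster_size_px pixels per intended cluster (>= 3).
#' @param omega_target_range named list of `c(lo, hi)` intervals for the
#'   intended asymmetry index per class; must be contained in the class
#'   definition intervals (unipolar within (0.9, 1], asymmetric within
#'   (0.2, 0.9), symmetric within [0, 0.2)).
#' @param noise_sd additive Gaussian noise applied to every pixel.
#' @param seed integer seed.
#' @return an object of class `snapshot_population_spec`.
#' @export
snapshot_population_spec <- function(n_cells,
                                     pattern_mixture,
                                     cell_length_px = 40,
                                     cell_width_px = 9,
                                     cytoplasm_mean = 100,
                                     cytoplasm_sd = 8,
                                     cluster_intensity_factor = 3,
                                     cluster_size_px = 6,
                                     omega_target_range = list(
                                       unipolar = c(1, 1),
                                       bipolar_asymmetric = c(0.3, 0.8),
                                       bipolar_symmetric = c(0, 0.15)),
                                     noise_sd = 4,
                                     seed = 1L) {
  assert_that(is_count(n_cells), "n_cells must be a positive integer")
  assert_that(is.numeric(pattern_mixture) && !is.null(names(pattern_mixture)),
              "pattern_mixture must be a named numeric vector")
  assert_that(all(names(pattern_mixture) %in% PATTERN_CLASSES),
              "unknown pattern class in mixture; use %s",
              paste(PATTERN_CLASSES, collapse = ", "))
  mix <- stats::setNames(numeric(length(PATTERN_CLASSES)), PATTERN_CLASSES)
  mix[names(pattern_mixture)] <- pattern_mixture
  assert_that(all(mix >= 0) && abs(sum(mix) - 1) < 1e-9,
              "pattern_mixture probabilities must be non-negative and sum to 1")
  assert_that(is_num1(cell_length_px) && cell_length_px > 0 &&
                is_num1(cell_width_px) && cell_width_px > 0,
              "cell dimensions must be positive")
  assert_that(cell_length_px >= 2 * cell_width_px,
              "cells must be rods: length >= 2 * width")
  assert_that(is_num1(cytoplasm_mean) && cytoplasm_mean > 0 &&
                is_num1(cytoplasm_sd) && cytoplasm_sd >= 0,
              "cytoplasm intensity parameters invalid")
  assert_that(is_num1(cluster_intensity_factor) && cluster_intensity_factor >= 1,
              "cluster_intensity_factor must be >= 1")
  has_clusters <- sum(mix[c("unipolar", "bipolar_asymmetric",
                            "bipolar_symmetric")]) > 0
  if (has_clusters) {
    assert_that(cluster_intensity_factor * cytoplasm_mean >
                  cytoplasm_mean + 2 * cytoplasm_sd,
                paste("cluster_intensity_factor too low: cluster pixels would",
                      "not exceed cytoplasm_mean + 2*cytoplasm_sd"))
  }
  assert_that(is_count(cluster_size_px) && cluster_size_px >= 3,
              "cluster_size_px must be an integer >= 3")
  class_bounds <- list(unipolar = c(0.9, 1),
                       bipolar_asymmetric = c(0.2, 0.9),
                       bipolar_symmetric = c(0, 0.2))
  for (cls in names(class_bounds)) {
    rng <- omega_target_range[[cls]]
    assert_that(!is.null(rng) && length(rng) == 2 && rng[1] <= rng[2] &&
                  rng[1] >= class_bounds[[cls]][1] &&
                  rng[2] <= class_bounds[[cls]][2],
                "omega_target_range for %s must lie within [%g, %g]",
                cls, class_bounds[[cls]][1], class_bounds[[cls]][2])
  }
  assert_that(is_num1(noise_sd) && noise_sd >= 0, "noise_sd must be >= 0")
  assert_that(is_count(abs(seed) + 1), "seed must be an integer")
  structure(list(n_cells = as.integer(n_cells), pattern_mixture = mix,
                 cell_length_px = cell_length_px, cell_width_px = cell_width_px,
                 cytoplasm_mean = cytoplasm_mean, cytoplasm_sd = cytoplasm_sd,
                 cluster_intensity_factor = cluster_intensity_factor,
                 cluster_size_px = as.integer(cluster_size_px),
                 omega_target_range = omega_target_range,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "snapshot_population_spec")
}

#' Specification of a synthetic motility time-lapse
#'
#' Cells glide along their long axis with per-interval speeds drawn from a
#' Gaussian and reverse direction as a Poisson process; at a reversal the
#' leading/lagging identities of the two poles swap instantaneously. Per-pole
#' cluster fluorescence follows `pole_fluorescence_rule`, which by default
#' emulates a lagging-pole protein (bright cluster at the lagging pole, none
#' at the leading pole). The default cadence (30 s frames for 15 min) matches
#' standard gliding-motility imaging.
#'
#' @param n_cells number of cells (one lane each; cells never collide).
#' @param frame_interval_s seconds between frames.
#' @param duration_s total duration in seconds.
#' @param speed_mean,speed_sd per-interval speed distribution (px/interval);
#'   negative draws are truncated at 0.
#' @param reversal_rate expected reversals per cell per minute (Poisson).
#' @param pole_fluorescence_rule named list with elements `leading` and
#'   `lagging`, each `c(mean, sd)` of the per-pixel cluster intensity at that
#'   pole (mean 0 means no cluster).
#' @param cell_length_px,cell_width_px,cytoplasm_mean,cytoplasm_sd,noise_sd,
#'   cluster_size_px image-rendering parameters as in
#'   [snapshot_population_spec()].
#' @param seed integer seed.
#' @return an object of class `track_spec`.
#' @export
track_spec <- function(n_cells,
                       frame_interval_s = 30,
                       duration_s = 900,
                       speed_mean = 8,
                       speed_sd = 1,
                       reversal_rate = 0.2,
                       pole_fluorescence_rule = list(
                         leading = c(mean = 0, sd = 0),
                         lagging = c(mean = 300, sd = 10)),
                       cell_length_px = 40,
                       cell_width_px = 9,
                       cytoplasm_mean = 100,
                       cytoplasm_sd = 8,
                       noise_sd = 4,
                       cluster_size_px = 6,
                       seed = 1L) {
  assert_that(is_count(n_cells), "n_cells must be a positive integer")
  assert_that(is_num1(frame_interval_s) && frame_interval_s > 0,
              "frame_interval_s must be > 0")
  assert_that(is_num1(duration_s) && duration_s >= 2 * frame_interval_s,
              "duration_s must cover at least two intervals")
  assert_that(is_num1(speed_mean) && speed_mean >= 0 &&
                is_num1(speed_sd) && speed_sd >= 0, "invalid speed parameters")
  assert_that(is_num1(reversal_rate) && reversal_rate >= 0,
              "reversal_rate must be >= 0")
  assert_that(is.list(pole_fluorescence_rule) &&
                all(c("leading", "lagging") %in% names(pole_fluorescence_rule)),
              "pole_fluorescence_rule needs 'leading' and 'lagging' entries")
  structure(list(n_cells = as.integer(n_cells),
                 frame_interval_s = frame_interval_s, duration_s = duration_s,
                 speed_mean = speed_mean, speed_sd = speed_sd,
                 reversal_rate = reversal_rate,
                 pole_fluorescence_rule = pole_fluorescence_rule,
                 cell_length_px = cell_length_px, cell_width_px = cell_width_px,
                 cytoplasm_mean = cytoplasm_mean, cytoplasm_sd = cytoplasm_sd,
                 noise_sd = noise_sd, cluster_size_px = as.integer(cluster_size_px),
                 seed = as.integer(seed)),
            class = "track_spec")
}

#' Specification of a synthetic NADH-coupled GTPase assay trace
#'
#' In the regenerative coupled assay each hydrolyzed GTP consumes one NADH
#' (pyruvate kinase / lactate dehydrogenase in excess, so coupling is
#' non-limiting), read as a linear decrease of A340. The generator produces
#' `A340(t) = a340_start - turnover * [E] * eps * l * t/3600 - background_rate * t + noise`.
#'
#' @param enzyme_conc GTPase concentration in uM (assay default 3 uM).
#' @param true_turnover GTP hydrolyzed per enzyme per hour.
#' @param epsilon_340 NADH molar extinction coefficient at 340 nm
#'   (M^-1 cm^-1; default 6220).
#' @param path_length effective optical path in cm (plate-reader wells;
#'   default 0.5).
#' @param a340_start initial absorbance.
#' @param duration_s,sample_interval_s trace duration and sampling cadence in
#'   seconds (default 60 min read every 30 s).
#' @param noise_sd Gaussian absorbance noise per point.
#' @param background_rate non-enzymatic absorbance drift (absorbance/s,
#'   subtracted as the matched no-GTPase control downstream).
#' @param seed integer seed.
#' @return an object of class `coupled_assay_spec`.
#' @export
coupled_assay_spec <- function(enzyme_conc = 3,
                               true_turnover = 2,
                               epsilon_340 = 6220,
                               path_length = 0.5,
                               a340_start = 1.0,
                               duration_s = 3600,
                               sample_interval_s = 30,
                               noise_sd = 0,
                               background_rate = 0,
                               seed = 1L) {
  assert_that(is_num1(enzyme_conc) && enzyme_conc > 0, "enzyme_conc must be > 0")
  assert_that(is_num1(true_turnover) && true_turnover >= 0,
              "true_turnover must be >= 0")
  assert_that(is_num1(epsilon_340) && epsilon_340 > 0 &&
                is_num1(path_length) && path_length > 0,
              "optical parameters must be positive")
  assert_that(is_num1(duration_s) && duration_s > 0 &&
                is_num1(sample_interval_s) && sample_interval_s > 0 &&
                duration_s >= 2 * sample_interval_s, "invalid time base")
  # deterministic end-point check: the noise-free trace must stay >= 0
  drop <- (true_turnover * enzyme_conc * 1e-6 / 3600 * epsilon_340 *
             path_length + background_rate) * duration_s
  assert_that(a340_start - drop >= 0,
              "parameters drive A340 below 0 within the assay duration")
  structure(list(enzyme_conc = enzyme_conc, true_turnover = true_turnover,
                 epsilon_340 = epsilon_340, path_length = path_length,
                 a340_start = a340_start, duration_s = duration_s,
                 sample_interval_s = sample_interval_s, noise_sd = noise_sd,
                 background_rate = background_rate, seed = as.integer(seed)),
            class = "coupled_assay_spec")
}

#' Specification of a synthetic malachite-green endpoint plate
#'
#' Linear colorimetric response: `A590 = intercept + slope * [Pi] + noise`
#' for standards and samples alike.
#'
#' @param standard_concs phosphate standard concentrations (uM), strictly
#'   increasing and including 0 (the blank).
#' @param true_slope absorbance per uM phosphate.
#' @param true_intercept blank absorbance.
#' @param sample_true_pi true phosphate content of the samples (uM).
#' @param noise_sd Gaussian absorbance noise.
#' @param seed integer seed.
#' @return an object of class `malachite_plate_spec`.
#' @export
malachite_plate_spec <- function(standard_concs = c(0, 5, 10, 20, 40, 60, 80, 100),
                                 true_slope = 0.008,
                                 true_intercept = 0.05,
                                 sample_true_pi = numeric(0),
                                 noise_sd = 0,
                                 seed = 1L) {
  assert_that(is.numeric(standard_concs) && length(standard_concs) >= 3 &&
                all(diff(standard_concs) > 0) && standard_concs[1] == 0,
              "standard_concs must be strictly increasing and include 0")
  assert_that(is_num1(true_slope) && true_slope > 0, "true_slope must be > 0")
  assert_that(is.numeric(sample_true_pi) && all(sample_true_pi >= 0),
              "sample_true_pi must be non-negative")
  structure(list(standard_concs = standard_concs, true_slope = true_slope,
                 true_intercept = true_intercept,
                 sample_true_pi = sample_true_pi, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "malachite_plate_spec")
}

#' Specification of a synthetic gene presence/absence matrix
#'
#' Emulates a phylogenomic screen over many genomes: a reference gene has a
#' Bernoulli presence profile, and every other gene matches the reference
#' profile per genome with its own co-occurrence probability (1 = identical
#' profile, 0.5 = uninformative).
#'
#' @param n_genomes number of genomes (rows).
#' @param gene_names character vector of gene (column) names.
#' @param reference_gene the reference; must be in `gene_names`.
#' @param co_occurrence_prob named per-gene probability of matching the
#'   reference profile in a genome (reference itself is ignored); a single
#'   unnamed value is recycled.
#' @param ref_prevalence probability the reference gene is present in a genome.
#' @param seed integer seed.
#' @return an object of class `presence_absence_spec`.
#' @export
presence_absence_spec <- function(n_genomes,
                                  gene_names,
                                  reference_gene,
                                  co_occurrence_prob = 0.5,
                                  ref_prevalence = 0.5,
                                  seed = 1L) {
  assert_that(is_count(n_genomes), "n_genomes must be a positive integer")
  assert_that(is.character(gene_names) && !anyDuplicated(gene_names),
              "gene_names must be unique")
  assert_that(reference_gene %in% gene_names,
              "reference_gene must be one of gene_names")
  others <- setdiff(gene_names, reference_gene)
  if (is.null(names(co_occurrence_prob))) {
    assert_that(length(co_occurrence_prob) == 1L,
                "unnamed co_occurrence_prob must be a single probability")
    co_occurrence_prob <- stats::setNames(rep(co_occurrence_prob, length(others)),
                                          others)
  }
  assert_that(all(others %in% names(co_occurrence_prob)),
              "co_occurrence_prob must cover every non-reference gene")
  co_occurrence_prob <- co_occurrence_prob[others]
  assert_that(all(co_occurrence_prob >= 0 & co_occurrence_prob <= 1) &&
                ref_prevalence >= 0 && ref_prevalence <= 1,
              "probabilities must lie in [0, 1]")
  structure(list(n_genomes = as.integer(n_genomes), gene_names = gene_names,
                 reference_gene = reference_gene,
                 co_occurrence_prob = co_occurrence_prob,
                 ref_prevalence = ref_prevalence, seed = as.integer(seed)),
            class = "presence_absence_spec")
}
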