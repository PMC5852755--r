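#' Default taxon labels for a caecal-like community
#'
#' Twenty genus/family-level labels typical of the mouse caecum, dominated by
#' Lachnospiraceae and other Clostridiales, used by [default_scenario()].
#'
#' @return Character vector of 20 taxon labels.
#' @export
caecal_taxa <- function() {
  c("Lachnospiraceae_uncl", "Clostridiales_uncl", "Ruminococcaceae_uncl",
    "Prevotella", "Dorea", "Bacteroides", "Turicibacter", "Oscillospira",
    "Blautia", "Roseburia", "Papillibacter", "Lactobacillus", "Alistipes",
    "Coprococcus", "Anaerostipes", "Porphyromonadaceae_uncl", "Akkermansia",
    "Desulfovibrio", "Butyricicoccus", "Mucispirillum")
}

#' Construct an RNA-SIP simulation scenario
#'
#' A scenario fully specifies one forward simulation of an RNA-SIP feeding
#' experiment: the community, how much heavy isotope each taxon incorporates at
#' each timepoint, the geometry of the isopycnic gradient, and the measurement
#' layers (amplicon sequencing depth, qPCR noise, metabolite isotopologues).
#'
#' The default gradient geometry follows a CsTFA gradient collected densest
#' first into 15 fractions, the trailing 2 being water and excluded, with the
#' analyzed fractions spanning 1.854 down to 1.757 g/mL linearly. Unlabeled
#' 16S rRNA bands near 1.786 g/mL; full substitution with the heavy isotope
#' shifts a taxon's buoyant density by `delta_rho_max` (default 0.035 g/mL).
#'
#' @param n_taxa Number of taxa.
#' @param baseline_abundances Simplex vector of length `n_taxa` (sums to 1).
#' @param label_atom_fraction Matrix `n_taxa x length(timepoints)` of the
#'   carbon atom fraction each taxon derives from the labeled substrate at
#'   each timepoint; values in \[0, 0.98\] (the substrate is 98% labeled).
#' @param timepoints Ordered character labels, e.g. `c("0h","2h","4h")`.
#' @param n_replicates Technical gradient replicates per timepoint.
#' @param seq_depth Reads per sequenced fraction-sample.
#' @param rho_top,rho_bottom Densities (g/mL) of the lightest and densest
#'   analyzed fractions; `rho_bottom > rho_top`.
#' @param n_fractions Fractions collected per gradient.
#' @param n_excluded Trailing (water) fractions excluded from analysis.
#' @param delta_rho_max Buoyant-density shift (g/mL) at atom fraction 1.
#' @param band_sigma Gaussian band width of a taxon's RNA in density (g/mL).
#' @param qpcr_cv Coefficient of variation of the lognormal noise on
#'   per-fraction total RNA.
#' @param unlabeled_density_mean,unlabeled_density_sd Per-taxon unlabeled
#'   buoyant densities are drawn Normal(mean, sd), truncated to the gradient
#'   range; the spread models GC-content variation.
#' @param label_threshold Atom fraction above which a taxon is recorded as
#'   truly labeled in the simulation ground truth.
#' @param taxa Optional taxon names.
#' @param metabolite_phi Named per-timepoint fraction of metabolite molecules
#'   derived from the labeled substrate (two-pool isotopologue model).
#' @param substrate_atom_fraction Per-carbon heavy-atom probability in
#'   substrate-derived molecules (default 0.98).
#' @param natural_abundance Per-carbon heavy-atom probability in background
#'   molecules (default 0.011).
#' @param n_molecules Molecules sampled per isotopologue measurement.
#' @param seed Integer seed; the simulation is bit-reproducible given the
#'   scenario.
#'
#' @return An object of class `sip_scenario`.
#' @seealso [default_scenario()], [simulate_experiment()]
#' @export
sip_scenario <- function(n_taxa,
                         baseline_abundances,
                         label_atom_fraction,
                         timepoints = c("0h", "2h", "4h"),
                         n_replicates = 3L,
                         seq_depth = 10000L,
                         rho_top = 1.757,
                         rho_bottom = 1.854,
                         n_fractions = 15L,
                         n_excluded = 2L,
                         delta_rho_max = 0.035,
                         band_sigma = 0.008,
                         qpcr_cv = 0.10,
                         unlabeled_density_mean = 1.786,
                         unlabeled_density_sd = 0.002,
                         label_threshold = 0.1,
                         taxa = NULL,
                         metabolite_phi = NULL,
                         substrate_atom_fraction = 0.98,
                         natural_abundance = 0.011,
                         n_molecules = 1e5,
                         seed = 1L) {
  n_taxa <- as.integer(n_taxa)
  stopifnot(n_taxa >= 1L)
  if (length(baseline_abundances) != n_taxa)
    stop("baseline_abundances must have length n_taxa")
  if (any(baseline_abundances < 0))
    stop("baseline_abundances must be nonnegative")
  if (abs(sum(baseline_abundances) - 1) > 1e-9)
    stop("baseline_abundances must sum to 1 (tolerance 1e-9)")
  label_atom_fraction <- as.matrix(label_atom_fraction)
  if (!all(dim(label_atom_fraction) == c(n_taxa, length(timepoints))))
    stop("label_atom_fraction must be an n_taxa x n_timepoints matrix")
  if (any(label_atom_fraction < 0) || any(label_atom_fraction > 0.98))
    stop("label_atom_fraction values must lie in [0, 0.98]")
  if (!(rho_bottom > rho_top)) stop("rho_bottom must exceed rho_top")
  n_fractions <- as.integer(n_fractions)
  n_excluded <- as.integer(n_excluded)
  if (n_excluded >= n_fractions) stop("n_excluded must be < n_fractions")
  if (band_sigma <= 0) stop("band_sigma must be positive")
  if (delta_rho_max < 0) stop("delta_rho_max must be nonnegative")
  if (qpcr_cv < 0) stop("qpcr_cv must be nonnegative")
  if (is.null(taxa)) taxa <- sprintf("taxon_%02d", seq_len(n_taxa))
  if (length(taxa) != n_taxa || anyDuplicated(taxa))
    stop("taxa must be n_taxa unique names")
  if (is.null(metabolite_phi)) {
    metabolite_phi <- stats::setNames(rep(0, length(timepoints)), timepoints)
  }
  if (is.null(names(metabolite_phi)) ||
      !setequal(names(metabolite_phi), timepoints))
    stop("metabolite_phi must be named by timepoint")
  if (any(metabolite_phi < 0) || any(metabolite_phi > 1))
    stop("metabolite_phi values must lie in [0, 1]")
  colnames(label_atom_fraction) <- timepoints
  rownames(label_atom_fraction) <- taxa
  structure(list(
    n_taxa = n_taxa,
    taxa = taxa,
    baseline_abundances = stats::setNames(as.numeric(baseline_abundances), taxa),
    label_atom_fraction = label_atom_fraction,
    timepoints = timepoints,
    n_replicates = as.integer(n_replicates),
    seq_depth = as.integer(seq_depth),
    rho_top = rho_top,
    rho_bottom = rho_bottom,
    n_fractions = n_fractions,
    n_excluded = n_excluded,
    delta_rho_max = delta_rho_max,
    band_sigma = band_sigma,
    qpcr_cv = qpcr_cv,
    unlabeled_density_mean = unlabeled_density_mean,
    unlabeled_density_sd = unlabeled_density_sd,
    label_threshold = label_threshold,
    metabolite_phi = metabolite_phi[timepoints],
    substrate_atom_fraction = substrate_atom_fraction,
    natural_abundance = natural_abundance,
    n_molecules = n_molecules,
    seed = as.integer(seed)
  ), class = "sip_scenario")
}

#' Default study-like scenario
#'
#' Emulates the study conditions: a 20-taxon caecal-like community with a
#' geometric rank-abundance curve (ratio 0.9, every taxon above 1.5%
#' baseline abundance), three timepoints (0h/2h/4h), three gradient
#' replicates, and five labeled taxa that reach atom fraction 0.25 at 2h and
#' 0.5 at 4h. Metabolite labeling follows the same time course
#' (substrate-derived molecule fraction 0, 0.25, 0.5).
#'
#' @param n_labeled Number of labeled taxa (taken from ranks 2, 4, 6, ...).
#' @param atom_fraction_test Atom fraction of labeled taxa at the final
#'   timepoint (half that at the middle timepoint).
#' @param seed Integer seed.
#' @param ... Overrides passed on to [sip_scenario()].
#' @return A `sip_scenario`.
#' @export
default_scenario <- function(n_labeled = 5L, atom_fraction_test = 0.5,
                             seed = 1L, ...) {
  n_taxa <- 20L
  ab <- 0.9 ^ (seq_len(n_taxa) - 1)
  ab <- ab / sum(ab)
  tp <- c("0h", "2h", "4h")
  laf <- matrix(0, n_taxa, 3L)
  labeled <- seq(2L, by = 2L, length.out = n_labeled)
  laf[labeled, 2L] <- atom_fraction_test / 2
  laf[labeled, 3L] <- atom_fraction_test
  sip_scenario(
    n_taxa = n_taxa,
    baseline_abundances = ab,
    label_atom_fraction = laf,
    timepoints = tp,
    taxa = caecal_taxa(),
    metabolite_phi = c("0h" = 0, "2h" = 0.25, "4h" = 0.5),
    seed = seed,
    ...
  )
}

#' @export
print.sip_scenario <- function(x, ...) {
  cat("RNA-SIP scenario:", x$n_taxa, "taxa,",
      length(x$timepoints), "timepoints x", x$n_replicates, "replicates\n")
  cat("  gradient:", x$n_fractions, "fractions (", x$n_excluded,
      "excluded ), density", x$rho_bottom, "->", x$rho_top, "g/mL\n")
  n_lab <- sum(apply(x$label_atom_fraction, 1, max) > x$label_threshold)
  cat("  labeled taxa:", n_lab, "| delta_rho_max:", x$delta_rho_max,
      "g/mL | band sigma:", x$band_sigma, "\n")
  invisible(x)
}

# Run code with a private, restored RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}
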