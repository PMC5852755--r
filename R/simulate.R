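#' Density grid of the analyzed gradient fractions
#'
#' Fraction 1 is the densest (collection order). Fraction centre densities
#' decrease linearly from `rho_bottom` (fraction 1) to `rho_top` (last
#' analyzed fraction); each fraction integrates RNA mass over an equal-width
#' density interval centred on its density. Excluded trailing (water)
#' fractions continue the linear spacing but carry no analyzable RNA.
#'
#' @param scenario A `sip_scenario`.
#' @return Data frame with columns `fraction`, `density`, `lower`, `upper`,
#'   `analyzed`.
#' @export
fraction_density_grid <- function(scenario) {
  n_an <- scenario$n_fractions - scenario$n_excluded
  step <- (scenario$rho_bottom - scenario$rho_top) / (n_an - 1)
  dens <- scenario$rho_bottom - (seq_len(scenario$n_fractions) - 1) * step
  data.frame(
    fraction = seq_len(scenario$n_fractions),
    density = dens,
    lower = dens - step / 2,
    upper = dens + step / 2,
    analyzed = seq_len(scenario$n_fractions) <= n_an
  )
}

# Per-taxon RNA mass in each analyzed fraction: Gaussian band centred on the
# taxon's buoyant density, integrated over each fraction's density interval,
# scaled by baseline abundance. Rows taxa, columns analyzed fractions.
taxon_fraction_mass <- function(centers, abundances, grid, band_sigma) {
  an <- grid[grid$analyzed, ]
  m <- vapply(seq_len(nrow(an)), function(j) {
    abundances * (stats::pnorm(an$upper[j], centers, band_sigma) -
                  stats::pnorm(an$lower[j], centers, band_sigma))
  }, numeric(length(centers)))
  m <- matrix(m, nrow = length(centers))
  colnames(m) <- an$fraction
  m
}

#' Expected per-fraction RNA mass profile of a scenario
#'
#' The noise-free forward model: per taxon, the Gaussian band centred on its
#' buoyant density at the given timepoint, integrated over each analyzed
#' fraction's density interval and scaled by baseline abundance. Community
#' mass banding outside the gradient range is returned as the `spillover`
#' attribute.
#'
#' @param scenario A `sip_scenario`.
#' @param timepoint Timepoint label.
#' @param unlabeled_densities Per-taxon unlabeled buoyant densities; by
#'   default every taxon sits at `unlabeled_density_mean` (no spread), which
#'   makes the profile deterministic.
#' @return Taxa x analyzed-fractions matrix of expected RNA mass (total
#'   community mass is 1 minus spillover), with attribute `spillover`.
#' @export
expected_fraction_profile <- function(scenario, timepoint,
                                      unlabeled_densities = NULL) {
  stopifnot(inherits(scenario, "sip_scenario"),
            timepoint %in% scenario$timepoints)
  if (is.null(unlabeled_densities))
    unlabeled_densities <- rep(scenario$unlabeled_density_mean,
                               scenario$n_taxa)
  grid <- fraction_density_grid(scenario)
  centers <- unlabeled_densities +
    scenario$label_atom_fraction[, timepoint] * scenario$delta_rho_max
  m <- taxon_fraction_mass(centers, scenario$baseline_abundances, grid,
                           scenario$band_sigma)
  rownames(m) <- scenario$taxa
  attr(m, "spillover") <- 1 - sum(m)
  m
}

#' Forward-simulate a complete RNA-SIP experiment
#'
#' Simulates, with known ground truth, every measured layer of an RNA-SIP
#' feeding experiment:
#' \itemize{
#'   \item per-taxon buoyant densities: unlabeled density drawn
#'     Normal(`unlabeled_density_mean`, `unlabeled_density_sd`) truncated to
#'     the gradient range, shifted by `atom_fraction * delta_rho_max` at each
#'     timepoint;
#'   \item per-fraction RNA mass: Gaussian band (sd `band_sigma`) integrated
#'     over each fraction's density interval, scaled by baseline abundance;
#'   \item qPCR totals: per-fraction summed mass times lognormal noise with
#'     coefficient of variation `qpcr_cv` (one gradient per timepoint and
#'     replicate);
#'   \item amplicon counts: multinomial draws of `seq_depth` reads per
#'     analyzed fraction of gradient replicate 1 at each timepoint;
#'   \item a random phylogeny over the taxa (exponential branch lengths);
#'   \item two-mass metabolite isotopologue intensities per timepoint for
#'     acetate, butyrate and lactate.
#' }
#'
#' The simulation is bit-reproducible: identical scenarios (including the
#' seed) give identical datasets.
#'
#' @param scenario A [sip_scenario()].
#' @return An object of class `sip_dataset`: a list with elements
#'   `gradients` (list of `sip_gradient`), `feature_table` (taxa x samples
#'   integer matrix), `metadata` (one row per feature-table column),
#'   `tree` (`phylo`), `isotopologues` (data frame), `truth` (data frame with
#'   per-taxon, per-timepoint atom fraction, buoyant density and labeled
#'   flag) and `scenario`.
#' @export
simulate_experiment <- function(scenario) {
  stopifnot(inherits(scenario, "sip_scenario"))
  if (scenario$band_sigma <= 0) stop("band_sigma must be positive")
  if (scenario$delta_rho_max < 0) stop("delta_rho_max must be nonnegative")
  grid <- fraction_density_grid(scenario)
  with_seed(scenario$seed, {
    # unlabeled buoyant densities, truncated to the analyzed density range
    centers0 <- numeric(scenario$n_taxa)
    for (i in seq_len(scenario$n_taxa)) {
      repeat {
        d <- stats::rnorm(1, scenario$unlabeled_density_mean,
                          scenario$unlabeled_density_sd)
        if (d >= scenario$rho_top && d <= scenario$rho_bottom) break
      }
      centers0[i] <- d
    }
    names(centers0) <- scenario$taxa

    truth <- do.call(rbind, lapply(scenario$timepoints, function(tp) {
      af <- scenario$label_atom_fraction[, tp]
      data.frame(
        taxon = scenario$taxa,
        timepoint = tp,
        atom_fraction = unname(af),
        unlabeled_density = unname(centers0),
        buoyant_density_mean = unname(centers0 + af * scenario$delta_rho_max),
        is_labeled = unname(af > scenario$label_threshold),
        row.names = NULL
      )
    }))

    sdlog <- sqrt(log(1 + scenario$qpcr_cv^2))
    gradients <- list()
    counts <- list()
    meta <- list()
    for (tp in scenario$timepoints) {
      af <- scenario$label_atom_fraction[, tp]
      centers <- centers0 + af * scenario$delta_rho_max
      mass <- taxon_fraction_mass(centers, scenario$baseline_abundances,
                                  grid, scenario$band_sigma)
      spill <- 1 - sum(mass)  # community mass banding outside the gradient
      for (rep_i in seq_len(scenario$n_replicates)) {
        totals <- colSums(mass) *
          stats::rlnorm(ncol(mass), meanlog = -sdlog^2 / 2, sdlog = sdlog)
        conc <- numeric(scenario$n_fractions)
        conc[grid$analyzed] <- totals
        g <- as_gradient(
          data.frame(fraction = grid$fraction, density = grid$density,
                     rna_concentration = conc),
          timepoint = tp, replicate = rep_i,
          n_excluded = scenario$n_excluded
        )
        attr(g, "spillover") <- spill
        gradients[[paste(tp, rep_i, sep = "_r")]] <- g
      }
      # amplicon sequencing of the analyzed fractions of replicate 1
      for (f in which(grid$analyzed)) {
        p <- mass[, f]
        cnt <- as.integer(stats::rmultinom(1, scenario$seq_depth, p))
        sample_id <- sprintf("%s_F%02d", tp, f)
        counts[[sample_id]] <- cnt
        meta[[sample_id]] <- data.frame(
          sample = sample_id, timepoint = tp, fraction = f,
          replicate = 1L, density = grid$density[f],
          stringsAsFactors = FALSE
        )
      }
    }
    feature_table <- do.call(cbind, counts)
    rownames(feature_table) <- scenario$taxa
    metadata <- do.call(rbind, meta)
    rownames(metadata) <- NULL
    n_an <- scenario$n_fractions - scenario$n_excluded
    wm <- window_map(heavy = 5:7, light = 8:10, n_fractions = n_an)
    metadata$density_class <- wm[as.character(metadata$fraction)]
    metadata$density_class[is.na(metadata$density_class)] <- "unassigned"

    tree <- simulate_tree(scenario$n_taxa, tip_labels = scenario$taxa)

    iso <- do.call(rbind, lapply(scenario$timepoints, function(tp) {
      phi <- scenario$metabolite_phi[[tp]]
      do.call(rbind, lapply(names(scfa_fragments()), function(cmp) {
        fr <- scfa_fragments()[[cmp]]
        m <- simulate_isotopologues(
          atom_fraction = scenario$substrate_atom_fraction,
          n_carbons = fr$n_carbons,
          natural_abundance = scenario$natural_abundance,
          n_molecules = scenario$n_molecules,
          phi = phi
        )
        data.frame(timepoint = tp, compound = cmp,
                   fragment_pair = fr$fragment_pair,
                   i12 = m$i12, i13 = m$i13, phi = phi,
                   stringsAsFactors = FALSE)
      }))
    }))
    rownames(iso) <- NULL

    structure(list(
      gradients = gradients,
      feature_table = feature_table,
      metadata = metadata,
      tree = tree,
      isotopologues = iso,
      truth = truth,
      scenario = scenario
    ), class = "sip_dataset")
  })
}

#' @export
print.sip_dataset <- function(x, ...) {
  cat("RNA-SIP simulated dataset:", nrow(x$feature_table), "taxa x",
      ncol(x$feature_table), "fraction-samples;",
      length(x$gradients), "gradients\n")
  cat("  timepoints:", paste(x$scenario$timepoints, collapse = ", "),
      "| truly labeled taxa:",
      length(unique(x$truth$taxon[x$truth$is_labeled])), "\n")
  invisible(x)
}

#' GC-MS fragment pairs monitored for the fermentation acids
#'
#' Mass pairs of the t-butyl-dimethyl-silyl derivatives used for two-mass
#' isotopologue ratios: acetate M-119/117 (2 carbons), butyrate M-147/145
#' (4 carbons), lactate M-119/117 (3 carbons).
#'
#' @return Named list with `n_carbons` and `fragment_pair` per compound.
#' @export
scfa_fragments <- function() {
  list(
    acetate  = list(n_carbons = 2L, fragment_pair = "M-119/117"),
    butyrate = list(n_carbons = 4L, fragment_pair = "M-147/145"),
    lactate  = list(n_carbons = 3L, fragment_pair = "M-119/117")
  )
}

#' Simulate a two-mass isotopologue measurement
#'
#' Two-pool model: a molecule is substrate-derived with probability `phi`
#' (each of its `n_carbons` carbons is heavy independently with probability
#' `atom_fraction`), otherwise background (heavy with probability
#' `natural_abundance`). The measurement records the intensities of the
#' unlabeled-mass peak (molecules with zero heavy carbons, `i12`) and the
#' fully-labeled-mass peak (all carbons heavy, `i13`), as monitored in
#' two-mass GC-MS ratios.
#'
#' @param atom_fraction Per-carbon heavy probability in substrate-derived
#'   molecules, in \[0, 1\].
#' @param n_carbons Carbons in the monitored fragment (>= 1).
#' @param natural_abundance Per-carbon heavy probability in background
#'   molecules.
#' @param n_molecules Number of molecules sampled.
#' @param phi Fraction of molecules that are substrate-derived, in \[0, 1\].
#' @param seed Optional integer seed (RNG state is restored).
#' @return List with `i12`, `i13`, `n_other` (molecules at intermediate
#'   masses, not monitored), and the inputs.
#' @export
simulate_isotopologues <- function(atom_fraction, n_carbons,
                                   natural_abundance, n_molecules,
                                   phi, seed = NULL) {
  if (n_carbons < 1) stop("n_carbons must be >= 1")
  stopifnot(atom_fraction >= 0, atom_fraction <= 1,
            natural_abundance >= 0, natural_abundance <= 1,
            phi >= 0, phi <= 1, n_molecules >= 1)
  draw <- function() {
    n_sub <- stats::rbinom(1, n_molecules, phi)
    n_bg <- n_molecules - n_sub
    pool <- function(n, a) {
      if (n == 0) return(c(0L, 0L))
      p0 <- (1 - a)^n_carbons
      pn <- a^n_carbons
      cnt <- stats::rmultinom(1, n, c(p0, pn, max(0, 1 - p0 - pn)))
      c(cnt[1L], cnt[2L])
    }
    s <- pool(n_sub, atom_fraction)
    b <- pool(n_bg, natural_abundance)
    list(i12 = s[1L] + b[1L], i13 = s[2L] + b[2L],
         n_other = n_molecules - (s[1L] + b[1L] + s[2L] + b[2L]),
         atom_fraction = atom_fraction, n_carbons = n_carbons,
         natural_abundance = natural_abundance, phi = phi,
         n_molecules = n_molecules)
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Simulate a random phylogeny over the community
#'
#' Random topology with independent unit-exponential branch lengths; used for
#' phylogenetic-diversity computations on simulated data.
#'
#' @param n_taxa Number of tips.
#' @param tip_labels Optional tip labels (length `n_taxa`).
#' @param seed Optional integer seed (RNG state restored); if `NULL`, draws
#'   from the current RNG stream.
#' @return A rooted `phylo` object.
#' @export
simulate_tree <- function(n_taxa, tip_labels = NULL, seed = NULL) {
  draw <- function() {
    tr <- ape::rtree(n_taxa, rooted = TRUE, br = stats::rexp)
    if (!is.null(tip_labels)) {
      # rtree labels tips t1..tn in random order; map onto our taxa by index
      idx <- as.integer(sub("^t", "", tr$tip.label))
      tr$tip.label <- tip_labels[idx]
    }
    tr
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}
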