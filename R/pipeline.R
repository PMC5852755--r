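#' Write a simulated dataset to plain-text files
#'
#' Emits the standard interchange formats: feature table TSV (taxa rows,
#' sample columns), metadata TSV, long gradient TSV, newick tree,
#' isotopologue CSV and ground-truth JSON.
#'
#' @param dataset A `sip_dataset`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of written paths.
#' @export
write_sip_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "sip_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    feature_table = file.path(dir, "feature_table.tsv"),
    metadata = file.path(dir, "metadata.tsv"),
    gradients = file.path(dir, "gradients.tsv"),
    tree = file.path(dir, "tree.nwk"),
    isotopologues = file.path(dir, "isotopologues.csv"),
    truth = file.path(dir, "truth.json")
  )
  ft <- data.frame(taxon = rownames(dataset$feature_table),
                   dataset$feature_table, check.names = FALSE)
  utils::write.table(ft, paths["feature_table"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(dataset$metadata, paths["metadata"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  gl <- do.call(rbind, lapply(dataset$gradients, function(g) {
    data.frame(timepoint = attr(g, "timepoint"),
               replicate = attr(g, "replicate"),
               fraction = g$fraction, density_g_per_ml = g$density,
               rna_conc = g$rna_concentration, analyzed = g$analyzed,
               stringsAsFactors = FALSE)
  }))
  utils::write.table(gl, paths["gradients"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  ape::write.tree(dataset$tree, paths["tree"])
  utils::write.csv(dataset$isotopologues, paths["isotopologues"],
                   row.names = FALSE, quote = FALSE)
  jsonlite::write_json(dataset$truth, paths["truth"], digits = NA)
  invisible(paths)
}

#' Read a feature table written by [write_sip_dataset()]
#' @param path TSV path (first column `taxon`, remaining columns samples).
#' @return Taxa x samples numeric matrix.
#' @export
read_feature_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1L]]
  m
}

#' Read a sample-metadata TSV
#' @param path TSV path with columns `sample`, `timepoint`, `fraction`,
#'   `replicate`, `density`, `density_class`.
#' @return Data frame.
#' @export
read_sample_metadata <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Read a long gradient TSV into `sip_gradient` objects
#' @param path TSV with columns `timepoint`, `replicate`, `fraction`,
#'   `density_g_per_ml`, `rna_conc` (and optionally `analyzed`).
#' @return Named list of `sip_gradient` objects.
#' @export
read_gradient_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  keys <- unique(df[, c("timepoint", "replicate")])
  out <- list()
  for (i in seq_len(nrow(keys))) {
    sub <- df[df$timepoint == keys$timepoint[i] &
                df$replicate == keys$replicate[i], ]
    n_exc <- if ("analyzed" %in% names(sub)) sum(!sub$analyzed) else 0L
    g <- as_gradient(
      data.frame(fraction = sub$fraction, density = sub$density_g_per_ml,
                 rna_concentration = sub$rna_conc),
      timepoint = keys$timepoint[i], replicate = keys$replicate[i],
      n_excluded = n_exc)
    out[[paste(keys$timepoint[i], keys$replicate[i], sep = "_r")]] <- g
  }
  out
}

#' Run the full RNA-SIP analysis over a simulated experiment
#'
#' Orchestrates the stages in order — simulate, gradient characterization
#' and window classification, labeled-taxon identification per test
#' timepoint, per-sample phylogenetic diversity, metabolite enrichment —
#' and returns one report. Identical configurations give identical reports.
#'
#' @param config Named list (or path to a YAML file with the same keys):
#'   \describe{
#'     \item{scenario}{A `sip_scenario`, or a list of arguments to
#'       [sip_scenario()]; absent entries fall back to
#'       [default_scenario()].}
#'     \item{baseline_timepoint, test_timepoints}{Timepoint labels
#'       (defaults: first timepoint; all later ones).}
#'     \item{window_policy}{`"fixed"` (default) or `"auto"`.}
#'     \item{alpha, trend, n_perm, mode, alternative}{Labeling-test
#'       settings (defaults 0.05, 0.10, 2000, `"montecarlo"`,
#'       `"greater"`).}
#'     \item{rarefaction_depth, rarefaction_iterations}{Diversity settings
#'       (defaults: minimum sample total; 10).}
#'     \item{seed}{Analysis seed for permutations and rarefaction
#'       (default: scenario seed + 1).}
#'     \item{out_dir}{If set, dataset and result tables are written there.}
#'   }
#' @return List of class `sip_report`: `config`, `dataset`, `window_map`,
#'   `gradient_summary`, `labeling` (one data frame per test timepoint),
#'   `diversity`, `metabolites`, `recovery` (against simulation truth) and
#'   `warnings`.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs requires the yaml package")
    config <- yaml::read_yaml(config)
  }
  warns <- character()
  scen <- config$scenario
  if (is.null(scen)) scen <- default_scenario()
  if (!inherits(scen, "sip_scenario")) scen <- do.call(sip_scenario, scen)
  baseline <- config$baseline_timepoint %||% scen$timepoints[1L]
  tests <- config$test_timepoints %||% setdiff(scen$timepoints, baseline)
  alpha <- config$alpha %||% 0.05
  trend <- config$trend %||% 0.10
  n_perm <- config$n_perm %||% 2000L
  mode <- config$mode %||% "montecarlo"
  alternative <- config$alternative %||% "greater"
  seed <- config$seed %||% (scen$seed + 1L)

  dataset <- simulate_experiment(scen)

  # gradient stage: relative RNA, windows from the baseline control
  dataset$gradients <- lapply(dataset$gradients, relative_rna_distribution)
  control <- dataset$gradients[[paste(baseline, 1L, sep = "_r")]]
  wm <- if (identical(config$window_policy, "auto")) {
    classify_fractions(control, policy = "auto")
  } else {
    classify_fractions(control, policy = "fixed")
  }
  dataset$metadata$density_class <-
    unname(wm[as.character(dataset$metadata$fraction)])
  gradient_summary <- do.call(rbind, lapply(dataset$gradients, function(g) {
    lin <- gradient_linearity(g)
    data.frame(timepoint = attr(g, "timepoint"),
               replicate = attr(g, "replicate"),
               peak_fraction = peak_fraction(g),
               r_squared = lin$r_squared,
               spillover = attr(g, "spillover") %||% NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(gradient_summary) <- NULL

  labeling <- lapply(stats::setNames(tests, tests), function(tp) {
    identify_labeled_taxa(dataset$feature_table, dataset$metadata,
                          baseline_timepoint = baseline, test_timepoint = tp,
                          alpha = alpha, trend = trend, n_perm = n_perm,
                          seed = seed + match(tp, scen$timepoints) * 1000L,
                          mode = mode, alternative = alternative)
  })
  for (tp in tests) {
    exc <- labeling[[tp]]$taxon[labeling[[tp]]$class == "baseline_excluded"]
    if (length(exc))
      warns <- c(warns, paste0("baseline-excluded at ", tp, ": ",
                               paste(exc, collapse = ", ")))
  }

  depth <- config$rarefaction_depth %||% min(colSums(dataset$feature_table))
  diversity <- pd_by_sample(dataset$feature_table, dataset$tree,
                            depth = depth,
                            n_iter = config$rarefaction_iterations %||% 10L,
                            seed = seed + 5000L)

  iso <- dataset$isotopologues
  iso$atom_pct <- atom_percent(iso$i12, iso$i13)
  base_iso <- iso[iso$timepoint == baseline, c("compound", "atom_pct")]
  metab <- do.call(rbind, lapply(tests, function(tp) {
    e <- iso[iso$timepoint == tp, ]
    b <- base_iso$atom_pct[match(e$compound, base_iso$compound)]
    cbind(timepoint = tp,
          atom_percent_excess(e$atom_pct, b, compound = e$compound))
  }))
  rownames(metab) <- NULL

  recovery <- do.call(rbind, lapply(tests, function(tp) {
    cbind(timepoint = tp,
          evaluate_recovery(labeling[[tp]], dataset$truth, timepoint = tp))
  }))

  report <- list(
    config = list(scenario = scen, baseline_timepoint = baseline,
                  test_timepoints = tests, alpha = alpha, trend = trend,
                  n_perm = n_perm, mode = mode, alternative = alternative,
                  rarefaction_depth = depth, seed = seed),
    dataset = dataset, window_map = wm,
    gradient_summary = gradient_summary, labeling = labeling,
    diversity = diversity, metabolites = metab, recovery = recovery,
    warnings = warns
  )
  class(report) <- "sip_report"
  if (!is.null(config$out_dir)) write_sip_report(report, config$out_dir)
  report
}

#' @export
print.sip_report <- function(x, ...) {
  cat("RNA-SIP pipeline report\n")
  cat("  baseline:", x$config$baseline_timepoint, "| test:",
      paste(x$config$test_timepoints, collapse = ", "), "\n")
  hv <- attr(x$window_map, "heavy"); lt <- attr(x$window_map, "light")
  cat("  windows: heavy", paste(range(hv), collapse = "-"),
      "| light", paste(range(lt), collapse = "-"), "\n")
  for (tp in names(x$labeling)) {
    lab <- x$labeling[[tp]]
    cat(sprintf("  %s: %d labeled, %d trend, %d baseline-excluded of %d taxa\n",
                tp, sum(lab$class == "labeled"), sum(lab$class == "trend"),
                sum(lab$class == "baseline_excluded"), nrow(lab)))
  }
  if (length(x$warnings)) cat("  warnings:", length(x$warnings), "\n")
  invisible(x)
}

#' Write pipeline result tables
#'
#' @param report A `sip_report`.
#' @param dir Output directory.
#' @return Invisibly, the directory.
#' @export
write_sip_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_sip_dataset(report$dataset, file.path(dir, "dataset"))
  for (tp in names(report$labeling))
    utils::write.table(report$labeling[[tp]],
                       file.path(dir, paste0("labeling_", tp, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(report$diversity, file.path(dir, "diversity.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(report$metabolites, file.path(dir, "metabolites.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(report$gradient_summary,
                     file.path(dir, "gradient_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(window_map = as.list(report$window_map),
         recovery = report$recovery, warnings = report$warnings),
    file.path(dir, "summary.json"), digits = NA, auto_unbox = TRUE)
  invisible(dir)
}

#' Compare labeling calls with simulation ground truth
#'
#' Two detection measures are reported, because the baseline-exclusion rule
#' deliberately trades sensitivity for specificity:
#' \itemize{
#'   \item `power`: the fraction of truly labeled taxa *flagged at the
#'     trend threshold* by the permutation test at the test timepoint
#'     (heavy above light and p <= trend), before baseline exclusion — the
#'     detection power of the test itself;
#'   \item `sensitivity`: the fraction of truly labeled taxa in the final
#'     `labeled`/`trend` call set, i.e. after taxa already heavy-enriched
#'     at baseline (e.g. through buoyant-density differences unrelated to
#'     labeling) have been excluded.
#' }
#' The false discovery rate is the fraction of final calls that are not
#' truly labeled; baseline-excluded taxa are not calls.
#'
#' @param labeling A [identify_labeled_taxa()] result.
#' @param truth Truth data frame from a `sip_dataset`.
#' @param timepoint Timepoint of the truth to compare against.
#' @return One-row data frame: `n_true`, `n_called`, `tp`, `fp`,
#'   `power`, `sensitivity`, `fdr`, `n_baseline_excluded`.
#' @export
evaluate_recovery <- function(labeling, truth, timepoint) {
  tr <- truth[truth$timepoint == timepoint, ]
  truly <- tr$taxon[tr$is_labeled]
  pars <- attr(labeling, "parameters")
  trend <- if (is.null(pars)) 0.10 else pars$trend
  flagged <- labeling$taxon[labeling$direction & labeling$p_perm <= trend]
  called <- labeling$taxon[labeling$class %in% c("labeled", "trend")]
  tp_n <- length(intersect(called, truly))
  fp_n <- length(setdiff(called, truly))
  data.frame(
    n_true = length(truly), n_called = length(called),
    tp = tp_n, fp = fp_n,
    power = if (length(truly))
      length(intersect(flagged, truly)) / length(truly) else NA_real_,
    sensitivity = if (length(truly)) tp_n / length(truly) else NA_real_,
    fdr = if (length(called)) fp_n / length(called) else 0,
    n_baseline_excluded = sum(labeling$class == "baseline_excluded"),
    stringsAsFactors = FALSE
  )
}

#' Write a small packaged test dataset
#'
#' Simulates a compact experiment (20 taxa, 3 timepoints, 3 replicates,
#' modest depth) and writes it under `dir` in the standard plain-text
#' formats, together with its ground truth.
#'
#' @param seed Integer seed.
#' @param dir Output directory.
#' @return Invisibly, the written paths (see [write_sip_dataset()]).
#' @export
make_fixtures <- function(seed = 1L, dir = tempfile("sip_fixtures_")) {
  ds <- simulate_experiment(default_scenario(seed = seed, seq_depth = 2000L))
  write_sip_dataset(ds, dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
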