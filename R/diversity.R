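#' Faith's phylogenetic diversity
#'
#' Sum of the branch lengths of the minimal subtree connecting the observed
#' taxa. With `include_root = TRUE` (the "PD whole tree" convention, the
#' default) the subtree is anchored at the root, so the shared path from the
#' root down to the taxa's most recent common ancestor is counted; with
#' `FALSE` only the spanning subtree of the tips is summed.
#'
#' @param taxa_present Character vector of tip labels observed in the sample.
#' @param tree Rooted `phylo` object with branch lengths.
#' @param include_root Anchor the subtree at the root?
#' @return Branch-length sum (numeric scalar).
#' @export
faiths_pd <- function(taxa_present, tree, include_root = TRUE) {
  stopifnot(inherits(tree, "phylo"), !is.null(tree$edge.length))
  taxa_present <- unique(as.character(taxa_present))
  if (length(taxa_present) == 0L) stop("taxa_present must be nonempty")
  tip_idx <- match(taxa_present, tree$tip.label)
  if (anyNA(tip_idx))
    stop("unknown tip name(s): ",
         paste(taxa_present[is.na(tip_idx)], collapse = ", "))
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  parent_of <- integer(max(tree$edge))
  parent_of[tree$edge[, 2L]] <- tree$edge[, 1L]
  # count, per node, how many of the present tips pass through it on the
  # way to the root; an edge is in the union of root paths iff its child
  # node has a positive count
  pass <- integer(max(tree$edge))
  for (tip in tip_idx) {
    node <- tip
    while (node != root) {
      pass[node] <- pass[node] + 1L
      node <- parent_of[node]
    }
  }
  child <- tree$edge[, 2L]
  keep <- pass[child] > 0L
  if (!include_root) keep <- keep & pass[child] < length(tip_idx)
  sum(tree$edge.length[keep])
}

#' Rarefied Faith's phylogenetic diversity
#'
#' Classical rarefaction: each iteration subsamples `depth` reads without
#' replacement from the sample's counts and computes [faiths_pd()] on the
#' taxa that received at least one read; the mean and standard deviation
#' over iterations are returned.
#'
#' @param counts Named nonnegative integer vector of per-taxon reads; names
#'   must match tree tips.
#' @param tree Rooted `phylo` object.
#' @param depth Rarefaction depth (reads); must not exceed `sum(counts)`.
#' @param n_iter Number of rarefaction iterations (default 10).
#' @param seed Optional integer seed (RNG state restored).
#' @param include_root Passed to [faiths_pd()].
#' @return List of class `pd_result`: `depth`, `n_iterations`, `pd_mean`,
#'   `pd_sd`, `pd_values`.
#' @export
rarefied_pd <- function(counts, tree, depth, n_iter = 10L, seed = NULL,
                        include_root = TRUE) {
  stopifnot(!is.null(names(counts)), all(counts >= 0))
  counts <- round(counts)
  total <- sum(counts)
  if (depth > total)
    stop("rarefaction depth (", depth, ") exceeds sample total (", total, ")")
  run <- function() {
    vapply(seq_len(n_iter), function(i) {
      drawn <- sample(rep.int(seq_along(counts), counts), depth)
      present <- names(counts)[tabulate(drawn, length(counts)) > 0L]
      faiths_pd(present, tree, include_root = include_root)
    }, numeric(1L))
  }
  vals <- if (is.null(seed)) run() else with_seed(seed, run())
  structure(list(depth = as.integer(depth), n_iterations = as.integer(n_iter),
                 pd_mean = mean(vals), pd_sd = stats::sd(vals),
                 pd_values = vals),
            class = "pd_result")
}

#' @export
print.pd_result <- function(x, ...) {
  cat(sprintf("Faith's PD: %.4g +/- %.4g (depth %d, %d iterations)\n",
              x$pd_mean, x$pd_sd, x$depth, x$n_iterations))
  invisible(x)
}

#' Rarefied PD for every sample of a feature table
#'
#' @param table Taxa x samples count matrix; row names must match tree tips.
#' @param tree Rooted `phylo` object.
#' @param depth Rarefaction depth; defaults to the minimum sample total.
#' @param n_iter,seed,include_root Passed to [rarefied_pd()]; with a seed,
#'   each sample receives its own derived seed.
#' @return Data frame with one row per sample: `sample`, `depth`,
#'   `n_iterations`, `pd_mean`, `pd_sd`.
#' @export
pd_by_sample <- function(table, tree, depth = NULL, n_iter = 10L,
                         seed = NULL, include_root = TRUE) {
  table <- as.matrix(table)
  if (is.null(depth)) depth <- min(colSums(table))
  res <- lapply(seq_len(ncol(table)), function(j) {
    s <- if (is.null(seed)) NULL else seed + j
    r <- rarefied_pd(stats::setNames(table[, j], rownames(table)), tree,
                     depth = depth, n_iter = n_iter, seed = s,
                     include_root = include_root)
    data.frame(sample = colnames(table)[j], depth = r$depth,
               n_iterations = r$n_iterations, pd_mean = r$pd_mean,
               pd_sd = r$pd_sd, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
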