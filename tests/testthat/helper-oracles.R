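# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# Brute-force Faith's PD: union of root-to-tip edge sets collected via
# ape::nodepath, summed; include_root = FALSE drops edges shared by every
# root path (the stem above the tips' MRCA).
oracle_pd <- function(tips, tree, include_root = TRUE) {
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  idx <- match(tips, tree$tip.label)
  paths <- lapply(idx, function(t) ape::nodepath(tree, root, t))
  edge_key <- function(p) paste(p[-length(p)], p[-1L])
  keys <- lapply(paths, edge_key)
  all_keys <- unique(unlist(keys))
  if (!include_root) {
    shared <- Reduce(intersect, keys)
    all_keys <- setdiff(all_keys, shared)
  }
  tree_keys <- paste(tree$edge[, 1L], tree$edge[, 2L])
  sum(tree$edge.length[match(all_keys, tree_keys)])
}

# Brute-force permutation ANOVA: enumerate every split of the pooled values
# into groups of sizes (n1, n2) with utils::combn, compute the classical
# one-way F through stats::anova(stats::lm(...)), and take the tail of the
# signed (or absolute) statistic.
oracle_exact_perm <- function(heavy, light,
                              alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  x <- c(heavy, light)
  n1 <- length(heavy)
  stat <- function(idx) {
    g <- factor(seq_along(x) %in% idx)
    f <- stats::anova(stats::lm(x ~ g))$`F value`[1L]
    s <- sign(mean(x[idx]) - mean(x[-idx]))
    if (alternative == "greater") s * f else f
  }
  obs <- stat(seq_len(n1))
  all_s <- apply(utils::combn(length(x), n1), 2L, stat)
  mean(all_s >= obs - 1e-10 * max(1, abs(obs)))
}

# Closed-form expected atom percent of the two-pool isotopologue model.
oracle_atom_percent <- function(phi, atom_fraction, natural_abundance,
                                n_carbons) {
  a <- atom_fraction; q <- natural_abundance; n <- n_carbons
  p13 <- phi * a^n + (1 - phi) * q^n
  p12 <- phi * (1 - a)^n + (1 - phi) * (1 - q)^n
  100 * p13 / (p12 + p13)
}

# A no-label scenario with zero between-taxon density spread: heavy and
# light fraction samples are exchangeable, so every taxon is a true null.
exchangeable_null_scenario <- function(seed) {
  default_scenario(seed = seed, n_labeled = 0, unlabeled_density_sd = 0)
}

# Community fully labeled at the final timepoint (atom fraction 0.98).
fully_labeled_scenario <- function(seed) {
  base <- default_scenario(seed = seed)
  laf <- matrix(0, base$n_taxa, 3L)
  laf[, 2L] <- 0.5
  laf[, 3L] <- 0.98
  sip_scenario(base$n_taxa, base$baseline_abundances, laf,
               taxa = base$taxa, metabolite_phi = base$metabolite_phi,
               seed = seed)
}
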