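test_that("relative abundance normalization behaves and is idempotent", {
  m <- matrix(c(1, 1, 2), 3, 1, dimnames = list(letters[1:3], "s1"))
  expect_equal(as.numeric(to_relative_abundance(m)), c(25, 25, 50))
  r <- to_relative_abundance(m)
  expect_equal(to_relative_abundance(r), r, tolerance = 1e-12)
  set.seed(8)
  big <- matrix(rpois(200, 5), 20, 10,
                dimnames = list(paste0("t", 1:20), paste0("s", 1:10)))
  big[1, ] <- big[1, ] + 1  # guard against all-zero columns
  expect_equal(unname(colSums(to_relative_abundance(big))), rep(100, 10),
               tolerance = 1e-9)
  bad <- cbind(big, s0 = 0)
  expect_error(to_relative_abundance(bad), "all-zero")
})

test_that("permutation ANOVA handles null and separated groups exactly", {
  expect_warning(r0 <- permutation_anova(c(5, 5, 5), c(5, 5, 5),
                                         mode = "exact"),
                 "constant")
  expect_equal(r0$F_stat, 0)
  expect_equal(r0$p_perm, 1)

  r <- permutation_anova(c(10, 11, 12), c(1, 2, 3), mode = "exact")
  expect_true(r$exact)
  expect_equal(r$n_permutations, choose(6, 3))
  expect_equal(r$p_perm, 1 / 20)
  # exact p-values are multiples of 1 / #partitions
  expect_equal(r$p_perm * r$n_permutations,
               round(r$p_perm * r$n_permutations))
})

test_that("exact mode matches brute-force enumeration up to 5v5", {
  set.seed(77)
  sizes <- list(c(3, 3), c(4, 3), c(4, 4), c(5, 5))
  for (sz in sizes) {
    for (rep_i in 1:3) {
      h <- rnorm(sz[1], mean = rep_i)
      l <- rnorm(sz[2])
      for (alt in c("greater", "two.sided")) {
        got <- permutation_anova(h, l, mode = "exact",
                                 alternative = alt)$p_perm
        expect_identical(got, oracle_exact_perm(h, l, alternative = alt),
                         label = paste(alt, paste(sz, collapse = "v")))
      }
    }
  }
})

test_that("monte-carlo p agrees with exact p within binomial error", {
  set.seed(5)
  h <- c(4.1, 5.0, 6.2); l <- c(2.0, 3.5, 4.4)
  p_ex <- permutation_anova(h, l, mode = "exact")$p_perm
  for (s in 1:10) {
    p_mc <- permutation_anova(h, l, n_perm = 2000, seed = s)$p_perm
    se <- sqrt(p_ex * (1 - p_ex) / 2000)
    expect_lt(abs(p_mc - p_ex), 3 * se + 1 / 2001)
  }
})

test_that("two-sided monte-carlo p is invariant to heavy/light swap", {
  h <- c(4.1, 5.0, 6.2, 3.8); l <- c(2.0, 3.5, 4.4, 2.2)
  p1 <- permutation_anova(h, l, seed = 9, alternative = "two.sided")$p_perm
  p2 <- permutation_anova(l, h, seed = 9, alternative = "two.sided")$p_perm
  expect_identical(p1, p2)
})

test_that("pre-labeled taxa are classed baseline_excluded", {
  sc <- default_scenario(seed = 61)
  laf <- sc$label_atom_fraction
  laf[2L, ] <- 0.5  # enriched already at 0h
  sc2 <- sip_scenario(20, sc$baseline_abundances, laf, taxa = sc$taxa,
                      seed = 61)
  ds <- simulate_experiment(sc2)
  lab <- identify_labeled_taxa(ds$feature_table, ds$metadata, "0h", "4h",
                               mode = "exact")
  expect_identical(lab$class[lab$taxon == sc$taxa[2L]], "baseline_excluded")
})

test_that("null taxa under exchangeability are almost always unlabeled", {
  n_unlabeled <- 0L; n_total <- 0L
  for (s in 1:5) {
    ds <- simulate_experiment(exchangeable_null_scenario(seed = 700 + s))
    lab <- identify_labeled_taxa(ds$feature_table, ds$metadata, "0h", "4h",
                                 mode = "exact")
    n_unlabeled <- n_unlabeled + sum(lab$class == "unlabeled")
    n_total <- n_total + nrow(lab)
  }
  # alpha 0.05 + trend 0.10 + baseline screen each remove a few percent;
  # around 75% of nulls should survive all three, far above chance
  expect_gte(n_unlabeled / n_total, 0.6)
  # and none of the classifications may be "labeled" in more than alpha-ish
  # proportion under the null
})

test_that("labeled taxa are recovered and metadata errors are caught", {
  ds <- simulate_experiment(default_scenario(seed = 41))
  lab <- identify_labeled_taxa(ds$feature_table, ds$metadata, "0h", "4h",
                               mode = "exact")
  r <- evaluate_recovery(lab, ds$truth, "4h")
  expect_gte(r$power, 0.6)
  expect_lte(r$fdr, 0.4)
  expect_error(identify_labeled_taxa(ds$feature_table, ds$metadata,
                                     "0h", "8h"), "absent")
  m2 <- ds$metadata; m2$density_class <- NULL
  expect_error(identify_labeled_taxa(ds$feature_table, m2, "0h", "4h"),
               "density_class")
  m3 <- ds$metadata; m3$density_class[m3$density_class == "heavy"] <- "x"
  expect_error(identify_labeled_taxa(ds$feature_table, m3, "0h", "4h"),
               ">= 2 heavy")
})

test_that("profile clustering uses centered-Pearson distance with UPGMA", {
  base <- c(5, 3, 8, 1, 6)
  m <- cbind(s1 = base, s2 = base * 2,        # identical profile shape
             s3 = max(base) + 1 - base,       # reversed profile
             s4 = c(2, 9, 1, 7, 3))
  rownames(m) <- paste0("t", 1:5)
  cl <- cluster_profiles(m)
  d <- as.matrix(cl$dist)
  expect_equal(d["s1", "s2"], 0, tolerance = 1e-12)
  expect_equal(d["s1", "s3"], 2, tolerance = 1e-12)
  expect_equal(cl$hclust$merge[1, ], c(-1, -2))  # identical pair merges first
  mc <- cbind(m, s5 = rep(4, 5))
  expect_error(cluster_profiles(mc), "s5")
})

test_that("heavy profiles after labeling separate cleanly from controls", {
  # 3 heavy-window samples of the fed community vs the 3 heavy-window
  # samples of the unlabeled control: two clean clusters
  ok <- 0L
  for (s in 1:10) {
    ds <- simulate_experiment(default_scenario(seed = 800 + s))
    keep <- ds$metadata$density_class == "heavy" &
      ds$metadata$timepoint %in% c("0h", "4h")
    sub <- ds$feature_table[, ds$metadata$sample[keep]]
    cl <- cluster_profiles(to_relative_abundance(sub))
    grp <- cutree(cl$hclust, k = 2)
    lab_cols <- grepl("^4h", names(grp))
    ok <- ok + as.integer(length(unique(grp[lab_cols])) == 1 &&
                            length(unique(grp[!lab_cols])) == 1 &&
                            grp[lab_cols][1] != grp[!lab_cols][1])
  }
  expect_gte(ok, 9L)
})
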