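test_that("PCA on individuals is deterministic with sound geometry", {
  ds <- quick_dataset(n_genes = 120, seed = 3)
  ic <- sum_replicates(ds$counts, ds$design)
  ei <- variance_stabilize(ic)
  pc <- pca_individuals(ei, n_pcs = 6)
  expect_true(all(diff(pc$explained) <= 1e-12))
  expect_lte(sum(pc$explained), 1 + 1e-12)
  # sign convention: the largest-magnitude loading of each PC is positive
  for (j in seq_len(ncol(pc$loadings)))
    expect_gt(pc$loadings[which.max(abs(pc$loadings[, j])), j], 0)
  # reconstruction at full rank reproduces the centered matrix
  full <- suppressMessages(pca_individuals(ei, n_pcs = ncol(ei)))
  centered <- scale(t(ei), center = TRUE, scale = FALSE)
  expect_equal(full$scores %*% t(full$loadings), unclass(centered),
               ignore_attr = TRUE, tolerance = 1e-8)
  # duplicate individuals get identical scores
  ei2 <- cbind(ei, dup = ei[, 1])
  colnames(ei2)[ncol(ei2)] <- "I999"
  pc2 <- pca_individuals(ei2, n_pcs = 3)
  expect_equal(unname(pc2$scores["I001", ]), unname(pc2$scores["I999", ]))
})

test_that("a single injected axis dominates PC1 by its variance share", {
  set.seed(11)
  G <- 200; I <- 30
  base <- matrix(rnorm(G * I, 0, 0.1), G, I)
  axis <- rnorm(I, 0, 1)
  load <- rnorm(G, 0, 0.3)
  X <- base + outer(load, axis)
  dimnames(X) <- list(paste0("g", 1:G), paste0("I", 1:I))
  pc <- pca_individuals(X, n_pcs = 5)
  injected_share <- sum(outer(load, axis)^2) /
    (sum(outer(load, axis)^2) + sum(base^2))
  expect_lt(abs(pc$explained[1] - injected_share), 0.1)
  expect_gt(pc$explained[1], 5 * pc$explained[2])
})

test_that("PC-trait screening uses the Bonferroni grid and skips constants", {
  ds <- quick_dataset(n_genes = 100, seed = 13)
  ic <- sum_replicates(ds$counts, ds$design)
  ei <- variance_stabilize(ic)
  idesign <- individual_design(ds$design)
  pc <- pca_individuals(ei, n_pcs = 4)
  # a trait equal to a PC's scores correlates perfectly
  idesign$pc_copy <- pc$scores[, 2]
  rep1 <- pc_trait_correlations(pc, idesign, n_pcs = 4,
                                traits = c("weight", "pc_copy"))
  row <- rep1[rep1$pc == "PC2" & rep1$trait == "pc_copy", ]
  expect_equal(row$r, 1)
  expect_equal(attr(rep1, "n_tests"), 8)
  expect_equal(rep1$p_bonferroni, pmin(1, rep1$p * 8))
  # constant trait skipped with a note
  idesign$flat <- 5
  expect_message(rep2 <- pc_trait_correlations(pc, idesign, n_pcs = 2,
                                               traits = c("weight", "flat")),
                 "constant")
  expect_false("flat" %in% rep2$trait)
})

test_that("an injected trait surfaces through a principal component", {
  cfg <- simulation_config(
    n_genes = 400, sigma2_A = 0, sigma2_B = 0.05, sigma2_e = 0.02,
    baseline_log_mean_range = c(10, 14),
    nb_dispersion_model = function(mu) 0.001 + 0.5 / mu,
    trait_effects = list(list(trait = "length", fraction = 0.5,
                              effect_sd = 0.6)),
    seed = 17)
  ds <- generate_dataset(cfg)
  ic <- sum_replicates(ds$counts, ds$design)
  ei <- variance_stabilize(ic)
  idesign <- individual_design(ds$design)
  pc <- pca_individuals(ei, n_pcs = 5)
  rep <- pc_trait_correlations(pc, idesign, n_pcs = 5)
  hit <- rep[rep$trait == "length", ]
  expect_lt(min(hit$p_bonferroni), 0.05)
})

test_that("UPGMA population tree reproduces hand agglomeration", {
  # three groups with distances d12 = 2, d13 = d23 = 4: join (1,2) at
  # height 2, then 3 at height 4
  fake_pair <- function(g1, g2, nst) {
    tab <- data.frame(gene_id = paste0("g", 1:4), mean_expr = 1,
                      Nst = nst, Nit = 0.5, Net = 0.5 - nst,
                      Nis = 0.5, Nig = 0.5, Mst = nst, Mit = 0.5,
                      Met = 0.5 - nst, defined = TRUE)
    fit <- list(table = data.frame(SS_T = rep(1, 4)))
    list(fit = fit, table = tab)
  }
  pw <- list("A:B" = fake_pair("A", "B", 2),
             "A:C" = fake_pair("A", "C", 4),
             "B:C" = fake_pair("B", "C", 4))
  class(pw) <- "pairwise_apportionment"
  tr <- population_distance_tree(pw, statistic = "Nst",
                                 weighting = "uniform")
  expect_equal(unname(tr$distance["A", "B"]), 2)
  expect_equal(tr$hclust$height, c(2, 4))
  first <- apportionr:::hclust_leafsets(tr$hclust)[[1]]
  expect_setequal(first, c("A", "B"))
  # invariance to uniform weight rescaling (SS_T weights x 10)
  pw2 <- pw
  for (nm in names(pw2)) pw2[[nm]]$fit$table$SS_T <- rep(10, 4)
  class(pw2) <- "pairwise_apportionment"
  tr2 <- population_distance_tree(pw2, weighting = "SS_T")
  expect_equal(tr2$distance, tr$distance)

  # a group with doubled shifts becomes the outgroup
  regs <- list(selection_regime("directional", 60, shift = c(0, 0, 0, 1.5)))
  ds <- quick_dataset(n_genes = 300, seed = 23, regimes = regs)
  expr <- variance_stabilize(ds$counts)
  pwr <- pairwise_apportionments(expr, ds$design)
  trr <- population_distance_tree(pwr)
  # G4 joins last: the first two merges exclude it
  sets <- apportionr:::hclust_leafsets(trr$hclust)
  expect_false("G4" %in% sets[[1]])
  expect_false("G4" %in% sets[[2]])
})

test_that("k-means profile partitioning separates mirror-image profiles", {
  ds <- quick_dataset(n_genes = 60, seed = 31)
  ic <- sum_replicates(ds$counts, ds$design)
  ei <- variance_stabilize(ic)
  idesign <- individual_design(ds$design)
  # construct two mirror-image blocks over individuals
  set.seed(32)
  p <- seq(-1, 1, length.out = ncol(ei))
  X <- rbind(matrix(p, 15, ncol(ei), byrow = TRUE),
             matrix(-p, 15, ncol(ei), byrow = TRUE)) +
    matrix(rnorm(30 * ncol(ei), 0, 0.05), 30, ncol(ei))
  dimnames(X) <- list(paste0("g", 1:30), colnames(ei))
  km <- kmeans_profiles(X, idesign, rownames(X), k = 2, seed = 33)
  expect_length(unique(km$cluster[1:15]), 1)
  expect_length(unique(km$cluster[16:30]), 1)
  expect_false(km$cluster[1] == km$cluster[16])
  # k = 1 puts everything together; k > genes errors; fixed seed is stable
  km1 <- kmeans_profiles(X, idesign, rownames(X), k = 1, seed = 33)
  expect_true(all(km1$cluster == 1))
  expect_error(kmeans_profiles(X, idesign, rownames(X), k = 31), "exceeds")
  km2 <- kmeans_profiles(X, idesign, rownames(X), k = 2, seed = 33)
  expect_identical(km$cluster, km2$cluster)
})
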