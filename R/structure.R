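## Global expression-structure analyses: PCA with trait screening,
## population distance dendrograms, and k-means profile partitioning.

#' Principal components of individuals
#'
#' PCA of an individual-level expression matrix: genes are centered,
#' components are over individuals. A deterministic sign convention is
#' applied (each component's largest-magnitude loading is positive).
#'
#' @param expr_by_individual Gene-by-individual expression matrix.
#' @param n_pcs Number of components to keep (truncated to the matrix
#'   rank, with a note).
#' @return List of class `pca_individuals`: `scores` (individuals x PCs),
#'   `loadings` (genes x PCs), `explained` (variance fractions).
#' @export
pca_individuals <- function(expr_by_individual, n_pcs = 10) {
  X <- t(expr_by_individual)                 # individuals x genes
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  rank <- sum(pc$sdev > pc$sdev[1] * 1e-12)
  if (n_pcs > rank) {
    message("requested ", n_pcs, " PCs; rank is ", rank, " - truncated")
    n_pcs <- rank
  }
  keep <- seq_len(n_pcs)
  scores <- pc$x[, keep, drop = FALSE]
  loadings <- pc$rotation[, keep, drop = FALSE]
  for (j in keep) {
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  explained <- (pc$sdev^2 / sum(pc$sdev^2))[keep]
  out <- list(scores = scores, loadings = loadings, explained = explained)
  class(out) <- "pca_individuals"
  out
}

#' Screen principal components against traits
#'
#' Pearson correlation of each PC's scores with each trait (binary traits
#' coded 0/1), with Bonferroni adjustment over the tested PC-by-trait
#' grid. Constant traits are skipped with a note.
#'
#' @param pca A [pca_individuals()] result.
#' @param design_by_individual Individual-level design with trait columns.
#' @param n_pcs Number of leading PCs to test.
#' @param traits Trait column names; defaults to the traits present plus
#'   the technical covariates.
#' @return data.frame of class `pc_trait_report` with r, raw and
#'   Bonferroni-adjusted p per (PC, trait); the multiplier is recorded in
#'   `attr(, "n_tests")`.
#' @export
pc_trait_correlations <- function(pca, design_by_individual, n_pcs = 5,
                                  traits = NULL) {
  stopifnot(inherits(pca, "pca_individuals"))
  if (is.null(traits))
    traits <- intersect(c("mapped_reads", "rin", TRAIT_COLUMNS),
                        colnames(design_by_individual))
  n_pcs <- min(n_pcs, ncol(pca$scores))
  keep <- character()
  vals <- list()
  for (tr in traits) {
    v <- trait_as_numeric(design_by_individual[[tr]], tr)
    if (stats::sd(v) == 0) {
      message("constant trait '", tr, "' skipped")
      next
    }
    keep <- c(keep, tr); vals[[tr]] <- v
  }
  n_tests <- n_pcs * length(keep)
  rows <- list()
  for (j in seq_len(n_pcs)) for (tr in keep) {
    ct <- stats::cor.test(pca$scores[, j], vals[[tr]])
    rows[[length(rows) + 1L]] <-
      data.frame(pc = paste0("PC", j), trait = tr,
                 explained = pca$explained[j],
                 r = unname(ct$estimate), p = ct$p.value,
                 p_bonferroni = min(1, ct$p.value * n_tests),
                 stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  attr(out, "n_tests") <- n_tests
  class(out) <- c("pc_trait_report", "data.frame")
  out
}

#' Weighted-mean population distance dendrogram
#'
#' Summarizes each pair of groups by the weighted mean of a pairwise
#' apportionment statistic (Nst by default) across genes, then
#' agglomerates the group-by-group distance matrix by UPGMA. The default
#' weight is each gene's total sum of squares in the pairwise fit;
#' `weighting = "uniform"` gives the unweighted mean and
#' `weighting = "mean_expr"` weights by mean expression.
#'
#' @param pairwise A [pairwise_apportionments()] result.
#' @param statistic `"Nst"` or `"Mst"`.
#' @param weighting `"SS_T"`, `"uniform"`, or `"mean_expr"`.
#' @return List of class `population_tree`: the distance matrix, the
#'   `hclust` object, the `ape` phylo tree, and its newick string, with
#'   the weighting scheme recorded.
#' @export
population_distance_tree <- function(pairwise, statistic = c("Nst", "Mst"),
                                     weighting = c("SS_T", "uniform",
                                                   "mean_expr")) {
  stopifnot(inherits(pairwise, "pairwise_apportionment"))
  statistic <- match.arg(statistic)
  weighting <- match.arg(weighting)
  groups <- sort(unique(unlist(strsplit(names(pairwise), ":", fixed = TRUE))))
  D <- matrix(0, length(groups), length(groups),
              dimnames = list(groups, groups))
  for (nm in names(pairwise)) {
    p <- strsplit(nm, ":", fixed = TRUE)[[1]]
    tab <- pairwise[[nm]]$table
    s <- tab[[statistic]]
    w <- switch(weighting,
                SS_T = pairwise[[nm]]$fit$table$SS_T,
                uniform = rep(1, nrow(tab)),
                mean_expr = tab$mean_expr)
    ok <- is.finite(s) & is.finite(w) & w >= 0
    D[p[1], p[2]] <- D[p[2], p[1]] <- sum(s[ok] * w[ok]) / sum(w[ok])
  }
  hc <- stats::hclust(stats::as.dist(D), method = "average")
  tree <- ape::as.phylo(hc)
  out <- list(distance = D, hclust = hc, tree = tree,
              newick = ape::write.tree(tree),
              statistic = statistic, weighting = weighting)
  class(out) <- "population_tree"
  out
}

#' @export
print.population_tree <- function(x, ...) {
  cat("Population distance tree (", x$statistic, ", weighting = ",
      x$weighting, ")\n", sep = "")
  print(round(x$distance, 4))
  cat(" ", x$newick, "\n")
  invisible(x)
}

#' K-means partitioning of expression profiles
#'
#' Standardizes each gene of the given set to mean 0 / sd 1 across
#' individuals, runs k-means with multiple restarts under a fixed seed,
#' and reports per-cluster mean profiles by group (for profile plots).
#'
#' @param expr_by_individual Gene-by-individual expression matrix.
#' @param design_by_individual Individual-level design.
#' @param genes Gene ids to partition (non-empty).
#' @param k Number of clusters (`1 <= k <= length(genes)`).
#' @param seed RNG seed.
#' @param nstart Number of random restarts.
#' @return List of class `kmeans_profiles`: `cluster` (named gene labels),
#'   `group_profiles` (cluster x group mean standardized expression),
#'   `withinss`, and the `kmeans` fit.
#' @export
kmeans_profiles <- function(expr_by_individual, design_by_individual,
                            genes, k, seed = 1L, nstart = 25) {
  if (length(genes) == 0) stop2("empty gene set")
  if (k > length(genes)) stop2("k exceeds the number of genes")
  X <- expr_by_individual[genes, , drop = FALSE]
  Xs <- t(scale(t(X)))
  Xs[!is.finite(Xs)] <- 0                      # constant genes sit at 0
  km <- with_seed(seed, stats::kmeans(Xs, centers = k, nstart = nstart,
                                      iter.max = 100))
  groups <- design_by_individual$group[
    match(colnames(X), design_by_individual$individual_id)]
  gp <- matrix(NA_real_, k, length(unique(groups)),
               dimnames = list(paste0("cluster", seq_len(k)),
                               sort(unique(groups))))
  for (cl in seq_len(k)) for (g in colnames(gp))
    gp[cl, g] <- mean(Xs[km$cluster == cl, groups == g, drop = FALSE])
  out <- list(cluster = km$cluster, group_profiles = gp,
              withinss = km$tot.withinss, kmeans = km, k = k, seed = seed)
  class(out) <- "kmeans_profiles"
  out
}
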