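## Classification of expression profiles into patterns consistent with
## directional, balancing, stabilizing, or diversifying selection, with
## neutrality as the complement. These are profile classifications, not
## formal tests of selection.

#' Artificial-gene null for inter-individual expression variance
#'
#' Builds a resampling null for the variance of a gene across individuals:
#' every gene is first centered (additively) to the global mean so all
#' genes share the same mean expression; an artificial gene then draws,
#' independently for each individual, the centered value of one real gene
#' chosen uniformly at random. The variance of each artificial gene is
#' computed across all individuals with no regard for group association.
#' The 1st and 99th percentiles of the resulting variance distribution are
#' the stabilizing and diversifying cutoffs.
#'
#' @param expr_by_individual Gene-by-individual expression matrix
#'   (replicates summed and renormalized).
#' @param n Number of artificial genes (default 10,000).
#' @param seed RNG seed.
#' @return Object of class `artificial_gene_null` with the sampled
#'   variances and `cutoffs` (`p01`, `p99`).
#' @export
artificial_gene_null <- function(expr_by_individual, n = 10000, seed = 1L) {
  G <- nrow(expr_by_individual)
  I <- ncol(expr_by_individual)
  if (G < 2) stop2("need >= 2 genes to resample artificial genes")
  grand <- mean(expr_by_individual)
  centered <- expr_by_individual - rowMeans(expr_by_individual) + grand
  vars <- with_seed(seed, {
    idx <- matrix(sample.int(G, n * I, replace = TRUE), n, I)
    V <- matrix(centered[cbind(as.vector(idx), rep(seq_len(I), each = n))],
                n, I)
    apply(V, 1, stats::var)
  })
  out <- list(variances = vars,
              cutoffs = c(p01 = perm_quantile(vars, 0.01),
                          p99 = perm_quantile(vars, 0.99)),
              n_artificial = n, n_genes = G, n_individuals = I,
              grand_mean = grand, seed = seed)
  class(out) <- "artificial_gene_null"
  out
}

#' @export
print.artificial_gene_null <- function(x, ...) {
  cat("Artificial-gene variance null:", x$n_artificial, "resampled genes over",
      x$n_individuals, "individuals\n")
  cat("  cutoffs: stabilizing <", signif(x$cutoffs["p01"], 4),
      "  diversifying >", signif(x$cutoffs["p99"], 4), "\n")
  invisible(x)
}

#' Classify genes into selection-consistent expression profiles
#'
#' Flags per gene: directional if Nst exceeds the 99th percentile of the
#' individuals-among-groups null; balancing if Nig exceeds the 99th
#' percentile of the replicates-within-groups null; stabilizing /
#' diversifying if the gene's variance across individuals falls below the
#' 1st / above the 99th percentile of the artificial-gene null (mutually
#' exclusive by construction). Neutral genes carry no flag. Directional
#' calls may overlap the variance-based modes.
#'
#' @param apportionment An [apportion_statistics()] table from the
#'   all-groups fit.
#' @param nst_null A [null_nst()] distribution.
#' @param nig_null A [null_nig()] distribution.
#' @param var_null An [artificial_gene_null()].
#' @param expr_by_individual Gene-by-individual expression matrix used for
#'   the variance-based modes (same genes, same data as `var_null`).
#' @return data.frame of class `selection_calls` with the four flags,
#'   `neutral`, and the supporting statistics; category proportions in
#'   `attr(, "proportions")`.
#' @export
classify_selection <- function(apportionment, nst_null, nig_null, var_null,
                               expr_by_individual) {
  if (missing(nst_null) || is.null(nst_null)) stop2("missing null: nst_null")
  if (missing(nig_null) || is.null(nig_null)) stop2("missing null: nig_null")
  if (missing(var_null) || is.null(var_null)) stop2("missing null: var_null")
  stopifnot(inherits(nst_null, "null_distribution"),
            inherits(nig_null, "null_distribution"),
            inherits(var_null, "artificial_gene_null"))
  tab <- apportionment
  if (!all(tab$gene_id %in% rownames(expr_by_individual)))
    stop2("apportionment genes missing from individual-level matrix")
  v <- apply(expr_by_individual[tab$gene_id, , drop = FALSE], 1, stats::var)
  out <- data.frame(gene_id = tab$gene_id,
                    Nst = tab$Nst, Nig = tab$Nig,
                    individual_variance = v,
                    stringsAsFactors = FALSE)
  out$directional <- !is.na(tab$Nst) & tab$Nst > nst_null$cutoffs["p99"]
  out$balancing <- !is.na(tab$Nig) & tab$Nig > nig_null$cutoffs["p99"]
  out$stabilizing <- v < var_null$cutoffs["p01"]
  out$diversifying <- v > var_null$cutoffs["p99"]
  stopifnot(!any(out$stabilizing & out$diversifying))
  out$neutral <- !(out$directional | out$balancing |
                   out$stabilizing | out$diversifying)
  prop <- c(directional = mean(out$directional),
            balancing = mean(out$balancing),
            stabilizing = mean(out$stabilizing),
            diversifying = mean(out$diversifying),
            neutral = mean(out$neutral))
  attr(out, "proportions") <- prop
  attr(out, "cutoffs") <- list(nst = unname(nst_null$cutoffs["p99"]),
                               nig = unname(nig_null$cutoffs["p99"]),
                               var_low = unname(var_null$cutoffs["p01"]),
                               var_high = unname(var_null$cutoffs["p99"]))
  class(out) <- c("selection_calls", "data.frame")
  out
}

#' @export
print.selection_calls <- function(x, ...) {
  p <- attr(x, "proportions")
  cat("Selection-profile calls on", nrow(x), "genes\n")
  for (nm in names(p))
    cat(sprintf("  %-12s %5.1f%% (%d genes)\n", nm, 100 * p[nm],
                sum(x[[nm]])))
  invisible(x)
}

#' Group structure recovered by directional genes
#'
#' Builds a UPGMA tree of individuals from the Euclidean distance over
#' per-gene standardized expression restricted to the directional gene
#' set (standardizing keeps every gene's group shift visible regardless
#' of its baseline level), runs a PCA on the same set, and scores group
#' separation by the mean silhouette width under the group labels.
#'
#' @param expr_by_individual Gene-by-individual expression matrix.
#' @param design_by_individual Individual-level design
#'   (see [individual_design()]).
#' @param directional_genes Character vector of gene ids (>= 2).
#' @return List of class `directional_structure`: `tree` (an `ape`
#'   phylo), `newick` string, `pca` scores/explained fractions,
#'   `silhouette` (mean width), per-group monophyly flags, and a
#'   `degenerate` flag when any group has a single individual.
#' @export
directional_structure_check <- function(expr_by_individual,
                                        design_by_individual,
                                        directional_genes) {
  if (length(directional_genes) < 2) stop2("need >= 2 directional genes")
  sub <- expr_by_individual[directional_genes, , drop = FALSE]
  groups <- design_by_individual$group[
    match(colnames(sub), design_by_individual$individual_id)]
  z <- t(scale(t(sub)))
  z[!is.finite(z)] <- 0
  d <- as.matrix(stats::dist(t(z))) / sqrt(nrow(z))
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  tree <- ape::as.phylo(hc)
  pc <- pca_individuals(sub)
  sizes <- table(groups)
  degenerate <- any(sizes < 2)
  sil <- if (length(unique(groups)) < 2 || degenerate) NA_real_ else {
    s <- cluster::silhouette(as.integer(factor(groups)), stats::as.dist(d))
    mean(s[, "sil_width"])
  }
  mono <- vapply(unique(groups), function(g)
    ape::is.monophyletic(tree, colnames(sub)[groups == g]), logical(1))
  names(mono) <- unique(groups)
  out <- list(tree = tree, newick = ape::write.tree(tree),
              pca = pc, silhouette = sil, monophyletic = mono,
              degenerate = degenerate, n_genes = length(directional_genes))
  class(out) <- "directional_structure"
  out
}
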