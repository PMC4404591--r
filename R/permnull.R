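## Permutation null distributions for the apportionment statistics.
##
## Three exchangeability schemes mirror the strata of the nested model:
##   - individuals_among_groups: whole individuals (replicates move
##     together) are reassigned to groups of the original sizes; nulls
##     among-group structure (Nst).
##   - replicates_within_groups: replicate libraries are shuffled among
##     individuals within each group; nulls among-individual structure
##     (Nig, Nit) while leaving group means untouched.
##   - reads_among_replicates: each individual's per-gene reads are pooled
##     and redistributed binomially between its two libraries in
##     proportion to library depth; nulls the replicate stratum (Net).

new_null_distribution <- function(scheme, statistic, values, n_perm,
                                  genes_per_perm, seed, degenerate = FALSE) {
  out <- list(scheme = scheme, statistic = statistic,
              values = values,
              cutoffs = c(p01 = perm_quantile(values, 0.01),
                          p99 = perm_quantile(values, 0.99)),
              n_perm = n_perm, genes_per_perm = genes_per_perm,
              seed = seed, degenerate = degenerate)
  class(out) <- "null_distribution"
  out
}

#' @export
print.null_distribution <- function(x, ...) {
  cat("Permutation null:", x$scheme, "/", x$statistic, "\n")
  cat("  ", x$n_perm, "permutations x", x$genes_per_perm, "genes =",
      length(x$values), "draws\n")
  cat("   cutoffs: 1st pct =", signif(x$cutoffs["p01"], 4),
      " 99th pct =", signif(x$cutoffs["p99"], 4), "\n")
  if (x$degenerate) cat("   WARNING: degenerate permutation scheme\n")
  invisible(x)
}

## Shared set-up: transposed expression, standardized covariates and
## design bookkeeping. Permuted statistics are computed with the same
## sequential-ANOVA engine as the observed fit.
perm_setup <- function(expr, design, covariates = c("mapped_reads", "rin")) {
  design <- assert_expr_design(expr, design)
  ind <- design$individual_id
  grp <- design$group
  inds <- unique(ind)
  grp_of_ind <- grp[match(inds, ind)]
  list(Y = t(expr), C = covariate_matrix(design, covariates),
       design = design, ind = ind, grp = grp,
       inds = inds, grp_of_ind = grp_of_ind)
}

nst_from_ss <- function(ss) {
  tot <- ss$SS_A + ss$SS_B + ss$SS_e
  ifelse(tot > 0, ss$SS_A / tot, NA_real_)
}
nig_from_ss <- function(ss) {
  den <- ss$SS_A + ss$SS_B
  ifelse(den > 0, ss$SS_B / den, NA_real_)
}

#' Null distribution of Nst by permuting individuals among groups
#'
#' Each permutation reassigns whole individuals (replicate libraries move
#' together) to groups while preserving group sizes, refits the nested
#' decomposition on a random sample of genes, and pools the resulting Nst
#' values. The 99th percentile of the pooled distribution is the
#' differential-expression cutoff.
#'
#' @param expr Normalized gene-by-library expression matrix.
#' @param design Library design.
#' @param n_perm Number of permutations.
#' @param genes_per_perm Genes sampled per permutation (capped at the
#'   number of genes with a warning).
#' @param seed RNG seed.
#' @return A `null_distribution` object.
#' @export
null_nst <- function(expr, design, n_perm = 1000, genes_per_perm = 100,
                     seed = 1L) {
  st <- perm_setup(expr, design)
  if (length(unique(st$grp)) < 2) stop2("cannot permute a 1-group design")
  G <- ncol(st$Y)
  if (genes_per_perm > G) {
    warning("genes_per_perm capped at the number of genes (", G, ")")
    genes_per_perm <- G
  }
  vals <- with_seed(seed, {
    unlist(lapply(seq_len(n_perm), function(p) {
      new_grp_of_ind <- sample(st$grp_of_ind)
      grp_perm <- new_grp_of_ind[match(st$ind, st$inds)]
      gs <- sample.int(G, genes_per_perm)
      ss <- simple_ss(st$Y[, gs, drop = FALSE], st$ind, grp_perm, st$C)
      nst_from_ss(ss)
    }))
  })
  vals <- vals[is.finite(vals)]
  new_null_distribution("individuals_among_groups", "Nst", vals,
                        n_perm, genes_per_perm, seed)
}

## Permute replicate libraries among individuals within each group:
## returns a permuted individual-id vector over libraries.
permute_replicates_within_groups <- function(ind, grp) {
  out <- ind
  for (g in unique(grp)) {
    idx <- which(grp == g)
    out[idx] <- sample(ind[idx])
  }
  ## reassign libraries to pseudo-individuals keeping replicate counts:
  ## a plain shuffle of individual labels over the group's libraries
  ## preserves each individual's library count within the group.
  out
}

#' Null distribution of Nig by permuting replicates within groups
#'
#' Shuffles replicate libraries among individuals within each group
#' (randomizing inter-individual differences while leaving group means
#' unchanged) and pools Nig over sampled genes. The 99th percentile of the
#' pooled distribution is the balancing-profile cutoff. If the permutation
#' leaves the data invariant (e.g. replicate libraries identical within
#' every individual) the null is flagged degenerate.
#'
#' @inheritParams null_nst
#' @return A `null_distribution` object.
#' @export
null_nig <- function(expr, design, n_perm = 1000, genes_per_perm = 100,
                     seed = 1L) {
  st <- perm_setup(expr, design)
  nrep <- table(st$ind)
  if (any(nrep < 2)) stop2("need >= 2 replicates per individual")
  G <- ncol(st$Y)
  if (genes_per_perm > G) {
    warning("genes_per_perm capped at the number of genes (", G, ")")
    genes_per_perm <- G
  }
  vals <- with_seed(seed, {
    unlist(lapply(seq_len(n_perm), function(p) {
      ind_perm <- permute_replicates_within_groups(st$ind, st$grp)
      gs <- sample.int(G, genes_per_perm)
      ss <- simple_ss(st$Y[, gs, drop = FALSE], ind_perm, st$grp, st$C)
      nig_from_ss(ss)
    }))
  })
  vals <- vals[is.finite(vals)]
  degenerate <- stats::sd(vals) == 0 ||
    isTRUE(all.equal(perm_quantile(vals, 0.99), perm_quantile(vals, 0.01)))
  if (degenerate)
    warning("replicate permutation left Nig invariant; null is degenerate")
  new_null_distribution("replicates_within_groups", "Nig", vals,
                        n_perm, genes_per_perm, seed, degenerate = degenerate)
}

## Redistribute each individual's pooled per-gene reads binomially between
## its two replicate libraries, proportional to total library depth.
permute_reads_among_replicates <- function(counts, design) {
  out <- counts
  for (id in unique(design$individual_id)) {
    libs <- design$library_id[design$individual_id == id]
    if (length(libs) != 2)
      stop2("reads_among_replicates needs exactly 2 replicates; individual ",
            id, " has ", length(libs))
    k1 <- counts[, libs[1]]; k2 <- counts[, libs[2]]
    tot <- k1 + k2
    L1 <- sum(k1); L2 <- sum(k2)
    new1 <- stats::rbinom(length(tot), tot, L1 / (L1 + L2))
    out[, libs[1]] <- new1
    out[, libs[2]] <- tot - new1
  }
  out
}

#' Permutation p-values for the mean apportionment estimates
#'
#' Tests whether the transcriptome-wide mean of each variation statistic
#' exceeds its permutation null: mean Nst against individuals permuted
#' among groups, mean Nit against libraries permuted among individuals
#' within groups, and mean Net against reads pooled within individuals
#' and redistributed binomially between the replicate libraries (the
#' permuted counts are renormalized before refitting). P-values use the
#' add-one convention, `p = (1 + #{perm >= obs}) / (n_perm + 1)`.
#'
#' @param expr Normalized gene-by-library expression matrix.
#' @param design Library design.
#' @param counts Raw counts (required for the reads scheme).
#' @param n_perm Permutations per scheme.
#' @param seed RNG seed; the three schemes draw from independent
#'   sub-streams.
#' @param pseudocount Passed to [variance_stabilize()] when renormalizing
#'   permuted counts.
#' @return Named numeric vector `c(Nst = , Nit = , Net = )` with the
#'   observed means as an attribute.
#' @export
mean_apportionment_pvalues <- function(expr, design, counts,
                                       n_perm = 1000, seed = 1L,
                                       pseudocount = 1) {
  st <- perm_setup(expr, design)
  obs_ss <- simple_ss(st$Y, st$ind, st$grp, st$C)
  tot <- obs_ss$SS_A + obs_ss$SS_B + obs_ss$SS_e
  ok <- tot > 1e-12
  obs <- c(Nst = mean(obs_ss$SS_A[ok] / tot[ok]),
           Nit = mean(obs_ss$SS_B[ok] / tot[ok]),
           Net = mean(obs_ss$SS_e[ok] / tot[ok]))
  seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L, 3L))

  mean_nst <- with_seed(seeds[1], vapply(seq_len(n_perm), function(p) {
    new_grp_of_ind <- sample(st$grp_of_ind)
    grp_perm <- new_grp_of_ind[match(st$ind, st$inds)]
    ss <- simple_ss(st$Y, st$ind, grp_perm, st$C)
    t2 <- ss$SS_A + ss$SS_B + ss$SS_e
    mean((ss$SS_A / t2)[t2 > 1e-12])
  }, numeric(1)))

  mean_nit <- with_seed(seeds[2], vapply(seq_len(n_perm), function(p) {
    ind_perm <- permute_replicates_within_groups(st$ind, st$grp)
    ss <- simple_ss(st$Y, ind_perm, st$grp, st$C)
    t2 <- ss$SS_A + ss$SS_B + ss$SS_e
    mean((ss$SS_B / t2)[t2 > 1e-12])
  }, numeric(1)))

  mean_net <- with_seed(seeds[3], vapply(seq_len(n_perm), function(p) {
    cp <- permute_reads_among_replicates(counts, st$design)
    ep <- variance_stabilize(cp, size_factors(cp, pseudo_reference = TRUE),
                             pseudocount = pseudocount)
    ss <- simple_ss(t(ep), st$ind, st$grp, st$C)
    t2 <- ss$SS_A + ss$SS_B + ss$SS_e
    mean((ss$SS_e / t2)[t2 > 1e-12])
  }, numeric(1)))

  p <- c(Nst = (1 + sum(mean_nst >= obs["Nst"])) / (n_perm + 1),
         Nit = (1 + sum(mean_nit >= obs["Nit"])) / (n_perm + 1),
         Net = (1 + sum(mean_net >= obs["Net"])) / (n_perm + 1))
  attr(p, "observed") <- obs
  p
}

#' Pairwise differential-expression gene sets from permutation cutoffs
#'
#' For every pair of groups, computes the pair-specific Nst null
#' (individuals permuted among the two groups) and flags genes whose
#' observed pairwise Nst exceeds the null's 99th percentile. The union
#' over pairs is reported alongside the per-pair sets.
#'
#' @param expr Normalized gene-by-library expression matrix.
#' @param design Library design.
#' @param n_perm,genes_per_perm Permutation settings per pair.
#' @param seed RNG seed (per-pair sub-streams are derived from it).
#' @return List of class `pairwise_de` with per-pair `cutoff` and `genes`,
#'   plus the `union` character vector.
#' @export
de_genes_pairwise <- function(expr, design, n_perm = 1000,
                              genes_per_perm = 100, seed = 1L) {
  design <- assert_expr_design(expr, design)
  pw <- pairwise_apportionments(expr, design)
  seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L, length(pw)))
  pairs <- lapply(seq_along(pw), function(i) {
    p <- strsplit(names(pw)[i], ":", fixed = TRUE)[[1]]
    keep <- design$group %in% p
    nul <- null_nst(expr[, design$library_id[keep], drop = FALSE],
                    design[keep, , drop = FALSE],
                    n_perm = n_perm, genes_per_perm = genes_per_perm,
                    seed = seeds[i])
    tab <- pw[[i]]$table
    hit <- !is.na(tab$Nst) & tab$Nst > nul$cutoffs["p99"]
    list(cutoff = unname(nul$cutoffs["p99"]),
         genes = tab$gene_id[hit], null = nul)
  })
  names(pairs) <- names(pw)
  out <- list(pairs = pairs,
              union = sort(unique(unlist(lapply(pairs, `[[`, "genes")))))
  class(out) <- "pairwise_de"
  out
}

#' @export
print.pairwise_de <- function(x, ...) {
  cat("Pairwise permutation DE:\n")
  for (nm in names(x$pairs))
    cat(sprintf("  %-12s cutoff Nst > %.3f : %d genes\n", nm,
                x$pairs[[nm]]$cutoff, length(x$pairs[[nm]]$genes)))
  cat("  union:", length(x$union), "genes\n")
  invisible(x)
}
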