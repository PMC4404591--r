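## Nested model-II ANOVA apportionment of expression variation.
##
## Per gene the simple model is
##   y_ijk = mu + x + z + A_i + B_ij + e_ijk
## fitted as one sequential (type I) hierarchical ANOVA: technical
## covariates x (mapped reads) and z (RIN) first, then the nested strata
## among groups (A), among individuals within groups (B), and among
## replicates within individuals (e). Group and individual effects are
## random with variances sigma2_A, sigma2_B, sigma2_e. Sequential fitting
## makes the residual mean square an exactly unbiased estimate of
## sigma2_e; with no covariates the stratum SS reduce to the classical
## mean-based nested formulas.

## Sequential SS engine for the simple model. Y is libraries x genes;
## C a (possibly 0-column) matrix of standardized covariates. Returns
## per-gene SS for each covariate, the group and individual strata, and
## the residual, with their degrees of freedom.
simple_ss <- function(Y, individual, group, C = NULL) {
  n <- nrow(Y)
  grp <- factor(group)
  ind <- factor(individual)
  q <- if (is.null(C)) 0L else ncol(C)
  X <- cbind(rep(1, n), C,
             stats::model.matrix(~grp)[, -1, drop = FALSE],
             stats::model.matrix(~ind)[, -1, drop = FALSE])
  assign <- c(0L, rep(seq_len(q), length.out = q),
              rep(q + 1L, nlevels(grp) - 1L),
              rep(q + 2L, nlevels(ind) - 1L))
  qrX <- qr(X)
  r <- qrX$rank
  eff <- qr.qty(qrX, Y)
  term_of_row <- assign[qrX$pivot[seq_len(r)]]
  ss_term <- function(k) {
    rows <- which(term_of_row == k)
    if (!length(rows)) return(numeric(ncol(Y)))
    colSums(eff[rows, , drop = FALSE]^2)
  }
  SS_cov <- if (q) t(vapply(seq_len(q), ss_term, numeric(ncol(Y))))
            else matrix(0, 0, ncol(Y))
  if (q) rownames(SS_cov) <- colnames(C)
  resid_rows <- if (r < n) seq(r + 1L, n) else integer(0)
  list(SS_cov = SS_cov,
       SS_A = ss_term(q + 1L),
       SS_B = ss_term(q + 2L),
       SS_e = colSums(eff[resid_rows, , drop = FALSE]^2),
       df_A = sum(term_of_row == q + 1L),
       df_B = sum(term_of_row == q + 2L),
       df_e = n - r,
       n_cov = sum(term_of_row >= 1L & term_of_row <= q))
}

## Standardized covariate matrix for a design (constant columns map to 0).
covariate_matrix <- function(design, covariates) {
  if (!length(covariates)) return(NULL)
  C <- vapply(covariates, function(cv) standardize(design[[cv]]),
              numeric(nrow(design)))
  matrix(C, nrow(design), length(covariates),
         dimnames = list(NULL, covariates))
}

## Sokal-Rohlf style unbalanced nested EMS coefficients:
##   E[MS_e] = s2;  E[MS_B] = s2 + n0 * s2_B;
##   E[MS_A] = s2 + n0p * s2_B + nb * s2_A.
ems_coefficients <- function(n_ij, grp_of_ind) {
  n_ij <- as.vector(n_ij, mode = "numeric")
  grp <- as.character(grp_of_ind)
  N <- sum(n_ij)
  a <- length(unique(grp))
  B <- length(n_ij)
  n_i <- tapply(n_ij, grp, sum)
  S_i <- tapply(n_ij^2, grp, sum)
  n0 <- (N - sum(S_i / n_i)) / (B - a)
  n0p <- (sum(S_i / n_i) - sum(n_ij^2) / N) / (a - 1)
  nb <- (N - sum(n_i^2) / N) / (a - 1)
  c(n0 = n0, n0p = n0p, nb = nb)
}

#' Fit the simple nested model per gene
#'
#' Fits the hierarchical model as one sequential (type I) ANOVA — the
#' standardized technical covariates first, in the stated order, then
#' group, then individual within group — decomposing each gene's total
#' sum of squares into covariate terms, among-group (`SS_A`),
#' among-individual within-group (`SS_B`) and replicate/error (`SS_e`)
#' strata. Additive variance components are estimated via the expected
#' mean squares of the unbalanced nested design (negative estimates
#' truncated to zero). With no covariates, the stratum SS equal the
#' classical nested mean-based formulas exactly.
#'
#' @param expr Normalized gene-by-library expression matrix.
#' @param design Library design.
#' @param groups Optional subset of group labels to fit (covariates are
#'   refitted on the subset).
#' @param covariates Design columns removed before the nested
#'   decomposition, fitted in this order. Default mapped reads then RIN.
#' @return Object of class `simple_fit` with a per-gene `table` (SS, MS,
#'   variance components, mean expression, `defined` flag), the stratum
#'   degrees of freedom, and the EMS coefficients used.
#' @export
fit_simple_model <- function(expr, design, groups = NULL,
                             covariates = c("mapped_reads", "rin")) {
  if (is.null(covariates)) covariates <- character(0)
  design <- assert_expr_design(expr, design)
  if (!is.null(groups)) {
    keep <- design$group %in% groups
    if (!any(keep)) stop2("no libraries in requested groups")
    design <- design[keep, , drop = FALSE]
    expr <- expr[, design$library_id, drop = FALSE]
  }
  a <- length(unique(design$group))
  if (a < 2) stop2("need >= 2 groups")
  ind_per_grp <- tapply(design$individual_id, design$group,
                        function(x) length(unique(x)))
  if (any(ind_per_grp < 2))
    stop2("each group needs >= 2 individuals; offending group(s): ",
          paste(names(ind_per_grp)[ind_per_grp < 2], collapse = ", "))
  N <- nrow(design)
  B <- length(unique(design$individual_id))
  C <- covariate_matrix(design, covariates)
  ss <- simple_ss(t(expr), design$individual_id, design$group, C)
  if (ss$df_e < 1)
    stop2("no residual degrees of freedom: need replicate libraries")
  df <- c(A = ss$df_A, B = ss$df_B, e = ss$df_e)
  MS_A <- ss$SS_A / df["A"]
  MS_B <- ss$SS_B / df["B"]
  MS_e <- ss$SS_e / df["e"]
  n_ij <- table(design$individual_id)
  grp_of_ind <- tapply(design$group, design$individual_id, `[`, 1L)
  k <- ems_coefficients(n_ij, grp_of_ind)
  s2_e <- MS_e
  s2_B_raw <- (MS_B - MS_e) / k["n0"]
  s2_A_raw <- (MS_A - MS_e - k["n0p"] * s2_B_raw) / k["nb"]
  SS_T <- ss$SS_A + ss$SS_B + ss$SS_e
  defined <- SS_T > 1e-12
  tab <- data.frame(gene_id = rownames(expr),
                    mean_expr = rowMeans(expr),
                    SS_A = ss$SS_A, SS_B = ss$SS_B, SS_e = ss$SS_e, SS_T = SS_T,
                    MS_A = MS_A, MS_B = MS_B, MS_e = MS_e,
                    sigma2_A = pmax(s2_A_raw, 0),
                    sigma2_B = pmax(s2_B_raw, 0),
                    sigma2_e = s2_e,
                    defined = defined,
                    row.names = NULL, stringsAsFactors = FALSE)
  if (nrow(ss$SS_cov)) for (cv in rownames(ss$SS_cov))
    tab[[paste0("SS_", cv)]] <- ss$SS_cov[cv, ]
  out <- list(table = tab, df = df, ems = k,
              n_libraries = N, n_individuals = B,
              groups = sort(unique(design$group)),
              covariates = covariates,
              design = design)
  class(out) <- "simple_fit"
  out
}

#' @export
print.simple_fit <- function(x, ...) {
  cat("Nested model-II ANOVA fit:", nrow(x$table), "genes,",
      x$n_libraries, "libraries,", x$n_individuals, "individuals,",
      length(x$groups), "groups\n")
  cat("  df: A =", x$df["A"], " B =", x$df["B"], " e =", x$df["e"], "\n")
  cat("  EMS coefficients: n0 =", signif(x$ems["n0"], 4),
      " n0' =", signif(x$ems["n0p"], 4), " nb =", signif(x$ems["nb"], 4), "\n")
  invisible(x)
}

#' Apportionment statistics from a simple-model fit
#'
#' Sums-of-squares (variation) statistics: `Nst = SS_A/SS_T`,
#' `Nit = SS_B/SS_T`, `Net = SS_e/SS_T`, `Nis = SS_B/(SS_B+SS_e)`,
#' `Nig = SS_B/(SS_A+SS_B)`. Variance statistics from the additive
#' components: `Mst`, `Mit`, `Met` as each component's share of their sum.
#' Genes with zero total SS are flagged undefined (`NA` statistics).
#'
#' @param fit A [fit_simple_model()] result.
#' @return data.frame of class `apportionment_table`, one row per gene.
#' @export
apportion_statistics <- function(fit) {
  stopifnot(inherits(fit, "simple_fit"))
  t <- fit$table
  out <- data.frame(gene_id = t$gene_id, mean_expr = t$mean_expr,
                    stringsAsFactors = FALSE)
  den <- ifelse(t$defined, t$SS_T, NA_real_)
  out$Nst <- t$SS_A / den
  out$Nit <- t$SS_B / den
  out$Net <- t$SS_e / den
  out$Nis <- ifelse(t$SS_B + t$SS_e > 0, t$SS_B / (t$SS_B + t$SS_e), NA_real_)
  out$Nig <- ifelse(t$SS_A + t$SS_B > 0, t$SS_B / (t$SS_A + t$SS_B), NA_real_)
  msum <- t$sigma2_A + t$sigma2_B + t$sigma2_e
  mden <- ifelse(msum > 0, msum, NA_real_)
  out$Mst <- t$sigma2_A / mden
  out$Mit <- t$sigma2_B / mden
  out$Met <- t$sigma2_e / mden
  out$defined <- t$defined
  class(out) <- c("apportionment_table", "data.frame")
  attr(out, "groups") <- fit$groups
  out
}

#' Pairwise apportionment over all group pairs
#'
#' Refits the simple model (covariates included, refitted per subset) on
#' every pair of groups.
#'
#' @inheritParams fit_simple_model
#' @return Named list, one element per pair (`"G1:G2"`), each holding the
#'   `fit` and its apportionment `table`.
#' @export
pairwise_apportionments <- function(expr, design,
                                    covariates = c("mapped_reads", "rin")) {
  design <- assert_expr_design(expr, design)
  gs <- sort(unique(design$group))
  if (length(gs) < 2) stop2("need >= 2 groups")
  pairs <- utils::combn(gs, 2, simplify = FALSE)
  out <- lapply(pairs, function(p) {
    fit <- fit_simple_model(expr, design, groups = p, covariates = covariates)
    list(fit = fit, table = apportion_statistics(fit))
  })
  names(out) <- vapply(pairs, paste, "", collapse = ":")
  class(out) <- "pairwise_apportionment"
  out
}

#' Inter-individual differential-expression tests
#'
#' Three per-gene tests of among-individual variation: (1) the F-ratio
#' `MS_B / MS_e` on (df_B, df_e); (2) the inverted ratio `MS_e / MS_B`
#' probing excess intra-individual variation; (3) a Gaussian
#' likelihood-ratio comparison of the covariate-only model against the
#' model adding individual as a factor, referred to chi-squared on the
#' added degrees of freedom. All p-values are Benjamini-Hochberg adjusted
#' across genes, per test.
#'
#' @param fit A [fit_simple_model()] result.
#' @param fdr Significance level applied to the adjusted p-values.
#' @return data.frame of class `individual_de` with statistics, p-values,
#'   adjusted p-values and significance flags.
#' @export
individual_de_tests <- function(fit, fdr = 0.05) {
  stopifnot(inherits(fit, "simple_fit"))
  t <- fit$table
  df_B <- fit$df["B"]; df_e <- fit$df["e"]
  F_ind <- ifelse(t$defined & t$MS_e > 0, t$MS_B / t$MS_e, NA_real_)
  p_F <- stats::pf(F_ind, df_B, df_e, lower.tail = FALSE)
  F_inv <- ifelse(t$defined & t$MS_B > 0, t$MS_e / t$MS_B, NA_real_)
  p_inv <- stats::pf(F_inv, df_e, df_B, lower.tail = FALSE)
  RSS0 <- t$SS_A + t$SS_B + t$SS_e
  RSS1 <- t$SS_e
  N <- fit$n_libraries
  lrt <- ifelse(t$defined & RSS1 > 0, N * log(RSS0 / RSS1), NA_real_)
  df_lrt <- fit$n_individuals - 1L
  p_lrt <- stats::pchisq(lrt, df_lrt, lower.tail = FALSE)
  out <- data.frame(gene_id = t$gene_id,
                    F_individual = F_ind, p_F = p_F,
                    padj_F = stats::p.adjust(p_F, "BH"),
                    F_inverted = F_inv, p_inverted = p_inv,
                    padj_inverted = stats::p.adjust(p_inv, "BH"),
                    lrt = lrt, p_lrt = p_lrt,
                    padj_lrt = stats::p.adjust(p_lrt, "BH"),
                    stringsAsFactors = FALSE)
  out$sig_F <- !is.na(out$padj_F) & out$padj_F <= fdr
  out$sig_inverted <- !is.na(out$padj_inverted) & out$padj_inverted <= fdr
  out$sig_lrt <- !is.na(out$padj_lrt) & out$padj_lrt <= fdr
  attr(out, "fdr") <- fdr
  attr(out, "df") <- c(B = unname(df_B), e = unname(df_e), lrt = df_lrt)
  class(out) <- c("individual_de", "data.frame")
  out
}

#' Correlations of mean expression with apportionment components
#'
#' Pearson correlations of per-gene mean expression with each sum of
#' squares and each variation statistic, with r-squared shares.
#'
#' @param table An [apportion_statistics()] table.
#' @param fit The matching [fit_simple_model()] result.
#' @return data.frame, one row per (statistic, r, r2); r is `NA` where the
#'   correlation is undefined (constant input).
#' @export
mean_expression_diagnostics <- function(table, fit) {
  stopifnot(inherits(fit, "simple_fit"))
  if (nrow(table) < 10) stop2("need >= 10 genes for diagnostics")
  m <- table$mean_expr
  comp <- cbind(SS_A = fit$table$SS_A, SS_B = fit$table$SS_B,
                SS_e = fit$table$SS_e,
                Nst = table$Nst, Nit = table$Nit, Net = table$Net,
                Nis = table$Nis, Nig = table$Nig)
  safe_cor <- function(x, y) {
    ok <- is.finite(x) & is.finite(y)
    if (sum(ok) < 3 || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0)
      return(NA_real_)
    stats::cor(x[ok], y[ok])
  }
  r <- apply(comp, 2, safe_cor, x = m)
  data.frame(statistic = colnames(comp), r = r, r_squared = r^2,
             row.names = NULL, stringsAsFactors = FALSE)
}
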