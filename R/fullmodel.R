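## Full partially-nested model with biological traits:
##   y_ijk = mu + x + z + s + w + l + c + f + o + d + v + A_i + B_ij + e_ijk
## (no interactions). Variation is apportioned by sequential (type I) sums
## of squares in exactly this variable order, so the SS identity
## SS_T = SS_x + SS_z + ... + SS_B + SS_e holds per gene, and each
## factor's share is its eta-squared.

full_model_terms <- function() {
  c("mapped_reads", "rin", TRAIT_COLUMNS, "group", "individual")
}

#' Fit the full trait model per gene
#'
#' Sequential (type I) decomposition with technical covariates first, the
#' eight biological traits next (sex, weight, length, delivery manner,
#' maternal age, maternal BMI, alcohol, vegetarian), then group and
#' individual, then error. Per factor: eta-squared (`SS/SS_T`), an F test
#' of `MS_factor / MS_e`, Benjamini-Hochberg adjustment across genes, and
#' the sign of the fitted effect (slope for quantitative traits, level
#' contrast for binary ones). Constant traits are dropped with a warning
#' and carry zero SS.
#'
#' @param expr Normalized gene-by-library expression matrix
#'   (replicate-level).
#' @param design Library design including the trait columns.
#' @param fdr Significance level on adjusted p-values.
#' @return Object of class `full_fit` with per-gene matrices `ss`, `eta2`,
#'   `F`, `p`, `padj`, trait effect `sign`, the term degrees of freedom,
#'   and `SS_e`/`SS_T` vectors.
#' @export
fit_full_model <- function(expr, design, fdr = 0.05) {
  design <- assert_expr_design(expr, design)
  miss <- setdiff(TRAIT_COLUMNS, colnames(design))
  if (length(miss)) stop2("design lacks trait columns: ", paste(miss, collapse = ", "))
  n <- nrow(design)
  Y <- t(expr)

  terms <- full_model_terms()
  cols <- list(`(Intercept)` = matrix(1, n, 1))
  assign <- c(0L)
  dropped <- character()
  sign_cols <- integer()                 # index of the single column per trait
  for (k in seq_along(terms)) {
    tm <- terms[k]
    if (tm == "group") {
      f <- factor(design$group)
      mm <- stats::model.matrix(~f)[, -1, drop = FALSE]
    } else if (tm == "individual") {
      f <- factor(design$individual_id)
      mm <- stats::model.matrix(~f)[, -1, drop = FALSE]
    } else {
      v <- if (tm %in% c("mapped_reads", "rin")) standardize(design[[tm]])
           else trait_as_numeric(design[[tm]], tm)
      if (stats::sd(v) == 0) {
        warning("constant factor '", tm, "' dropped from full model")
        dropped <- c(dropped, tm)
        next
      }
      mm <- matrix(v, n, 1, dimnames = list(NULL, tm))
    }
    cols[[tm]] <- mm
    assign <- c(assign, rep(k, ncol(mm)))
  }
  X <- do.call(cbind, cols)
  qrX <- qr(X)
  r <- qrX$rank
  eff <- qr.qty(qrX, Y)
  term_of_row <- assign[qrX$pivot[seq_len(r)]]

  fitted_terms <- setdiff(terms, dropped)
  ss <- matrix(0, ncol(Y), length(terms),
               dimnames = list(colnames(Y), terms))
  dfs <- stats::setNames(integer(length(terms)), terms)
  for (k in seq_along(terms)) {
    rows <- which(term_of_row == k)
    dfs[k] <- length(rows)
    if (length(rows))
      ss[, k] <- colSums(eff[rows, , drop = FALSE]^2)
  }
  resid_rows <- if (r < n) seq(r + 1L, n) else integer(0)
  SS_e <- colSums(eff[resid_rows, , drop = FALSE]^2)
  df_e <- n - r
  if (df_e < 1) stop2("full model leaves no residual degrees of freedom")
  SS_T <- rowSums(ss) + SS_e
  eta2 <- cbind(ss, error = SS_e) / ifelse(SS_T > 0, SS_T, NA_real_)

  MS_e <- SS_e / df_e
  Fm <- pm <- padj <- matrix(NA_real_, ncol(Y), length(terms),
                             dimnames = dimnames(ss))
  for (k in seq_along(terms)) {
    if (dfs[k] == 0) next
    Fm[, k] <- (ss[, k] / dfs[k]) / MS_e
    pm[, k] <- stats::pf(Fm[, k], dfs[k], df_e, lower.tail = FALSE)
    padj[, k] <- stats::p.adjust(pm[, k], "BH")
  }

  ## trait effect directions from the full-model coefficients
  beta <- qr.coef(qrX, Y)
  rownames(beta) <- colnames(X)
  sgn <- matrix(NA_real_, ncol(Y), length(TRAIT_COLUMNS),
                dimnames = list(colnames(Y), TRAIT_COLUMNS))
  for (tm in TRAIT_COLUMNS) {
    if (tm %in% dropped || !tm %in% rownames(beta)) next
    sgn[, tm] <- sign(beta[tm, ])
  }

  out <- list(ss = ss, SS_e = SS_e, SS_T = SS_T, eta2 = eta2,
              F = Fm, p = pm, padj = padj, sign = sgn,
              df = c(dfs, error = df_e), fdr = fdr,
              terms = terms, dropped = dropped,
              gene_id = colnames(Y))
  class(out) <- "full_fit"
  out
}

#' @export
print.full_fit <- function(x, ...) {
  cat("Full trait model:", length(x$gene_id), "genes,",
      length(x$terms) - length(x$dropped), "fitted factors",
      if (length(x$dropped)) paste0("(dropped: ",
                                    paste(x$dropped, collapse = ", "), ")"),
      "\n")
  sh <- colMeans(x$eta2, na.rm = TRUE)
  cat("  mean eta-squared shares:\n")
  print(round(sh, 3))
  invisible(x)
}

#' Partition a trait's significant genes by effect direction
#'
#' Splits the genes significant for a trait (BH-adjusted p at the fit's
#' FDR) into those whose expression increases with the trait and those
#' whose expression decreases; the two sets are disjoint and their union
#' is the significant set.
#'
#' @param full A [fit_full_model()] result.
#' @param trait One of the eight trait names.
#' @return List with character vectors `increasing` and `decreasing`.
#' @export
trait_direction_partition <- function(full, trait) {
  stopifnot(inherits(full, "full_fit"))
  if (!trait %in% TRAIT_COLUMNS) stop2("unknown trait: ", trait)
  if (trait %in% full$dropped) stop2("trait '", trait, "' was not fitted")
  sig <- !is.na(full$padj[, trait]) & full$padj[, trait] <= full$fdr
  s <- full$sign[, trait]
  list(increasing = full$gene_id[sig & !is.na(s) & s > 0],
       decreasing = full$gene_id[sig & !is.na(s) & s <= 0])
}
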