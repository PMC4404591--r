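# Shared fixture builders. Everything is generated in code; no files.

# A balanced library design with inert (constant) technical covariates,
# so toy expression values pass through residualization unchanged except
# for grand-mean centering.
make_design <- function(a = 2, b = 2, n = 2, constant_covariates = TRUE,
                        seed = 1L) {
  N <- a * b * n
  design <- data.frame(
    library_id = sprintf("L%03d", seq_len(N)),
    individual_id = rep(sprintf("I%03d", seq_len(a * b)), each = n),
    group = rep(paste0("G", seq_len(a)), each = b * n),
    stringsAsFactors = FALSE)
  if (constant_covariates) {
    design$mapped_reads <- 1e6
    design$rin <- 8
  } else {
    set.seed(seed)
    design$mapped_reads <- round(runif(N, 1e6, 2e6))
    design$rin <- round(runif(N, 6.5, 9.9), 1)
  }
  design
}

# Expression matrix for a design from per-library values (one gene per row).
make_expr <- function(values, design, gene_ids = NULL) {
  m <- matrix(values, ncol = nrow(design), byrow = TRUE)
  rownames(m) <- gene_ids %||% sprintf("g%03d", seq_len(nrow(m)))
  colnames(m) <- design$library_id
  m
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent oracle for the nested decomposition: residualize covariates
# with lm(), then accumulate sums of squares by explicit loops over
# group / individual / replicate means.
brute_force_ss <- function(y, design, covariates = character(0)) {
  if (length(covariates)) {
    X <- data.frame(y = y)
    for (cv in covariates) {
      v <- design[[cv]]
      X[[cv]] <- if (sd(v) > 0) as.vector(scale(v)) else rep(0, length(v))
    }
    fit0 <- lm(stats::reformulate(covariates, "y"), data = X)
    r <- resid(fit0)
  } else r <- y
  gbar <- mean(r)
  SS_A <- 0; SS_B <- 0; SS_e <- 0
  for (g in unique(design$group)) {
    ig <- design$group == g
    gm <- mean(r[ig])
    SS_A <- SS_A + sum(ig) * (gm - gbar)^2
    for (id in unique(design$individual_id[ig])) {
      ii <- design$individual_id == id
      im <- mean(r[ii])
      SS_B <- SS_B + sum(ii) * (im - gm)^2
      SS_e <- SS_e + sum((r[ii] - im)^2)
    }
  }
  c(SS_A = SS_A, SS_B = SS_B, SS_e = SS_e)
}

# Random unbalanced nested design: groups of unequal individual counts,
# individuals with unequal replicate counts.
random_design <- function(seed) {
  set.seed(seed)
  a <- sample(2:4, 1)
  rows <- list()
  ind <- 0L
  for (g in seq_len(a)) {
    b <- sample(2:5, 1)
    for (j in seq_len(b)) {
      ind <- ind + 1L
      n <- sample(2:3, 1)
      rows[[length(rows) + 1L]] <- data.frame(
        individual_id = sprintf("I%03d", ind),
        group = paste0("G", g), n = n, stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  design <- tab[rep(seq_len(nrow(tab)), tab$n), c("individual_id", "group")]
  design$library_id <- sprintf("L%03d", seq_len(nrow(design)))
  design$mapped_reads <- round(runif(nrow(design), 1e6, 2e6))
  design$rin <- round(runif(nrow(design), 6.5, 9.9), 1)
  rownames(design) <- NULL
  design
}

# Small simulated dataset under scalar variance components; deep libraries
# and low dispersion keep the count layer close to the latent values.
quick_dataset <- function(n_genes = 200, s2A = 0.02, s2B = 0.15, s2e = 0.08,
                          seed = 1L, regimes = list(), deep = TRUE, ...) {
  cfg <- simulation_config(
    n_genes = n_genes, sigma2_A = s2A, sigma2_B = s2B, sigma2_e = s2e,
    baseline_log_mean_range = if (deep) c(10, 14) else c(2, 9),
    nb_dispersion_model = if (deep) function(mu) 0.001 + 0.5 / mu
                          else function(mu) 0.05 + 2 / mu,
    seed = seed, ...)
  generate_dataset(cfg, regimes)
}
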