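## Synthetic hierarchical RNA-seq experiments with known variance
## components. The generator mirrors the replicate-aware study design the
## package targets: groups of individuals, each individual sequenced as
## two dissection-replicate libraries, counts negative binomial around a
## latent log2 expression built from group / individual / replicate
## effects plus small technical terms.

#' Simulation configuration
#'
#' Defaults emulate the kind of experiment the apportionment model was
#' built for: 4 groups x 10 individuals x 2 replicate libraries,
#' 13,156 genes, library depths around 1.5 million mapped reads, RIN
#' values in the high-quality range, and per-gene variance components
#' drawn log-normally with medians (0.02, 0.15, 0.08) squared-log2 units
#' for the group / individual / replicate levels, so the implied mean
#' apportionment sits near (0.08, 0.60, 0.32). Technical coefficients
#' default to explaining roughly 2% of latent variance each.
#'
#' @param n_groups,n_individuals_per_group,n_replicates Design counts.
#' @param n_genes Number of genes.
#' @param baseline_log_mean_range Range (log2 expected counts at the
#'   reference depth) from which per-gene baselines are drawn uniformly.
#' @param sigma2_A,sigma2_B,sigma2_e Per-gene variance components
#'   (squared log2 units): a scalar, a function of `n` returning `n`
#'   draws, or a function of `(n, mu)` receiving the per-gene baseline
#'   log2 means (to couple variance to expression level).
#' @param nb_dispersion_model Function mapping mean count to negative
#'   binomial dispersion; the default `0.05 + 2/mean` gives typical bulk
#'   RNA-seq overdispersion with a Poisson-excess term at low counts.
#' @param library_size_range Integer range of mapped reads per library.
#' @param rin_range Range of RNA integrity numbers.
#' @param beta_mapped_reads,beta_rin Latent log2 effect per standard
#'   deviation of log library size / RIN.
#' @param trait_effects Optional list of lists with elements `trait`
#'   (name), `fraction` (of genes affected), and `effect_sd` (sd of the
#'   per-gene slope on the standardized trait).
#' @param seed Integer seed; the dataset is a pure function of
#'   (config, regimes).
#' @return Object of class `sim_config`.
#' @export
simulation_config <- function(n_groups = 4, n_individuals_per_group = 10,
                              n_replicates = 2, n_genes = 13156,
                              baseline_log_mean_range = c(2, 9),
                              sigma2_A = function(n) stats::rlnorm(n, log(0.02), 1),
                              sigma2_B = function(n) stats::rlnorm(n, log(0.15), 1),
                              sigma2_e = function(n) stats::rlnorm(n, log(0.08), 1),
                              nb_dispersion_model = function(mu) 0.05 + 2 / mu,
                              library_size_range = c(1e6, 2e6),
                              rin_range = c(6.5, 9.9),
                              beta_mapped_reads = 0.07, beta_rin = 0.07,
                              trait_effects = NULL,
                              seed = 1L) {
  stopifnot(n_groups >= 1, n_individuals_per_group >= 1, n_replicates >= 1,
            n_genes >= 1,
            length(baseline_log_mean_range) == 2,
            diff(baseline_log_mean_range) >= 0,
            length(library_size_range) == 2, all(library_size_range > 0),
            length(rin_range) == 2, all(rin_range > 0),
            is.function(nb_dispersion_model))
  for (s2 in list(sigma2_A, sigma2_B, sigma2_e))
    if (!is.function(s2) && (!is.numeric(s2) || any(s2 < 0)))
      stop2("variance components must be non-negative scalars or functions")
  if (!is.null(trait_effects))
    for (te in trait_effects) {
      if (is.null(te$trait) || is.null(te$fraction) || is.null(te$effect_sd))
        stop2("each trait effect needs 'trait', 'fraction', 'effect_sd'")
      if (te$fraction < 0 || te$fraction > 1)
        stop2("trait-effect fraction must lie in [0, 1]")
    }
  out <- as.list(environment())
  class(out) <- "sim_config"
  out
}

#' Selection regime for injected genes
#'
#' Regimes partition disjoint blocks of gene indices and perturb the
#' generative parameters: `directional` adds fixed per-group shifts to the
#' latent mean; `balancing` pins sigma2_A to 0 and multiplies sigma2_B;
#' `stabilizing` shrinks sigma2_B and sigma2_e; `diversifying` inflates
#' sigma2_B.
#'
#' @param mode One of `"directional"`, `"balancing"`, `"stabilizing"`,
#'   `"diversifying"`, `"neutral"`.
#' @param n_genes Number of genes under the regime.
#' @param shift Directional per-group shifts (log2 units), recycled to
#'   the number of groups.
#' @param factor Multiplier applied by the variance-modifying modes.
#' @return Object of class `selection_regime`.
#' @export
selection_regime <- function(mode = c("directional", "balancing",
                                      "stabilizing", "diversifying",
                                      "neutral"),
                             n_genes,
                             shift = c(0, 0, 0, 2),
                             factor = switch(match.arg(mode),
                                             balancing = 4,
                                             stabilizing = 0.1,
                                             diversifying = 6, 1)) {
  mode <- match.arg(mode)
  stopifnot(n_genes >= 1, factor >= 0)
  out <- list(mode = mode, n_genes = n_genes, shift = shift, factor = factor)
  class(out) <- "selection_regime"
  out
}

#' Generate a synthetic hierarchical RNA-seq dataset
#'
#' Per gene g, draws group effects `A_i ~ N(0, sigma2_A)`, individual
#' effects `B_ij ~ N(0, sigma2_B)` and replicate noise
#' `e_ijk ~ N(0, sigma2_e)`; the latent log2 expression is
#' `mu_g + A + B + e` plus the technical terms (coefficients times
#' standardized log library size and standardized RIN). Counts are
#' negative binomial with mean `2^latent * depth_j / mean(depth)` and
#' dispersion from the configured model (`dispersion == 0` is the Poisson
#' limit; negative dispersion is an error naming the gene and mean).
#' Regime blocks occupy consecutive gene indices from gene 1.
#'
#' @param config A [simulation_config()].
#' @param regimes List of [selection_regime()] objects; their total gene
#'   count must fit within `n_genes`.
#' @return Object of class `synthetic_dataset`: integer `counts`, the
#'   library `design` (with traits), the per-gene `truth` table (variance
#'   components, regime, expected Mst/Mit/Met), the noise-free `latent`
#'   matrix, and the echoed config.
#' @export
generate_dataset <- function(config, regimes = list()) {
  stopifnot(inherits(config, "sim_config"))
  n_reg <- sum(vapply(regimes, function(r) r$n_genes, numeric(1)))
  if (n_reg > config$n_genes) stop2("regimes exceed n_genes")
  a <- config$n_groups; b <- config$n_individuals_per_group
  n <- config$n_replicates; G <- config$n_genes
  N <- a * b * n
  with_seed(config$seed, {
    groups <- paste0("G", seq_len(a))
    design <- data.frame(
      library_id = sprintf("L%03d", seq_len(N)),
      individual_id = rep(sprintf("I%03d", seq_len(a * b)), each = n),
      group = rep(groups, each = b * n),
      stringsAsFactors = FALSE)
    design$mapped_reads <- round(stats::runif(N, config$library_size_range[1],
                                              config$library_size_range[2]))
    design$rin <- round(stats::runif(N, config$rin_range[1],
                                     config$rin_range[2]), 1)
    ## individual-level biological traits, repeated across replicates
    nind <- a * b
    ind_traits <- data.frame(
      individual_id = sprintf("I%03d", seq_len(nind)),
      sex = sample(c("F", "M"), nind, replace = TRUE),
      weight = round(stats::rnorm(nind, 3.4, 0.5), 2),
      length = round(stats::rnorm(nind, 50, 2.5), 1),
      delivery = sample(c("cesarean", "vaginal"), nind, replace = TRUE),
      maternal_age = round(stats::runif(nind, 19, 42)),
      bmi = round(stats::rnorm(nind, 24, 4), 1),
      alcohol = stats::rbinom(nind, 1, 0.3),
      vegetarian = stats::rbinom(nind, 1, 0.15),
      stringsAsFactors = FALSE)
    design <- merge(design, ind_traits, by = "individual_id", sort = FALSE)
    design <- design[order(design$library_id),
                     c("library_id", "individual_id", "group", "mapped_reads",
                       "rin", unname(TRAIT_COLUMNS))]
    rownames(design) <- NULL

    mu <- stats::runif(G, config$baseline_log_mean_range[1],
                       config$baseline_log_mean_range[2])
    ## a component may be a scalar, a function of n (draws across genes),
    ## or a function of (n, mu) coupling variance to baseline expression
    draw <- function(s2) {
      if (!is.function(s2)) return(rep(s2, G))
      if (length(formals(s2)) >= 2) s2(G, mu) else s2(G)
    }
    s2A <- draw(config$sigma2_A)
    s2B <- draw(config$sigma2_B)
    s2e <- draw(config$sigma2_e)

    regime <- rep("neutral", G)
    shifts <- matrix(0, G, a)
    idx <- 1L
    for (r in regimes) {
      rows <- seq(idx, idx + r$n_genes - 1L)
      idx <- idx + r$n_genes
      regime[rows] <- r$mode
      if (r$mode == "directional") {
        shifts[rows, ] <- matrix(rep_len(r$shift, a), length(rows), a,
                                 byrow = TRUE)
      } else if (r$mode == "balancing") {
        s2A[rows] <- 0
        s2B[rows] <- s2B[rows] * r$factor
      } else if (r$mode == "stabilizing") {
        s2B[rows] <- s2B[rows] * r$factor
        s2e[rows] <- s2e[rows] * r$factor
      } else if (r$mode == "diversifying") {
        s2B[rows] <- s2B[rows] * r$factor
      }
    }

    grp_idx <- match(design$group, groups)            # length N
    ind_idx <- match(design$individual_id, unique(design$individual_id))
    sx <- standardize(log(design$mapped_reads))
    sz <- standardize(design$rin)
    tech <- config$beta_mapped_reads * sx + config$beta_rin * sz

    A <- matrix(stats::rnorm(G * a), G, a) * sqrt(s2A) + shifts
    B <- matrix(stats::rnorm(G * nind), G, nind) * sqrt(s2B)
    E <- matrix(stats::rnorm(G * N), G, N) * sqrt(s2e)
    latent <- mu + A[, grp_idx, drop = FALSE] + B[, ind_idx, drop = FALSE] +
      E + matrix(tech, G, N, byrow = TRUE)

    ## optional per-gene trait effects on the latent scale
    if (!is.null(config$trait_effects)) for (te in config$trait_effects) {
      tv <- standardize(trait_as_numeric(design[[te$trait]], te$trait))
      hit <- which(regime == "neutral")
      hit <- hit[seq_len(min(length(hit), floor(te$fraction * G)))]
      slope <- stats::rnorm(length(hit), 0, te$effect_sd)
      latent[hit, ] <- latent[hit, ] + outer(slope, tv)
      attr(latent, paste0("trait_genes_", te$trait)) <- hit
      attr(latent, paste0("trait_slopes_", te$trait)) <- slope
    }

    depth <- design$mapped_reads / mean(design$mapped_reads)
    mu_count <- 2^latent * rep(depth, each = G)
    phi <- config$nb_dispersion_model(mu_count)
    if (any(phi < 0)) {
      bad <- which(phi < 0, arr.ind = TRUE)[1, ]
      stop2("non-positive dispersion for gene ", bad[1],
            " at mean ", signif(mu_count[bad[1], bad[2]], 4))
    }
    counts <- matrix(0L, G, N)
    pois <- phi == 0
    counts[pois] <- stats::rpois(sum(pois), mu_count[pois])
    if (any(!pois))
      counts[!pois] <- stats::rnbinom(sum(!pois), mu = mu_count[!pois],
                                      size = 1 / phi[!pois])
    storage.mode(counts) <- "integer"
    gene_ids <- sprintf("gene%05d", seq_len(G))
    dimnames(counts) <- dimnames(latent) <- list(gene_ids, design$library_id)

    tot <- s2A + s2B + s2e
    truth <- data.frame(gene_id = gene_ids, mu = mu,
                        sigma2_A = s2A, sigma2_B = s2B, sigma2_e = s2e,
                        regime = regime,
                        Mst_expected = ifelse(tot > 0, s2A / tot, NA_real_),
                        Mit_expected = ifelse(tot > 0, s2B / tot, NA_real_),
                        Met_expected = ifelse(tot > 0, s2e / tot, NA_real_),
                        stringsAsFactors = FALSE)
    out <- list(counts = counts, design = design, truth = truth,
                latent = latent, config = config, regimes = regimes,
                seed = config$seed)
    class(out) <- "synthetic_dataset"
    out
  })
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("Synthetic dataset:", nrow(x$counts), "genes x", ncol(x$counts),
      "libraries (", x$config$n_groups, "groups x",
      x$config$n_individuals_per_group, "individuals x",
      x$config$n_replicates, "replicates), seed", x$seed, "\n")
  print(table(x$truth$regime))
  invisible(x)
}

#' Write a synthetic dataset as plain-text fixtures
#'
#' Writes `counts.tsv`, `design.tsv`, `truth.tsv` and `config.yaml` into a
#' directory; the files round-trip losslessly through [read_counts()] and
#' [read_design()], and regeneration under the same seed reproduces them
#' byte-identically.
#'
#' @param dataset A [generate_dataset()] result.
#' @param directory Output directory (created if needed).
#' @param overwrite Refuse to clobber existing files unless `TRUE`.
#' @return Invisibly, the written file paths.
#' @export
export_fixture <- function(dataset, directory, overwrite = FALSE) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(directory, c("counts.tsv", "design.tsv", "truth.tsv",
                                  "config.yaml"))
  if (!overwrite && any(file.exists(paths)))
    stop2("refusing to overwrite existing fixture files in ", directory,
          " (set overwrite = TRUE)")
  cnt <- data.frame(gene_id = rownames(dataset$counts), dataset$counts,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(cnt, paths[1], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(dataset$design, paths[2], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(dataset$truth, paths[3], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  cfg <- dataset$config
  echo <- lapply(cfg[setdiff(names(cfg), c("sigma2_A", "sigma2_B", "sigma2_e",
                                           "nb_dispersion_model",
                                           "trait_effects"))],
                 function(v) if (is.numeric(v)) as.vector(v) else v)
  echo$variance_components <- "see truth.tsv (per-gene draws)"
  yaml::write_yaml(echo, paths[4])
  invisible(paths)
}
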