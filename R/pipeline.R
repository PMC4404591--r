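## End-to-end pipeline: simulate or ingest, QC, apportion, permutation
## nulls, selection calls, structure analyses, with seeded reproducibility
## and a machine-readable manifest.

#' Validate a pipeline configuration
#'
#' A configuration is a list (or YAML file) with exactly one of an
#' `input` block (`counts`, `design` paths) or a `simulate` block
#' (arguments for [simulation_config()] plus an optional `regimes` list),
#' an `output` directory, a master `seed`, and optional blocks
#' `normalization` (`pseudocount`), `qc` (`drop_unpaired`),
#' `permutation` (`n_perm`, `genes_per_perm`, `mean_n_perm`),
#' `selection` (`n_artificial`), `analysis` (`fdr`, `n_pcs`, `kmeans_k`,
#' `full_model`, `pairwise_de`, `mean_pvalues`).
#'
#' @param config List or path to a YAML file.
#' @return The validated, default-filled config list.
#' @export
validate_pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  if (!is.list(config)) stop2("config must be a list or YAML path")
  has_input <- !is.null(config$input)
  has_sim <- !is.null(config$simulate)
  if (has_input == has_sim)
    stop2("config must contain exactly one of 'input' or 'simulate'")
  if (is.null(config$output)) stop2("config needs an 'output' directory")
  config$seed <- as.integer(config$seed %||% 1L)
  nz <- config$normalization %||% list()
  config$normalization <- list(pseudocount = nz$pseudocount %||% 1)
  qc <- config$qc %||% list()
  config$qc <- list(drop_unpaired = isTRUE(qc$drop_unpaired %||% TRUE))
  pm <- config$permutation %||% list()
  config$permutation <- list(n_perm = pm$n_perm %||% 1000,
                             genes_per_perm = pm$genes_per_perm %||% 100,
                             mean_n_perm = pm$mean_n_perm %||% 200)
  sl <- config$selection %||% list()
  config$selection <- list(n_artificial = sl$n_artificial %||% 10000)
  an <- config$analysis %||% list()
  config$analysis <- list(fdr = an$fdr %||% 0.05,
                          n_pcs = an$n_pcs %||% 5,
                          kmeans_k = an$kmeans_k %||% 2,
                          full_model = isTRUE(an$full_model %||% TRUE),
                          pairwise_de = isTRUE(an$pairwise_de %||% TRUE),
                          mean_pvalues = isTRUE(an$mean_pvalues %||% FALSE))
  config
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

## Load a cached permutation null or compute and cache it. Caching is
## keyed by (scheme, seed, n_perm, genes_per_perm) so re-runs resume.
cached_null <- function(fun, scheme, dir, expr, design, n_perm,
                        genes_per_perm, seed) {
  key <- sprintf("%s_seed%d_perm%d_genes%d.tsv", scheme, seed, n_perm,
                 genes_per_perm)
  path <- file.path(dir, key)
  if (file.exists(path)) {
    vals <- utils::read.delim(path)$value
    return(new_null_distribution(scheme,
                                 if (scheme == "individuals_among_groups")
                                   "Nst" else "Nig",
                                 vals, n_perm, genes_per_perm, seed))
  }
  nul <- fun(expr, design, n_perm = n_perm, genes_per_perm = genes_per_perm,
             seed = seed)
  write_tsv(data.frame(value = nul$values), path)
  nul
}

#' Run the full apportionment pipeline
#'
#' Executes: simulate-or-ingest, normalization, replicate QC (optionally
#' dropping unpaired individuals), the simple-model apportionment (all
#' groups and pairwise), inter-individual DE tests, the full trait model
#' (when traits are present), the permutation nulls, selection-profile
#' classification, and the structure analyses (PCA + trait screen,
#' population distance tree, k-means on directional genes). All tables
#' are written as TSV under the output directory together with a YAML
#' manifest recording parameters, per-stage seeds and file checksums.
#'
#' @param config List or YAML path; see [validate_pipeline_config()].
#' @return Invisibly, a result bundle with all in-memory objects and the
#'   manifest.
#' @export
run_pipeline <- function(config) {
  config <- validate_pipeline_config(config)
  out_dir <- config$output
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  null_dir <- file.path(out_dir, "nulls")
  dir.create(null_dir, showWarnings = FALSE)
  seeds <- with_seed(config$seed,
                     sample.int(.Machine$integer.max - 1L, 8L))
  names(seeds) <- c("simulate", "null_nst", "null_nig", "mean_p",
                    "artificial", "kmeans", "pairwise_de", "spare")
  stages <- character()
  t0 <- Sys.time()
  log_stage <- function(name, detail = "") {
    stages <<- c(stages, name)
    message(sprintf("[%s] %s %s", format(Sys.time(), "%H:%M:%S"), name,
                    detail))
  }
  run_stage <- function(name, code, detail = "") {
    log_stage(name, detail)
    tryCatch(code, error = function(e)
      stop2("pipeline stage '", name, "' failed: ", conditionMessage(e),
            "; completed stages: ", paste(stages, collapse = " -> ")))
  }

  ## --- data ---------------------------------------------------------
  dataset <- NULL
  if (!is.null(config$simulate)) {
    sim <- config$simulate
    regimes <- lapply(sim$regimes %||% list(), function(r)
      selection_regime(mode = r$mode, n_genes = r$n_genes,
                       shift = r$shift %||% c(0, 0, 0, 2),
                       factor = r$factor %||%
                         switch(r$mode, balancing = 4, stabilizing = 0.1,
                                diversifying = 6, 1)))
    sim$regimes <- NULL
    sim$seed <- sim$seed %||% seeds["simulate"]
    cfg <- run_stage("simulate", do.call(simulation_config, sim))
    dataset <- generate_dataset(cfg, regimes)
    counts <- dataset$counts
    design <- dataset$design
    write_tsv(dataset$truth, file.path(out_dir, "truth.tsv"))
  } else {
    counts <- run_stage("ingest", read_counts(config$input$counts))
    design <- read_design(config$input$design, counts)
  }

  ## --- normalization + QC -------------------------------------------
  expr <- run_stage("normalize", variance_stabilize(
    counts, size_factors(counts, pseudo_reference = TRUE),
    pseudocount = config$normalization$pseudocount))
  qc <- run_stage("replicate_qc", replicate_qc(expr, design))
  write_tsv(data.frame(individual_id = names(qc$paired), paired = qc$paired),
            file.path(out_dir, "replicate_qc.tsv"))
  writeLines(ape::write.tree(ape::as.phylo(qc$tree)),
             file.path(out_dir, "library_tree.nwk"))
  if (config$qc$drop_unpaired && length(qc$dropped)) {
    flt <- drop_unpaired(counts, design, qc)
    counts <- flt$counts; design <- flt$design
    expr <- variance_stabilize(counts,
                               size_factors(counts, pseudo_reference = TRUE),
                               pseudocount = config$normalization$pseudocount)
  }

  ## --- apportionment ------------------------------------------------
  fit <- run_stage("apportion", fit_simple_model(expr, design))
  apport <- apportion_statistics(fit)
  write_tsv(cbind(fit$table[, c("gene_id", "mean_expr", "SS_A", "SS_B",
                                "SS_e", "SS_T", "sigma2_A", "sigma2_B",
                                "sigma2_e")],
                  apport[, c("Nst", "Nit", "Net", "Nis", "Nig",
                             "Mst", "Mit", "Met")]),
            file.path(out_dir, "apportionment.tsv"))
  pw <- run_stage("pairwise", pairwise_apportionments(expr, design))
  de_ind <- run_stage("individual_de",
                      individual_de_tests(fit, fdr = config$analysis$fdr))
  write_tsv(de_ind, file.path(out_dir, "individual_de.tsv"))

  full <- NULL
  if (config$analysis$full_model &&
      all(TRAIT_COLUMNS %in% colnames(design))) {
    full <- run_stage("full_model",
                      fit_full_model(expr, design, fdr = config$analysis$fdr))
    write_tsv(data.frame(gene_id = full$gene_id, full$eta2,
                         check.names = FALSE),
              file.path(out_dir, "full_model_eta2.tsv"))
  }

  ## --- permutation nulls --------------------------------------------
  np <- config$permutation
  nst_null <- run_stage("null_nst", cached_null(
    null_nst, "individuals_among_groups", null_dir, expr, design,
    np$n_perm, np$genes_per_perm, seeds["null_nst"]))
  nig_null <- run_stage("null_nig", cached_null(
    null_nig, "replicates_within_groups", null_dir, expr, design,
    np$n_perm, np$genes_per_perm, seeds["null_nig"]))
  mean_p <- NULL
  if (config$analysis$mean_pvalues)
    mean_p <- run_stage("mean_pvalues", mean_apportionment_pvalues(
      expr, design, counts, n_perm = np$mean_n_perm, seed = seeds["mean_p"]))
  pde <- NULL
  if (config$analysis$pairwise_de)
    pde <- run_stage("pairwise_de", de_genes_pairwise(
      expr, design, n_perm = np$n_perm, genes_per_perm = np$genes_per_perm,
      seed = seeds["pairwise_de"]))

  ## --- selection ----------------------------------------------------
  ind_counts <- sum_replicates(counts, design)
  expr_ind <- variance_stabilize(ind_counts,
                                 size_factors(ind_counts,
                                              pseudo_reference = TRUE),
                                 pseudocount = config$normalization$pseudocount)
  ind_design <- individual_design(design)
  var_null <- run_stage("artificial_null", artificial_gene_null(
    expr_ind, n = config$selection$n_artificial, seed = seeds["artificial"]))
  calls <- run_stage("classify", classify_selection(
    apport, nst_null, nig_null, var_null, expr_ind))
  write_tsv(calls, file.path(out_dir, "selection_calls.tsv"))

  ## --- structure ----------------------------------------------------
  pca <- run_stage("pca", pca_individuals(expr_ind,
                                          n_pcs = config$analysis$n_pcs))
  pct <- pc_trait_correlations(pca, ind_design,
                               n_pcs = config$analysis$n_pcs)
  write_tsv(pct, file.path(out_dir, "pc_trait_correlations.tsv"))
  ptree <- run_stage("population_tree", population_distance_tree(pw))
  writeLines(ptree$newick, file.path(out_dir, "population_tree.nwk"))
  dir_genes <- calls$gene_id[calls$directional]
  dstruct <- NULL
  km <- NULL
  if (length(dir_genes) >= 2) {
    dstruct <- run_stage("directional_structure", directional_structure_check(
      expr_ind, ind_design, dir_genes))
    writeLines(dstruct$newick, file.path(out_dir, "directional_tree.nwk"))
    if (length(dir_genes) >= config$analysis$kmeans_k)
      km <- run_stage("kmeans", kmeans_profiles(
        expr_ind, ind_design, dir_genes, k = config$analysis$kmeans_k,
        seed = seeds["kmeans"]))
  }

  ## --- manifest -----------------------------------------------------
  files <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
  files <- files[!grepl("manifest[.]yaml$", files)]
  manifest <- list(
    package_version = as.character(utils::packageVersion("apportionr")),
    master_seed = config$seed,
    stage_seeds = as.list(stats::setNames(as.integer(seeds), names(seeds))),
    stages = stages,
    n_genes = nrow(counts), n_libraries = ncol(counts),
    n_individuals = length(unique(design$individual_id)),
    groups = sort(unique(design$group)),
    parameters = config[c("normalization", "qc", "permutation", "selection",
                          "analysis")],
    elapsed_seconds = round(as.numeric(difftime(Sys.time(), t0,
                                                units = "secs")), 2),
    checksums = as.list(stats::setNames(unname(tools::md5sum(files)),
                                        basename(files))))
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))

  invisible(list(counts = counts, design = design, expr = expr, qc = qc,
                 fit = fit, apportionment = apport, pairwise = pw,
                 individual_de = de_ind, full_model = full,
                 nst_null = nst_null, nig_null = nig_null,
                 mean_pvalues = mean_p, pairwise_de = pde,
                 expr_by_individual = expr_ind, var_null = var_null,
                 selection = calls, pca = pca, pc_traits = pct,
                 population_tree = ptree, directional_structure = dstruct,
                 kmeans = km, manifest = manifest, dataset = dataset))
}
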