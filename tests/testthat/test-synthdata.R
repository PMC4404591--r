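test_that("generation is a pure function of config and seed", {
  d1 <- quick_dataset(n_genes = 40, seed = 11)
  d2 <- quick_dataset(n_genes = 40, seed = 11)
  d3 <- quick_dataset(n_genes = 40, seed = 12)
  expect_identical(d1$counts, d2$counts)
  expect_identical(d1$design, d2$design)
  expect_identical(d1$truth, d2$truth)
  expect_false(identical(d1$counts, d3$counts))
})

test_that("all variance sources off yields identical latent means per gene", {
  cfg <- simulation_config(n_genes = 10, sigma2_A = 0, sigma2_B = 0,
                           sigma2_e = 0, beta_mapped_reads = 0, beta_rin = 0,
                           nb_dispersion_model = function(mu) mu * 0,
                           baseline_log_mean_range = c(5, 8), seed = 3)
  ds <- generate_dataset(cfg)
  expect_true(all(apply(ds$latent, 1, sd) == 0))
  expect_true(all(ds$counts >= 0))
  expect_true(all(ds$counts == round(ds$counts)))
})

test_that("latent variance decomposition matches the configured components", {
  ds <- quick_dataset(n_genes = 1500, seed = 21, beta_mapped_reads = 0,
                      beta_rin = 0)
  # oracle: direct nested decomposition of the latent values (no counts)
  ss <- vapply(seq_len(50), function(g)
    brute_force_ss(ds$latent[g, ], ds$design), numeric(3))
  # component estimates from expected mean squares at the balanced design
  a <- 4; b <- 10; n <- 2
  MS_A <- ss["SS_A", ] / (a - 1)
  MS_B <- ss["SS_B", ] / (a * b - a)
  MS_e <- ss["SS_e", ] / (a * b * (n - 1))
  expect_lt(abs(mean(MS_e) - 0.08), 0.01)
  expect_lt(abs(mean((MS_B - MS_e) / n) - 0.15), 0.025)
  # law of total variance across many genes on the latent scale
  v_tot <- apply(ds$latent, 1, var)
  expect_lt(abs(mean(v_tot) - (0.02 + 0.15 + 0.08)), 0.015)
})

test_that("expected apportionment truth is consistent and sums to one", {
  ds <- quick_dataset(n_genes = 30, seed = 5)
  sums <- with(ds$truth, Mst_expected + Mit_expected + Met_expected)
  expect_true(all(abs(sums - 1) < 1e-12))
  expect_equal(ds$truth$Mst_expected[1], 0.02 / 0.25)
})

test_that("directional regime injects the configured group shifts", {
  ds <- quick_dataset(
    n_genes = 300, seed = 31,
    regimes = list(selection_regime("directional", 50,
                                    shift = c(0, 0, 0, 2))))
  dir_genes <- which(ds$truth$regime == "directional")
  g4 <- ds$design$group == "G4"
  g1 <- ds$design$group == "G1"
  diffs <- rowMeans(ds$latent[dir_genes, g4]) -
    rowMeans(ds$latent[dir_genes, g1])
  # realized among-group mean difference equals the injected shift
  expect_equal(mean(diffs), 2, tolerance = 0.15)
  neu <- which(ds$truth$regime == "neutral")
  diffs0 <- rowMeans(ds$latent[neu, g4]) - rowMeans(ds$latent[neu, g1])
  expect_lt(abs(mean(diffs0)), 0.15)
})

test_that("variance-modifying regimes rescale the truth components", {
  regs <- list(selection_regime("balancing", 10),
               selection_regime("stabilizing", 10),
               selection_regime("diversifying", 10))
  ds <- quick_dataset(n_genes = 50, seed = 41, regimes = regs)
  tr <- ds$truth
  expect_true(all(tr$sigma2_A[tr$regime == "balancing"] == 0))
  expect_true(all(tr$sigma2_B[tr$regime == "balancing"] == 0.15 * 4))
  expect_true(all(tr$sigma2_B[tr$regime == "stabilizing"] == 0.15 * 0.1))
  expect_true(all(tr$sigma2_e[tr$regime == "stabilizing"] == 0.08 * 0.1))
  expect_true(all(tr$sigma2_B[tr$regime == "diversifying"] == 0.15 * 6))
  expect_error(generate_dataset(
    simulation_config(n_genes = 5, seed = 1),
    list(selection_regime("directional", 6))), "exceed")
})

test_that("negative dispersion is rejected with gene and mean named", {
  cfg <- simulation_config(n_genes = 5, sigma2_A = 0, sigma2_B = 0,
                           sigma2_e = 0, baseline_log_mean_range = c(5, 5),
                           nb_dispersion_model = function(mu) -1 + mu * 0,
                           seed = 2)
  expect_error(generate_dataset(cfg), "dispersion for gene")
})

test_that("fixtures round-trip losslessly and are byte-stable", {
  ds <- quick_dataset(n_genes = 10, seed = 8)
  dir1 <- tempfile("fix1"); dir2 <- tempfile("fix2")
  paths <- export_fixture(ds, dir1)
  expect_error(export_fixture(ds, dir1), "overwrite")
  counts2 <- read_counts(file.path(dir1, "counts.tsv"))
  design2 <- read_design(file.path(dir1, "design.tsv"), counts2)
  expect_identical(counts2, ds$counts)
  expect_identical(design2$individual_id, ds$design$individual_id)
  expect_equal(design2$rin, ds$design$rin)
  truth2 <- utils::read.delim(file.path(dir1, "truth.tsv"))
  expect_equal(nrow(truth2), 10)
  # regeneration under the same seed writes byte-identical files
  export_fixture(quick_dataset(n_genes = 10, seed = 8), dir2)
  for (f in c("counts.tsv", "design.tsv", "truth.tsv"))
    expect_identical(readLines(file.path(dir1, f)),
                     readLines(file.path(dir2, f)))
})
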