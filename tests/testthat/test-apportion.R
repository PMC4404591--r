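test_that("nested SS match brute-force computation on random instances", {
  # randomized unbalanced designs: without covariates the sequential SS
  # equal the classical mean-based nested formulas exactly
  for (seed in 1:25) {
    design <- random_design(seed)
    set.seed(seed + 1000)
    Y <- make_expr(rnorm(nrow(design) * 4), design)
    fit <- fit_simple_model(Y, design, covariates = character(0))
    for (g in 1:4) {
      oracle <- brute_force_ss(Y[g, ], design)
      expect_equal(fit$table$SS_A[g], oracle["SS_A"], tolerance = 1e-10,
                   ignore_attr = TRUE)
      expect_equal(fit$table$SS_B[g], oracle["SS_B"], tolerance = 1e-10,
                   ignore_attr = TRUE)
      expect_equal(fit$table$SS_e[g], oracle["SS_e"], tolerance = 1e-10,
                   ignore_attr = TRUE)
    }
    # df identity: strata sum to n_libraries - 1
    expect_identical(sum(fit$df), nrow(design) - 1L)
  }
})

test_that("covariate-adjusted SS agree with R's sequential ANOVA", {
  for (seed in 1:6) {
    design <- random_design(seed + 50)
    set.seed(seed + 2000)
    Y <- make_expr(rnorm(nrow(design) * 2), design)
    fit <- fit_simple_model(Y, design)
    d <- design
    d$x <- as.vector(scale(d$mapped_reads))
    d$z <- as.vector(scale(d$rin))
    for (g in 1:2) {
      d$y <- Y[g, ]
      tab <- anova(lm(y ~ x + z + group + individual_id, data = d))
      expect_equal(fit$table$SS_A[g], tab["group", "Sum Sq"])
      expect_equal(fit$table$SS_B[g], tab["individual_id", "Sum Sq"])
      expect_equal(fit$table$SS_e[g], tab["Residuals", "Sum Sq"])
      expect_equal(fit$table$SS_mapped_reads[g], tab["x", "Sum Sq"])
      expect_equal(fit$table$SS_rin[g], tab["z", "Sum Sq"])
    }
    expect_identical(sum(fit$df), nrow(design) - 1L - 2L)
  }
})

test_that("balanced toy decomposition places all variation among groups", {
  des <- make_design(a = 2, b = 2, n = 2)
  Y <- make_expr(c(0, 0, 0, 0, 2, 2, 2, 2), des)
  fit <- fit_simple_model(Y, des, covariates = character(0))
  expect_equal(fit$table$SS_A, 8)
  expect_equal(fit$table$SS_B, 0)
  expect_equal(fit$table$SS_e, 0)
  ap <- apportion_statistics(fit)
  expect_equal(ap$Nst, 1)
  expect_equal(ap$Net, 0)
})

test_that("constant genes are flagged undefined, not NaN-propagated", {
  des <- make_design(a = 2, b = 2, n = 2)
  Y <- make_expr(c(rep(3, 8), rnorm(8)), des)
  fit <- fit_simple_model(Y, des, covariates = character(0))
  expect_false(fit$table$defined[1])
  expect_true(fit$table$defined[2])
  ap <- apportion_statistics(fit)
  expect_true(is.na(ap$Nst[1]))
  expect_false(anyNA(ap[2, c("Nst", "Nit", "Net")]))
})

test_that("apportionment statistics follow their defining ratios", {
  # direct-formula cases built from a synthetic fit object
  fake <- list(table = data.frame(
    gene_id = c("g1", "g2"), mean_expr = c(5, 6),
    SS_A = c(1, 2), SS_B = c(1, 2), SS_e = c(2, 4),
    SS_T = c(4, 8), MS_A = 1, MS_B = 1, MS_e = 1,
    sigma2_A = c(0, 1), sigma2_B = c(3, 1), sigma2_e = c(1, 2),
    defined = TRUE), df = c(A = 1, B = 2, e = 4),
    n_libraries = 8, n_individuals = 4)
  class(fake) <- "simple_fit"
  ap <- apportion_statistics(fake)
  expect_equal(ap$Nst[1], 0.25)
  expect_equal(ap$Nit[1], 0.25)
  expect_equal(ap$Net[1], 0.5)
  expect_equal(ap$Nis[1], 1 / 3)
  expect_equal(ap$Nig[1], 0.5)
  expect_equal(ap$Mst[1], 0)
  expect_equal(ap$Mit[1], 0.75)
  expect_equal(ap$Met[1], 0.25)
})

test_that("apportionments satisfy their identities on simulated data", {
  ds <- quick_dataset(n_genes = 120, seed = 61, deep = FALSE)
  expr <- variance_stabilize(ds$counts)
  fit <- fit_simple_model(expr, ds$design)
  ap <- apportion_statistics(fit)
  ok <- ap$defined
  expect_true(all(abs(ap$Nst[ok] + ap$Nit[ok] + ap$Net[ok] - 1) < 1e-10))
  expect_true(all(abs(ap$Mst[ok] + ap$Mit[ok] + ap$Met[ok] - 1) < 1e-10))
  for (col in c("Nst", "Nit", "Net", "Nis", "Nig", "Mst", "Mit", "Met"))
    expect_true(all(ap[[col]][ok] >= 0 & ap[[col]][ok] <= 1), label = col)
  # decomposition identity against the residualized total
  expect_equal(fit$table$SS_A + fit$table$SS_B + fit$table$SS_e,
               fit$table$SS_T, tolerance = 1e-12)
})

test_that("variance components are recovered from counts", {
  ds <- quick_dataset(n_genes = 800, seed = 71)
  expr <- variance_stabilize(ds$counts)
  fit <- fit_simple_model(expr, ds$design)
  expect_lt(abs(mean(fit$table$sigma2_e) - 0.08), 0.01)
  expect_lt(abs(mean(fit$table$sigma2_B) - 0.15), 0.01)
  expect_lt(abs(mean(fit$table$sigma2_A) - 0.02), 0.015)
})

test_that("group subsets and pairwise fits behave", {
  ds <- quick_dataset(n_genes = 60, seed = 81)
  expr <- variance_stabilize(ds$counts)
  pw <- pairwise_apportionments(expr, ds$design)
  expect_length(pw, 6)
  expect_named(pw, c("G1:G2", "G1:G3", "G1:G4", "G2:G3", "G2:G4", "G3:G4"))
  # pairwise fit equals a direct fit on the subset
  sub <- ds$design$group %in% c("G1", "G2")
  direct <- fit_simple_model(expr[, ds$design$library_id[sub]],
                             ds$design[sub, ])
  expect_equal(pw[["G1:G2"]]$fit$table$SS_A, direct$table$SS_A)
  # a group with one individual is rejected
  bad <- ds$design[ds$design$group != "G1" |
                     ds$design$individual_id == "I001", ]
  expect_error(fit_simple_model(expr[, bad$library_id], bad), "individuals")
})

test_that("inter-individual DE tests are calibrated and powered", {
  # null: no individual effects
  ds0 <- quick_dataset(n_genes = 600, s2A = 0, s2B = 0, s2e = 0.1, seed = 91)
  expr0 <- variance_stabilize(ds0$counts)
  de0 <- individual_de_tests(fit_simple_model(expr0, ds0$design))
  expect_lt(mean(de0$sig_F), 0.02)
  expect_lt(mean(de0$sig_inverted), 0.02)
  # raw F p-values approximately uniform under the null
  expect_gt(ks.test(de0$p_F, "punif")$p.value, 1e-4)

  # strong individual effects: both tests approach full power
  ds1 <- quick_dataset(n_genes = 300, s2A = 0, s2B = 0.6, s2e = 0.05,
                       seed = 92)
  expr1 <- variance_stabilize(ds1$counts)
  de1 <- individual_de_tests(fit_simple_model(expr1, ds1$design))
  expect_gt(mean(de1$sig_F), 0.95)
  expect_gt(mean(de1$sig_lrt), 0.95)
  expect_equal(mean(de1$sig_inverted), 0)

  # identical individual means but replicate noise: small F, not significant
  des <- make_design(a = 2, b = 3, n = 2)
  set.seed(9)
  y <- rep(0, 12) + rnorm(12, 0, 0.1)
  y <- y - ave(y, des$individual_id) # individual means exactly equal
  de2 <- individual_de_tests(
    fit_simple_model(make_expr(y, des), des, covariates = character(0)))
  expect_false(de2$sig_F[1])
})

test_that("mean-expression diagnostics report correlations and edge cases", {
  # residual variance coupled to baseline expression: residual SS and the
  # replicate-share statistic track mean expression
  cfg <- simulation_config(
    n_genes = 400, sigma2_A = 0.02, sigma2_B = 0.15,
    sigma2_e = function(n, mu) 0.02 + 0.012 * mu,
    baseline_log_mean_range = c(10, 14),
    nb_dispersion_model = function(mu) 0.001 + 0.5 / mu, seed = 101)
  ds <- generate_dataset(cfg)
  expr <- variance_stabilize(ds$counts)
  fit <- fit_simple_model(expr, ds$design)
  ap <- apportion_statistics(fit)
  diag <- mean_expression_diagnostics(ap, fit)
  expect_gt(diag$r[diag$statistic == "SS_e"], 0.2)
  expect_equal(diag$r_squared, diag$r^2)
  # constant mean expression: correlation undefined, reported as NA
  ap2 <- ap; ap2$mean_expr <- 1
  diag2 <- mean_expression_diagnostics(ap2, fit)
  expect_true(all(is.na(diag2$r)))
})
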