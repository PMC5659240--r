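test_that("config validation names the offending fields", {
  expect_error(simulation_config(background_fraction = 1), "background_fraction")
  expect_error(simulation_config(n_genes = -5), "n_genes")
  expect_error(simulation_config(wt_capture_scale = 0), "wt_capture_scale")
  expect_error(
    simulation_config(population_profiles = list(Sepw1 = c(0.5, 0.6))),
    "population_profiles")
})

test_that("marker bookkeeping in the catalog is exact", {
  cfg <- simulation_config(n_genes = 5000, frac_markers_per_layer = 0.02, seed = 3)
  cat5k <- generate_catalog(cfg)
  tab <- table(cat5k$genes$home_layer)
  patterned <- cfg$layer_names[-length(cfg$layer_names)]
  expect_equal(as.vector(tab[patterned]), rep(100L, 5))
  expect_equal(as.vector(tab["unpatterned"]), 4500L)
  # weights are probability vectors and markers peak at their home layer
  expect_equal(rowSums(cat5k$weights), rep(1, 5000), tolerance = 1e-12,
               ignore_attr = TRUE)
  is_marker <- cat5k$genes$home_layer != "unpatterned"
  peak <- colnames(cat5k$weights)[apply(cat5k$weights, 1, which.max)]
  expect_true(all(peak[is_marker] == cat5k$genes$home_layer[is_marker]))
})

test_that("null effect size and zero marker fraction plant no signal", {
  cfg0 <- small_config(effect_size = 1)
  cat0 <- generate_catalog(cfg0)
  L <- length(cfg0$layer_names)
  expect_true(all(abs(cat0$weights - 1 / L) < 1e-12))
  cfg_none <- small_config(frac_markers_per_layer = 0)
  expect_true(all(generate_catalog(cfg_none)$genes$home_layer == "unpatterned"))
})

test_that("labeling kinetics follow the first-order closed form", {
  expect_equal(new_fraction(5, 5), 1 - exp(-log(2)), tolerance = 1e-12)
  expect_equal(new_fraction(5, 5), 0.5, tolerance = 1e-3)
  expect_error(new_fraction(0, 5), "half_life_h")
  # truth table stores exactly this fraction
  cfg <- small_config()
  catal <- generate_catalog(cfg)
  tt <- truth_table(catal, cfg)
  expect_equal(tt$new_fraction,
               1 - exp(-log(2) * cfg$labeling_window_h / catal$genes$half_life))
})

test_that("expected abundance honors profile independence and limits", {
  cfg <- small_config(effect_size = 1, background_fraction = 0)
  catal <- generate_catalog(cfg)  # all genes have uniform weights
  mu_a <- expected_abundance(catal, cfg, "Sepw1")$expected_mean
  mu_b <- expected_abundance(catal, cfg, "Nr5a1")$expected_mean
  expect_equal(mu_a, mu_b, tolerance = 1e-12)
  # infinite half-life: purified signal collapses to background carryover
  cfg_b <- small_config(background_fraction = 0.3)
  catal_b <- generate_catalog(cfg_b)
  catal_b$genes$half_life <- rep(1e12, cfg_b$n_genes)
  mu <- expected_abundance(catal_b, cfg_b, "Sepw1")$expected_mean
  lam <- catal_b$genes$baseline
  tissue <- cfg_b$population_profiles[["WT"]]
  bg <- lam * as.vector(catal_b$weights %*% tissue)
  expect_equal(mu, 0.3 * bg, tolerance = 1e-6)
  expect_error(expected_abundance(catal, cfg, "nope"), "Sepw1")
})

test_that("expected marker enrichment grows with effect size and is 1 at null", {
  ratios <- sapply(c(1, 2, 4, 8), function(e) {
    cfg <- small_config(effect_size = e)
    catal <- generate_catalog(cfg)
    l23 <- catal$genes$home_layer == cfg$layer_names[1]
    mu_a <- expected_abundance(catal, cfg, "Sepw1")$expected_mean
    mu_b <- expected_abundance(catal, cfg, "Nr5a1")$expected_mean
    mean(mu_a[l23] / mu_b[l23])
  })
  expect_equal(ratios[1], 1, tolerance = 1e-12)
  expect_true(all(diff(ratios) > 0))
})

test_that("half-life dynamics bias the purified-vs-background ratio", {
  # equal half-lives, no background: expected log-ratio identical across
  # unpatterned genes; heterogeneous half-lives: strictly decreasing in t
  cfg <- small_config(background_fraction = 0)
  catal <- generate_catalog(cfg)
  unp <- catal$genes$home_layer == "unpatterned"
  catal_eq <- catal
  catal_eq$genes$half_life <- rep(4, cfg$n_genes)
  lr <- function(ct) {
    log(expected_abundance(ct, cfg, "Sepw1")$expected_mean /
          expected_abundance(ct, cfg, "WT")$expected_mean)
  }
  expect_equal(diff(range(lr(catal_eq)[unp])), 0, tolerance = 1e-12)
  het <- lr(catal)[unp]
  t_g <- catal$genes$half_life[unp]
  expect_true(all(diff(het[order(t_g)]) < 0))
})

test_that("counts are reproducible, NB-dispersed, and converge to s_j * mu_g", {
  cfg <- small_config()
  catal <- generate_catalog(cfg)
  sim1 <- simulate_counts(catal, cfg)
  sim2 <- simulate_counts(catal, cfg)
  expect_identical(sim1$counts, sim2$counts)
  # Poisson limit: a0 = a1 = 0
  cfg_p <- simulation_config(n_genes = 60, n_replicates_per_type = 120,
                             dispersion_a0 = 0, dispersion_a1 = 0, seed = 5)
  cat_p <- generate_catalog(cfg_p)
  sim_p <- simulate_counts(cat_p, cfg_p)
  j <- sim_p$sample_sheet$sample_type == "Sepw1"
  q <- sweep(sim_p$counts[, j], 2, sim_p$library_factors[j], `/`)
  vm <- apply(q, 1, var) / rowMeans(q)
  expect_equal(median(vm), 1, tolerance = 0.35)
  # NB variance: mu = 100, phi = 0.1 -> variance 100 + 0.1 * 100^2 = 1100
  withr::with_seed(8, {
    x <- rnbinom(2000, mu = 100, size = 10)
  })
  expect_equal(var(x), 1100, tolerance = 0.15)
  # law of large numbers on the full generator for one gene
  cfg_l <- simulation_config(n_genes = 1, n_replicates_per_type = 10000,
                             frac_markers_per_layer = 0, seed = 21)
  cat_l <- generate_catalog(cfg_l)
  sim_l <- simulate_counts(cat_l, cfg_l)
  mu <- expected_abundance(cat_l, cfg_l, "Sepw1")$expected_mean
  j <- sim_l$sample_sheet$sample_type == "Sepw1"
  expect_equal(mean(sim_l$counts[1, j] / sim_l$library_factors[j]), mu,
               tolerance = 0.01)
})

test_that("simulated NB counts match the dispersion trend they were drawn from", {
  # one gene at fixed scaled mean: empirical variance matches m + phi m^2
  cfg <- simulation_config(n_genes = 1, n_replicates_per_type = 4000,
                           frac_markers_per_layer = 0,
                           dispersion_a0 = 0.1, dispersion_a1 = 0,
                           library_size_range = c(1, 1), seed = 13)
  catal <- generate_catalog(cfg)
  sim <- simulate_counts(catal, cfg)
  j <- sim$sample_sheet$sample_type == "Sepw1"
  m <- expected_abundance(catal, cfg, "Sepw1")$expected_mean
  expect_equal(var(sim$counts[1, j]), m + 0.1 * m^2, tolerance = 0.15)
})

test_that("simulation files round-trip through the writers", {
  cfg <- simulation_config(n_genes = 50, seed = 2)
  sim <- simulate_experiment(cfg)
  dir <- withr::local_tempdir()
  paths <- write_simulation(sim, cfg, dir)
  expect_identical(read_counts(paths[["counts"]]), sim$counts)
  sheet <- read_sample_sheet(paths[["samples"]])
  expect_equal(sheet, sim$sample_sheet)
  cfg_back <- yaml::read_yaml(paths[["config"]])
  expect_equal(cfg_back$background_fraction, cfg$background_fraction)
  expect_equal(cfg_back$n_genes, cfg$n_genes)
})
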