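test_that("CPM rescales each library to one million", {
  one <- matrix(c(1L, 3L), ncol = 1, dimnames = list(c("g1", "g2"), "s1"))
  expect_equal(as.vector(cpm(one)), c(250000, 750000))
  m <- rbind(tiny_counts(), g4 = c(0L, 0L))
  expect_equal(unname(colSums(cpm(m))), c(1e6, 1e6))
  expect_equal(unname(cpm(m)["g4", ]), c(0, 0))
  big <- matrix(c(2L, rep(666666L, 3)), ncol = 1,
                dimnames = list(paste0("g", 1:4), "s1"))
  expect_equal(cpm(big)["g1", "s1"], 1.0)  # count 2 in a 2e6 library
  zero <- matrix(0L, 2, 1, dimnames = list(c("g1", "g2"), "empty"))
  expect_error(cpm(zero), "empty")
})

test_that("low-count filter applies the three-or-more-samples rule exactly", {
  # 6 samples, equal library sizes of 1e6 so CPM == count
  base <- matrix(1000L, nrow = 4, ncol = 6,
                 dimnames = list(paste0("g", 1:4), paste0("s", 1:6)))
  base["g2", 1:3] <- 0L   # below 1 CPM in exactly 3 samples -> removed
  base["g3", 1:2] <- 0L   # below in exactly 2 -> kept (boundary)
  base["g4", ] <- 0L      # below everywhere -> removed
  filler <- 1e6 - colSums(base)
  m <- rbind(base, filler = as.integer(filler))
  kept <- filter_low_counts(m)
  expect_equal(rownames(kept), c("g1", "g3", "filler"))
  # filter is idempotent
  expect_identical(filter_low_counts(kept), kept)
  expect_error(filter_low_counts(m, character(0)), "empty comparison")
})

test_that("filter CPM uses comparison samples with pre-filter library sizes", {
  m <- matrix(c(10L, 990990L,  9L, 999991L), nrow = 2,
              dimnames = list(c("g1", "big"), c("s1", "s2")))
  m <- rbind(m, g3 = c(9000L, 0L))
  # within comparison c(s1, s2): g1 has CPM 10 and ~9 (no sample below
  # threshold) while g3 drops out in s2; strict filtering keeps only g1
  kept <- filter_low_counts(m, c("s1", "s2"), min_cpm = 1, max_samples_below = 0)
  expect_true("g1" %in% rownames(kept))
  expect_false("g3" %in% rownames(kept))
})

test_that("size factors follow the median-of-ratios closed forms", {
  m <- nb_matrix(40, 2, seed = 4)
  same <- cbind(m[, 1], m[, 1])
  dimnames(same) <- list(rownames(m), c("a", "b"))
  expect_equal(unname(size_factors(same)), c(1, 1))
  doubled <- cbind(a = m[, 1], b = 2L * m[, 1])
  expect_equal(unname(size_factors(doubled)), c(1 / sqrt(2), sqrt(2)),
               tolerance = 1e-12)
  # scale equivariance via the two-sample closed form: scaling column b by c
  # multiplies its factor by sqrt(c) and divides the other by sqrt(c)
  for (c_mult in c(3, 10)) {
    scaled <- cbind(a = m[, 1], b = c_mult * m[, 1])
    expect_equal(unname(size_factors(scaled)),
                 c(1 / sqrt(c_mult), sqrt(c_mult)), tolerance = 1e-12)
  }
  m4 <- nb_matrix(51, 4, seed = 7)  # odd gene count: the two median
  # conventions (element on log scale vs ratio scale) coincide exactly
  expect_equal(unname(size_factors(m4)), brute_size_factors(m4),
               tolerance = 1e-12)
  # independent cross-check against the reference implementation
  expect_equal(unname(size_factors(m4)),
               unname(DESeq2::estimateSizeFactorsForMatrix(m4)),
               tolerance = 1e-10)
  allzero <- matrix(c(0L, 1L, 1L, 0L), 2, dimnames = list(c("g1", "g2"), c("a", "b")))
  expect_error(size_factors(allzero), "nonzero")
})

test_that("dispersion estimation recovers planted values and handles degeneracy", {
  cond <- rep(c("A", "B"), each = 6)
  m <- nb_matrix(1500, 12, mu_range = c(200, 5000), phi = 0.05, seed = 11)
  sf <- size_factors(m)
  est <- estimate_dispersions(m, sf, cond)
  expect_equal(median(est$raw), 0.05, tolerance = 0.2)
  expect_true(all(est$dispersion >= 1e-8))
  # near-Poisson data: per-gene moments estimates scatter around zero
  mp <- nb_matrix(1500, 12, mu_range = c(200, 5000), phi = 0, seed = 12)
  estp <- estimate_dispersions(mp, size_factors(mp), cond)
  expect_lt(abs(median(estp$raw)), 0.01)
  expect_lt(estp$a0, 0.01)
  # constant counts within conditions: raw <= 0, trend value is used
  mc <- matrix(rep(c(100L, 50L), each = 6), nrow = 1,
               dimnames = list("g1", paste0("s", 1:12)))
  mc <- rbind(mc, g2 = rep(c(400L, 600L), 6))
  estc <- estimate_dispersions(mc, rep(1, 12), cond)
  expect_lte(estc$raw[1], 0)
  expect_equal(unname(estc$dispersion[1]),
               max(estc$a0 + estc$a1 / estc$base_mean[1], 1e-8))
  expect_error(estimate_dispersions(mc[, c(1, 7), drop = FALSE], c(1, 1), c("A", "B")),
               "replicates")
})

test_that("NB exact test matches symmetry, enumeration, and the Poisson limit", {
  # symmetric design: observed split is the modal one, every split counts
  expect_equal(nb_exact_test(c(10, 10), c(10, 10), c(1, 1), c(1, 1), 0.1), 1)
  expect_equal(nb_exact_test(c(0, 0), c(0, 0), c(1, 1), c(1, 1), 0.1), 1)
  # enumeration oracle across many small instances
  withr::with_seed(42, {
    for (i in 1:40) {
      K <- sample(1:50, 1)
      ka <- sample(0:K, 1)
      sf_a <- runif(2, 0.5, 2)
      sf_b <- runif(3, 0.5, 2)
      phi <- runif(1, 0, 0.5)
      q_hat <- K / (sum(sf_a) + sum(sf_b))
      got <- nb_exact_test(c(ka, 0), c(K - ka, 0, 0), sf_a, sf_b, phi)
      want <- min(1, brute_nb_exact(ka, K, q_hat, sf_a, sf_b, phi))
      expect_equal(got, want, tolerance = 1e-9)
    }
  })
  # phi -> 0 with equal size factors: conditional binomial with rate 1/2
  for (ka in c(3, 10, 17)) {
    K <- 20
    got <- nb_exact_test(c(ka), c(K - ka), 1, 1, 0)
    want <- stats::binom.test(ka, K, 0.5)$p.value
    expect_equal(got, want, tolerance = 1e-4)
  }
})

test_that("BH adjustment is the step-up procedure in input order", {
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  withr::with_seed(5, {
    p <- runif(50)
    q <- bh_adjust(p)
    expect_true(all(q >= p & q <= 1))
    expect_true(all(diff(q[order(p)]) >= -1e-15))
  })
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("run_comparison calls nothing when groups are relabeled copies", {
  m <- nb_matrix(300, 4, seed = 9)
  sheet <- data.frame(sample_id = colnames(m),
                      sample_type = c("A", "B", "A", "B"))
  # B samples are literal copies of A samples
  m[, 2] <- m[, 1]
  m[, 4] <- m[, 3]
  de <- run_comparison(m, sheet, "A", "B")
  expect_equal(sum(de$enriched), 0)
  expect_true(all(de$padj >= de$pval))
  expect_error(run_comparison(m, sheet[-1, ], "A", "B"), "at least 2")
})

test_that("the global-null simulation keeps false enrichment rare", {
  calls <- 0L
  genes <- 0L
  for (s in 1:6) {
    cfg <- simulation_config(n_genes = 600, effect_size = 1, seed = 300 + s)
    sim <- simulate_experiment(cfg)
    de <- run_comparison(sim$counts, sim$sample_sheet, "Sepw1", "Nr5a1")
    calls <- calls + sum(de$enriched)
    genes <- genes + nrow(de)
  }
  expect_lt(calls / genes, 0.01)
})

test_that("comparison metadata records the analysis settings", {
  cfg <- small_config()
  sim <- simulate_experiment(cfg)
  de <- run_comparison(sim$counts, sim$sample_sheet, "Sepw1", "WT", alpha = 0.05)
  expect_identical(attr(de, "type_a"), "Sepw1")
  expect_identical(attr(de, "alpha"), 0.05)
  expect_length(attr(de, "size_factors"), 6)
  expect_true(is.finite(attr(de, "dispersion_a1")))
  expect_true(all(de$enriched == (de$padj < 0.05 & de$fold_enrichment > 1)))
})
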