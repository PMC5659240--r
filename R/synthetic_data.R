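#' Configuration for the TU-tagging count simulator
#'
#' Builds and validates the parameter set controlling the synthetic
#' experiment: a gene universe with per-layer expression weights, planted
#' layer-marker genes, first-order labeling kinetics over the 4TU labeling
#' window, purification background carryover, and NB count noise with a
#' dispersion--mean trend.
#'
#' The generative model for the expected purified abundance of gene g in a
#' UPRT-positive sample type with population layer profile \eqn{\pi} is
#' \deqn{\mu_g = (1-b)\,\lambda_g \left(\sum_l \pi_l w_{g,l}\right) r_g +
#'       b\,\mathrm{bg}_g,}
#' where \eqn{r_g = 1 - \exp(-\ln 2 \cdot T / t_g)} is the fraction of a
#' steady-state transcript pool synthesized during the labeling window
#' \eqn{T} given half-life \eqn{t_g}, \eqn{b} is the background
#' (carryover) fraction, and \eqn{\mathrm{bg}_g = \lambda_g \sum_l
#' \pi^{\mathrm{tissue}}_l w_{g,l}} is the total-RNA abundance of the gene
#' in bulk tissue (no labeling-kinetics weighting). The no-UPRT control
#' ("WT-pure") captures background only, scaled by `wt_capture_scale`.
#'
#' @param n_genes number of genes in the universe.
#' @param n_replicates_per_type replicates per sample type (default 3).
#' @param labeling_window_h labeling window T in hours (default 5, the time
#'   between 4TU injection and tissue collection).
#' @param background_fraction proportion b in `[0, 1)` of a purified
#'   sample's expected signal that is unlabeled carryover RNA.
#' @param wt_capture_scale positive scalar (< 1): yield of the no-UPRT
#'   control purification relative to a UPRT-positive purification.
#' @param layer_names ordered layer labels; the last entry is the
#'   "unpatterned" (non-laminar) compartment.
#' @param population_profiles named list of probability vectors over
#'   `layer_names`, one per sample type. Defaults model a Cre line
#'   labeling layer 2/3 with minor layer 4 mass ("Sepw1"), a line
#'   concentrated on layer 4 ("Nr5a1"), and bulk tissue ("WT", uniform).
#' @param effect_size fold elevation of a marker gene's weight in its home
#'   layer (1 = no planted signal).
#' @param frac_markers_per_layer proportion of genes planted as markers of
#'   each patterned layer.
#' @param dispersion_a0,dispersion_a1 intercept and slope of the NB
#'   dispersion trend \eqn{\phi(\mu) = a_0 + a_1/\mu}.
#' @param baseline_meanlog,baseline_sdlog log-normal parameters of the
#'   baseline abundance \eqn{\lambda_g} (arbitrary expression units).
#' @param half_life_median_h,half_life_sdlog log-normal parameters of the
#'   transcript half-life distribution (hours).
#' @param library_size_range range of the uniform draw for per-sample
#'   library scaling factors.
#' @param seed integer seed for all randomness in the simulation.
#' @return a validated list of class `"tutag_sim_config"`.
#' @export
simulation_config <- function(n_genes = 5000,
                              n_replicates_per_type = 3,
                              labeling_window_h = 5,
                              background_fraction = 0.2,
                              wt_capture_scale = 0.1,
                              layer_names = c("L2/3", "L4", "L5", "L6", "L6b", "unpatterned"),
                              population_profiles = NULL,
                              effect_size = 4,
                              frac_markers_per_layer = 0.02,
                              dispersion_a0 = 0.02,
                              dispersion_a1 = 2,
                              baseline_meanlog = log(5000),
                              baseline_sdlog = 1.2,
                              half_life_median_h = 5,
                              half_life_sdlog = 0.8,
                              library_size_range = c(0.7, 1.4),
                              seed = 1L) {
  if (is.null(population_profiles)) {
    population_profiles <- default_population_profiles(layer_names)
  }
  cfg <- list(
    n_genes = n_genes,
    n_replicates_per_type = n_replicates_per_type,
    labeling_window_h = labeling_window_h,
    background_fraction = background_fraction,
    wt_capture_scale = wt_capture_scale,
    layer_names = layer_names,
    population_profiles = population_profiles,
    effect_size = effect_size,
    frac_markers_per_layer = frac_markers_per_layer,
    dispersion_a0 = dispersion_a0,
    dispersion_a1 = dispersion_a1,
    baseline_meanlog = baseline_meanlog,
    baseline_sdlog = baseline_sdlog,
    half_life_median_h = half_life_median_h,
    half_life_sdlog = half_life_sdlog,
    library_size_range = library_size_range,
    seed = seed
  )
  class(cfg) <- "tutag_sim_config"
  validate_sim_config(cfg)
  cfg
}

#' Default population layer profiles for the three sample types
#'
#' "Sepw1": weighted to layer 2/3 with lesser layer 4 mass; "Nr5a1":
#' concentrated on layer 4; "WT": uniform over layer mass (bulk tissue).
#' Deep-layer and unpatterned mass are equal across the two purified
#' profiles, so planted deep-layer markers have identical expected
#' abundance in both.
#'
#' @param layer_names layer labels; last entry is the unpatterned
#'   compartment.
#' @return named list of probability vectors.
#' @export
default_population_profiles <- function(layer_names) {
  L <- length(layer_names)
  if (L < 2) input_error("layer_names: need at least two layers, got %d", L)
  uniform <- rep(1 / L, L)
  sepw1 <- uniform
  nr5a1 <- uniform
  if (identical(layer_names, c("L2/3", "L4", "L5", "L6", "L6b", "unpatterned"))) {
    sepw1 <- c(0.55, 0.20, 0.05, 0.05, 0.02, 0.13)
    nr5a1 <- c(0.03, 0.72, 0.05, 0.05, 0.02, 0.13)
  } else {
    # generic fallback: first layer heavy for type A, second for type B
    sepw1[1] <- sepw1[1] + 0.5
    nr5a1[2] <- nr5a1[2] + 0.5
    sepw1 <- sepw1 / sum(sepw1)
    nr5a1 <- nr5a1 / sum(nr5a1)
  }
  profiles <- list(sepw1, nr5a1, uniform)
  names(profiles) <- c("Sepw1", "Nr5a1", "WT")
  profiles <- lapply(profiles, function(p) {
    names(p) <- layer_names
    p
  })
  profiles
}

validate_sim_config <- function(cfg) {
  problems <- character()
  chk <- function(ok, msg) if (!isTRUE(ok)) problems <<- c(problems, msg)
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  chk(num1(cfg$n_genes) && cfg$n_genes >= 1, "n_genes: must be a positive integer")
  chk(num1(cfg$n_replicates_per_type) && cfg$n_replicates_per_type >= 1,
      "n_replicates_per_type: must be a positive integer")
  chk(num1(cfg$labeling_window_h) && cfg$labeling_window_h > 0,
      "labeling_window_h: must be > 0")
  chk(num1(cfg$background_fraction) && cfg$background_fraction >= 0 &&
        cfg$background_fraction < 1,
      "background_fraction: must be in [0, 1)")
  chk(num1(cfg$wt_capture_scale) && cfg$wt_capture_scale > 0,
      "wt_capture_scale: must be > 0")
  chk(is.character(cfg$layer_names) && !anyDuplicated(cfg$layer_names),
      "layer_names: must be unique strings")
  chk(num1(cfg$effect_size) && cfg$effect_size >= 1,
      "effect_size: must be >= 1")
  chk(num1(cfg$frac_markers_per_layer) && cfg$frac_markers_per_layer >= 0 &&
        cfg$frac_markers_per_layer <= 1 / max(1, length(cfg$layer_names) - 1),
      "frac_markers_per_layer: must be in [0, 1/(number of patterned layers)]")
  chk(num1(cfg$dispersion_a0) && cfg$dispersion_a0 >= 0, "dispersion_a0: must be >= 0")
  chk(num1(cfg$dispersion_a1) && cfg$dispersion_a1 >= 0, "dispersion_a1: must be >= 0")
  chk(num1(cfg$half_life_median_h) && cfg$half_life_median_h > 0,
      "half_life_median_h: must be > 0")
  chk(is.numeric(cfg$library_size_range) && length(cfg$library_size_range) == 2L &&
        all(cfg$library_size_range > 0) && diff(cfg$library_size_range) >= 0,
      "library_size_range: must be two positive increasing values")
  chk(num1(cfg$seed), "seed: must be a single number")
  if (!is.list(cfg$population_profiles) || is.null(names(cfg$population_profiles))) {
    chk(FALSE, "population_profiles: must be a named list")
  } else {
    for (nm in names(cfg$population_profiles)) {
      p <- cfg$population_profiles[[nm]]
      chk(length(p) == length(cfg$layer_names),
          sprintf("population_profiles[%s]: length must match layer_names", nm))
      chk(all(p >= 0) && abs(sum(p) - 1) < 1e-8,
          sprintf("population_profiles[%s]: must be a probability vector summing to 1", nm))
    }
  }
  if (length(problems)) {
    input_error("invalid simulation config:\n  - %s", paste(problems, collapse = "\n  - "))
  }
  invisible(cfg)
}

#' Fraction of a steady-state transcript pool labeled within the window
#'
#' First-order decay kinetics: a transcript with half-life `half_life_h`
#' turns over so that after a labeling window of `window_h` hours the
#' newly transcribed fraction of the steady-state pool is
#' \eqn{r = 1 - \exp(-\ln 2 \cdot T / t)}.
#'
#' @param half_life_h transcript half-life in hours (> 0).
#' @param window_h labeling window in hours.
#' @return newly transcribed fraction in (0, 1].
#' @export
new_fraction <- function(half_life_h, window_h) {
  if (any(half_life_h <= 0)) input_error("half_life_h: must be > 0")
  1 - exp(-log(2) * window_h / half_life_h)
}

#' Generate the per-gene ground-truth catalog
#'
#' Draws baseline abundances and half-lives (log-normal), assigns
#' `round(frac_markers_per_layer * n_genes)` marker genes to each patterned
#' layer, and builds each gene's layer-weight probability vector: uniform
#' over layers for unpatterned genes; for a marker, the home-layer weight
#' is elevated `effect_size`-fold and the vector renormalized.
#'
#' @param config a [simulation_config()].
#' @return a list of class `"tutag_catalog"` with elements `genes` (a
#'   data.frame: `gene_id`, `baseline`, `half_life`, `home_layer`) and
#'   `weights` (genes x layers probability matrix).
#' @export
generate_catalog <- function(config) {
  validate_sim_config(config)
  G <- as.integer(config$n_genes)
  layers <- config$layer_names
  patterned <- layers[-length(layers)]
  n_marker <- round(config$frac_markers_per_layer * G)
  if (n_marker * length(patterned) > G) {
    input_error("frac_markers_per_layer: %d markers per layer exceed %d genes",
                n_marker, G)
  }
  with_seed(derive_seed(config$seed, 1L), {
    gene_id <- sprintf("gene_%05d", seq_len(G))
    baseline <- stats::rlnorm(G, meanlog = config$baseline_meanlog,
                              sdlog = config$baseline_sdlog)
    half_life <- stats::rlnorm(G, meanlog = log(config$half_life_median_h),
                               sdlog = config$half_life_sdlog)
    home_layer <- rep("unpatterned", G)
    idx <- sample.int(G)  # random placement of markers in the universe
    pos <- 0L
    for (l in patterned) {
      if (n_marker > 0) {
        home_layer[idx[pos + seq_len(n_marker)]] <- l
        pos <- pos + n_marker
      }
    }
    L <- length(layers)
    weights <- matrix(1 / L, nrow = G, ncol = L, dimnames = list(gene_id, layers))
    e <- config$effect_size
    for (l in patterned) {
      rows <- which(home_layer == l)
      if (length(rows)) {
        weights[rows, l] <- e / L
        weights[rows, ] <- weights[rows, , drop = FALSE] /
          rowSums(weights[rows, , drop = FALSE])
      }
    }
    out <- list(
      genes = data.frame(gene_id = gene_id, baseline = baseline,
                         half_life = half_life, home_layer = home_layer,
                         stringsAsFactors = FALSE),
      weights = weights,
      layer_names = layers
    )
    class(out) <- "tutag_catalog"
    out
  })
}

#' Expected purified abundance of every gene for one sample type
#'
#' Evaluates the generative mixture (see [simulation_config()]): labeled
#' signal weighted by the population layer profile and the newly
#' transcribed fraction, plus background carryover at the bulk-tissue
#' abundance; the no-UPRT type ("WT") captures background only, scaled by
#' `wt_capture_scale`. The bulk-tissue profile is the profile named `"WT"`
#' if present, otherwise uniform.
#'
#' @param catalog a [generate_catalog()] result.
#' @param config the matching [simulation_config()].
#' @param sample_type a name of `config$population_profiles`.
#' @return data.frame: `gene_id`, `home_layer`, `is_l23_marker`,
#'   `new_fraction`, `expected_mean`.
#' @export
expected_abundance <- function(catalog, config, sample_type) {
  profiles <- config$population_profiles
  if (!sample_type %in% names(profiles)) {
    input_error("unknown sample_type '%s'; known types: %s", sample_type,
                paste(names(profiles), collapse = ", "))
  }
  lam <- catalog$genes$baseline
  r <- new_fraction(catalog$genes$half_life, config$labeling_window_h)
  b <- config$background_fraction
  tissue <- if ("WT" %in% names(profiles)) profiles[["WT"]] else
    rep(1 / ncol(catalog$weights), ncol(catalog$weights))
  bg <- lam * as.vector(catalog$weights %*% tissue)
  if (identical(sample_type, "WT")) {
    mu <- config$wt_capture_scale * bg
  } else {
    signal <- lam * as.vector(catalog$weights %*% profiles[[sample_type]]) * r
    mu <- (1 - b) * signal + b * bg
  }
  data.frame(
    gene_id = catalog$genes$gene_id,
    home_layer = catalog$genes$home_layer,
    is_l23_marker = catalog$genes$home_layer == catalog$layer_names[1],
    new_fraction = r,
    expected_mean = mu,
    stringsAsFactors = FALSE
  )
}

#' Ground-truth table across all sample types
#'
#' One row per gene with the expected purified abundance for every sample
#' type (columns `mean_<type>`), half-life, newly transcribed fraction and
#' marker labels.
#'
#' @inheritParams expected_abundance
#' @return data.frame of class `"tutag_truth"`.
#' @export
truth_table <- function(catalog, config) {
  types <- names(config$population_profiles)
  base <- expected_abundance(catalog, config, types[1])
  out <- data.frame(
    gene_id = base$gene_id,
    home_layer = base$home_layer,
    is_l23_marker = base$is_l23_marker,
    half_life = catalog$genes$half_life,
    new_fraction = base$new_fraction,
    stringsAsFactors = FALSE
  )
  for (ty in types) {
    out[[paste0("mean_", gsub("[^A-Za-z0-9]", "_", ty))]] <-
      expected_abundance(catalog, config, ty)$expected_mean
  }
  class(out) <- c("tutag_truth", class(out))
  out
}

#' Simulate an NB count matrix from a catalog
#'
#' Draws one library scaling factor per sample uniformly from
#' `library_size_range`, then each count from a negative binomial with
#' mean \eqn{s_j \mu_g} and dispersion \eqn{\phi = a_0 + a_1/(s_j\mu_g)}
#' (variance \eqn{m + \phi m^2}); \eqn{\phi = 0} gives Poisson counts.
#' Genes are drawn row by row from a seeded stream, so extending the
#' catalog appends draws without perturbing earlier genes.
#'
#' @inheritParams expected_abundance
#' @return list with `counts` (integer matrix, genes x samples),
#'   `sample_sheet` (data.frame `sample_id`, `sample_type`),
#'   `library_factors`, and `truth` (the [truth_table()]).
#' @export
simulate_counts <- function(catalog, config) {
  validate_sim_config(config)
  types <- names(config$population_profiles)
  nrep <- config$n_replicates_per_type
  sample_type <- rep(types, each = nrep)
  sample_id <- paste0(gsub("[^A-Za-z0-9]", "_", sample_type), "_",
                      rep(seq_len(nrep), times = length(types)))
  n_samp <- length(sample_id)
  s <- with_seed(derive_seed(config$seed, 2L),
                 stats::runif(n_samp, config$library_size_range[1],
                              config$library_size_range[2]))
  names(s) <- sample_id
  mu <- matrix(unlist(lapply(types, function(ty) {
    expected_abundance(catalog, config, ty)$expected_mean
  })), ncol = length(types), dimnames = list(NULL, types))
  mu_mat <- mu[, match(sample_type, types), drop = FALSE]
  mu_mat <- sweep(mu_mat, 2L, s, `*`)
  a0 <- config$dispersion_a0
  a1 <- config$dispersion_a1
  counts <- with_seed(derive_seed(config$seed, 3L), {
    k <- matrix(0L, nrow = config$n_genes, ncol = n_samp)
    for (g in seq_len(config$n_genes)) {
      m <- mu_mat[g, ]
      phi <- ifelse(m > 0, a0 + a1 / m, 0)
      pois <- phi <= 0 | m == 0
      row <- numeric(n_samp)
      if (any(pois)) row[pois] <- stats::rpois(sum(pois), m[pois])
      if (any(!pois)) {
        row[!pois] <- stats::rnbinom(sum(!pois), mu = m[!pois], size = 1 / phi[!pois])
      }
      k[g, ] <- row
    }
    storage.mode(k) <- "integer"
    k
  })
  dimnames(counts) <- list(catalog$genes$gene_id, sample_id)
  list(
    counts = counts,
    sample_sheet = data.frame(sample_id = sample_id, sample_type = sample_type,
                              stringsAsFactors = FALSE),
    library_factors = s,
    truth = truth_table(catalog, config)
  )
}

#' Simulate a full experiment from a configuration
#'
#' Convenience wrapper: [generate_catalog()] then [simulate_counts()].
#'
#' @param config a [simulation_config()].
#' @return the [simulate_counts()] result with the catalog attached as
#'   element `catalog`.
#' @export
simulate_experiment <- function(config) {
  catalog <- generate_catalog(config)
  sim <- simulate_counts(catalog, config)
  sim$catalog <- catalog
  sim
}

#' Marker gene sets implied by a catalog
#'
#' One set per patterned layer (the planted markers), mirroring the
#' layer-marker database lists used for overlap testing.
#'
#' @param catalog a [generate_catalog()] result.
#' @return named list of gene-id vectors.
#' @export
catalog_gene_sets <- function(catalog) {
  patterned <- catalog$layer_names[-length(catalog$layer_names)]
  sets <- lapply(patterned, function(l) {
    catalog$genes$gene_id[catalog$genes$home_layer == l]
  })
  names(sets) <- patterned
  sets
}

#' Write a simulated experiment to plain-text files
#'
#' Emits the count matrix, sample sheet and truth table as TSV and the
#' configuration as YAML into `dir`.
#'
#' @param sim a [simulate_experiment()] result.
#' @param config the [simulation_config()] used.
#' @param dir output directory (created if missing).
#' @return invisibly, the paths written.
#' @export
write_simulation <- function(sim, config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    counts = file.path(dir, "counts.tsv"),
    samples = file.path(dir, "sample_sheet.tsv"),
    truth = file.path(dir, "truth.tsv"),
    config = file.path(dir, "config.yaml")
  )
  write_counts(sim$counts, paths["counts"])
  utils::write.table(sim$sample_sheet, paths["samples"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(as.data.frame(unclass(sim$truth)), paths["truth"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cfg <- config
  class(cfg) <- NULL
  cfg$population_profiles <- lapply(cfg$population_profiles, as.list)
  yaml::write_yaml(cfg, paths["config"])
  invisible(paths)
}
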