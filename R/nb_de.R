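#' Counts per million
#'
#' Scales each sample to a library of one million: entry =
#' count / column sum x 1e6.
#'
#' @param counts count matrix (genes x samples).
#' @return real matrix of the same shape; every column sums to 1e6.
#' @export
cpm <- function(counts) {
  libs <- colSums(counts)
  zero <- which(libs == 0)
  if (length(zero)) {
    input_error("sample '%s' has zero library size", colnames(counts)[zero[1]])
  }
  sweep(counts, 2L, libs, `/`) * 1e6
}

#' Remove low-count genes before differential testing
#'
#' A gene is removed when `max_samples_below + 1` or more of the
#' comparison's samples have CPM below `min_cpm` (defaults: removed when
#' three or more samples are under 1 CPM). CPM is computed on the
#' comparison's samples only, with library sizes taken from the unfiltered
#' matrix; gene order is preserved.
#'
#' @param counts full count matrix.
#' @param samples_in_comparison sample ids of the comparison; default all.
#' @param min_cpm CPM threshold (default 1).
#' @param max_samples_below maximum number of below-threshold samples a
#'   kept gene may have (default 2).
#' @return the filtered count matrix, restricted to
#'   `samples_in_comparison`.
#' @export
filter_low_counts <- function(counts, samples_in_comparison = colnames(counts),
                              min_cpm = 1, max_samples_below = 2) {
  if (!length(samples_in_comparison)) input_error("empty comparison: no samples given")
  missing <- setdiff(samples_in_comparison, colnames(counts))
  if (length(missing)) {
    input_error("samples not in matrix: %s", paste(missing, collapse = ", "))
  }
  sub <- counts[, samples_in_comparison, drop = FALSE]
  n_below <- rowSums(cpm(sub) < min_cpm)
  sub[n_below <= max_samples_below, , drop = FALSE]
}

#' Median-of-ratios size factors
#'
#' For each sample, the median over genes (with nonzero counts in every
#' sample) of the ratio of the gene's count to its across-sample geometric
#' mean. Columns that are identical get factor 1.
#'
#' @param counts count matrix.
#' @return named positive numeric vector, one factor per sample.
#' @export
size_factors <- function(counts) {
  log_geo <- rowMeans(log(counts))
  use <- is.finite(log_geo)  # genes with a nonzero count in every sample
  if (!any(use)) input_error("no gene has nonzero counts in every sample")
  apply(counts, 2L, function(col) {
    exp(stats::median(log(col[use]) - log_geo[use]))
  })
}

#' Per-gene NB dispersions with a parametric mean trend
#'
#' Method-of-moments gene dispersions from size-factor-normalized counts,
#' using within-condition (pooled) variance:
#' \eqn{\phi_g = (v_g - \bar{\xi}\,\mu_g)/\mu_g^2} with \eqn{v_g} the
#' pooled within-condition sample variance, \eqn{\mu_g} the normalized
#' mean and \eqn{\bar{\xi}} the mean reciprocal size factor (the shot-noise
#' term). A parametric trend \eqn{\phi(\mu) = a_0 + a_1/\mu} is fitted to
#' the genes with positive raw dispersion by iterated gamma-family
#' regression, and the working dispersion is the maximum of the gene
#' estimate and the trend (conservative sharing), floored at 1e-8.
#'
#' @param counts filtered count matrix.
#' @param sf size factors from [size_factors()].
#' @param conditions factor/character of per-sample conditions.
#' @return list: `dispersion` (working per-gene values), `raw`
#'   (method-of-moments values, may be negative), `fitted` (trend values),
#'   `a0`, `a1`, `base_mean`.
#' @export
estimate_dispersions <- function(counts, sf, conditions) {
  conditions <- as.character(conditions)
  stopifnot(length(conditions) == ncol(counts), length(sf) == ncol(counts))
  reps <- table(conditions)
  if (all(reps < 2)) {
    input_error(paste("no condition has replicates; dispersion cannot be",
                      "estimated (blind/pooled-over-conditions modes are not supported)"))
  }
  q <- sweep(counts, 2L, sf, `/`)
  base_mean <- rowMeans(q)
  # pooled within-condition variance over replicated conditions
  ss <- 0
  df <- 0
  used <- logical(ncol(counts))
  for (cond in names(reps)[reps >= 2]) {
    j <- conditions == cond
    used <- used | j
    m <- rowMeans(q[, j, drop = FALSE])
    ss <- ss + rowSums((q[, j, drop = FALSE] - m)^2)
    df <- df + sum(j) - 1L
  }
  v <- ss / df
  xi <- mean(1 / sf[used])
  raw <- (v - xi * base_mean) / base_mean^2
  raw[!is.finite(raw)] <- NA_real_
  fit <- fit_dispersion_trend(base_mean, raw)
  fitted_vals <- fit$a0 + fit$a1 / base_mean
  disp <- pmax(ifelse(is.na(raw), -Inf, raw), fitted_vals, na.rm = FALSE)
  disp <- pmax(disp, 1e-8)
  list(dispersion = disp, raw = raw, fitted = fitted_vals,
       a0 = fit$a0, a1 = fit$a1, base_mean = base_mean)
}

# gamma-family identity-link regression of dispersion on 1/mean, iterated
# to self-consistent weights; falls back to least squares if the GLM
# cannot be fitted (few usable genes)
fit_dispersion_trend <- function(base_mean, raw) {
  use <- which(is.finite(raw) & raw > 0 & base_mean > 0)
  if (length(use) < 2) {
    # degenerate input (e.g. near-Poisson toy data): flat trend at a floor
    return(list(a0 = 1e-8, a1 = 0))
  }
  d <- raw[use]
  x <- 1 / base_mean[use]
  coefs <- c(0.1, 1)
  ok <- FALSE
  for (iter in 1:10) {
    fit <- tryCatch(
      suppressWarnings(
        stats::glm(d ~ x, family = stats::Gamma(link = "identity"),
                   start = coefs, control = list(maxit = 50))),
      error = function(e) NULL)
    if (is.null(fit)) break
    new_coefs <- unname(stats::coef(fit))
    if (any(!is.finite(new_coefs))) break
    converged <- max(abs(new_coefs - coefs) / (abs(coefs) + 1e-8)) < 1e-6
    coefs <- new_coefs
    ok <- TRUE
    if (converged) break
  }
  if (!ok) {
    ls <- stats::lm(d ~ x)
    coefs <- unname(stats::coef(ls))
  }
  list(a0 = max(coefs[1], 0), a1 = max(coefs[2], 0))
}

#' NB exact test for one gene
#'
#' Conditions on the total count \eqn{K} of the gene across both sample
#' groups and asks how probable splits at least as extreme as the observed
#' one are. Each split \eqn{(a, K-a)} has probability
#' \eqn{p(a) = f_A(a) f_B(K-a)} where \eqn{f_A} is the NB density of the
#' group-A sum with mean \eqn{\hat q \sum_{j \in A} s_j} and variance
#' \eqn{\hat q \sum_A s_j + \phi\, \hat q^2 \sum_A s_j^2}
#' (\eqn{\hat q} the pooled normalized mean). The p-value is the sum of
#' the probabilities of all splits no more probable than the observed one,
#' normalized by the total over all splits.
#'
#' @param k_a,k_b integer count vectors (replicates of groups A and B).
#' @param sf_a,sf_b size factors of the same samples.
#' @param phi NB dispersion (>= 0).
#' @return two-sided p-value in (0, 1]; a gene with all counts zero
#'   returns 1 (no evidence).
#' @export
nb_exact_test <- function(k_a, k_b, sf_a, sf_b, phi) {
  stopifnot(phi >= 0, length(k_a) >= 1, length(k_b) >= 1)
  ka <- sum(k_a)
  kb <- sum(k_b)
  K <- ka + kb
  if (K == 0) return(1)
  q_hat <- K / (sum(sf_a) + sum(sf_b))
  p <- nb_test_pval(ka, K, q_hat, sum(sf_a), sum(sf_a^2), sum(sf_b), sum(sf_b^2), phi)
  min(1, p)
}

# core of the exact test: p-value for observed group-A sum `ka` of total K
nb_test_pval <- function(ka, K, q_hat, sA, sA2, sB, sB2, phi) {
  mu_a <- q_hat * sA
  mu_b <- q_hat * sB
  # variance of a sum of NB replicates; floored just above Poisson so the
  # NB size parameter stays finite as phi -> 0
  var_a <- max(mu_a + phi * q_hat^2 * sA2, mu_a * (1 + 1e-8))
  var_b <- max(mu_b + phi * q_hat^2 * sB2, mu_b * (1 + 1e-8))
  size_a <- mu_a^2 / (var_a - mu_a)
  size_b <- mu_b^2 / (var_b - mu_b)
  a <- 0:K
  ps <- stats::dnbinom(a, mu = mu_a, size = size_a) *
    stats::dnbinom(K - a, mu = mu_b, size = size_b)
  total <- sum(ps)
  if (total == 0) return(1)
  p_obs <- ps[ka + 1]
  sum(ps[ps <= p_obs * (1 + 1e-7)]) / total
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment in input order (wraps [stats::p.adjust()]).
#'
#' @param pvals numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values, same order.
#' @export
bh_adjust <- function(pvals) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE)) {
    input_error("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvals, method = "BH")
}

#' Differential enrichment between two sample types
#'
#' The full per-comparison pipeline: restrict to the two types' samples,
#' drop low-count genes ([filter_low_counts()]), estimate size factors and
#' dispersions, run the NB exact test per gene, adjust with
#' Benjamini-Hochberg, and call a gene enriched in type A when
#' `padj < alpha` and its normalized fold enrichment exceeds 1.
#'
#' @param counts full count matrix.
#' @param sample_sheet data.frame with `sample_id`, `sample_type`.
#' @param type_a,type_b the sample types compared; enrichment is reported
#'   for A over B.
#' @param alpha BH-adjusted significance cutoff (default 0.1).
#' @param min_cpm,max_samples_below low-count filter settings (see
#'   [filter_low_counts()]).
#' @return data.frame of class `"tutag_de"`: `gene_id`, `base_mean_a`,
#'   `base_mean_b` (normalized means), `fold_enrichment` (A over B; `Inf`
#'   when B is zero), `pval`, `padj`, `enriched`; comparison metadata in
#'   attributes (`type_a`, `type_b`, `alpha`, `size_factors`,
#'   `dispersion_a0`, `dispersion_a1`).
#' @export
run_comparison <- function(counts, sample_sheet, type_a, type_b, alpha = 0.1,
                           min_cpm = 1, max_samples_below = 2) {
  for (ty in c(type_a, type_b)) {
    n <- sum(sample_sheet$sample_type == ty)
    if (n < 2) input_error("sample type '%s' has %d sample(s); need at least 2", ty, n)
  }
  ids_a <- sample_sheet$sample_id[sample_sheet$sample_type == type_a]
  ids_b <- sample_sheet$sample_id[sample_sheet$sample_type == type_b]
  missing <- setdiff(c(ids_a, ids_b), colnames(counts))
  if (length(missing)) {
    input_error("sample sheet names samples absent from matrix: %s",
                paste(missing, collapse = ", "))
  }
  filtered <- filter_low_counts(counts, c(ids_a, ids_b),
                                min_cpm = min_cpm,
                                max_samples_below = max_samples_below)
  sf <- size_factors(filtered)
  cond <- ifelse(colnames(filtered) %in% ids_a, type_a, type_b)
  disp <- estimate_dispersions(filtered, sf, cond)
  q <- sweep(filtered, 2L, sf, `/`)
  in_a <- colnames(filtered) %in% ids_a
  mean_a <- rowMeans(q[, in_a, drop = FALSE])
  mean_b <- rowMeans(q[, !in_a, drop = FALSE])
  sf_a <- sf[in_a]
  sf_b <- sf[!in_a]
  sA <- sum(sf_a); sA2 <- sum(sf_a^2)
  sB <- sum(sf_b); sB2 <- sum(sf_b^2)
  ka <- rowSums(filtered[, in_a, drop = FALSE])
  kb <- rowSums(filtered[, !in_a, drop = FALSE])
  K <- ka + kb
  q_hat <- K / (sA + sB)
  pval <- vapply(seq_len(nrow(filtered)), function(g) {
    if (K[g] == 0) return(1)
    min(1, nb_test_pval(ka[g], K[g], q_hat[g], sA, sA2, sB, sB2,
                        disp$dispersion[g]))
  }, numeric(1))
  padj <- bh_adjust(pval)
  fold <- ifelse(mean_b > 0, mean_a / mean_b, ifelse(mean_a > 0, Inf, NaN))
  out <- data.frame(
    gene_id = rownames(filtered),
    base_mean_a = mean_a,
    base_mean_b = mean_b,
    fold_enrichment = fold,
    pval = pval,
    padj = padj,
    enriched = padj < alpha & fold > 1,
    row.names = NULL,
    stringsAsFactors = FALSE
  )
  attr(out, "type_a") <- type_a
  attr(out, "type_b") <- type_b
  attr(out, "alpha") <- alpha
  attr(out, "size_factors") <- sf
  attr(out, "dispersion_a0") <- disp$a0
  attr(out, "dispersion_a1") <- disp$a1
  class(out) <- c("tutag_de", class(out))
  out
}
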