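#' Restrict a marker gene set to a testing universe
#'
#' Genes outside the filtered-count universe were never eligible for
#' enrichment, so marker sets are intersected with the universe before any
#' overlap statistics (order-stable).
#'
#' @param db_set character vector of gene ids (a marker set).
#' @param universe character vector of gene ids (the filtered universe).
#' @return the subset of `db_set` present in `universe`.
#' @export
restrict_to_universe <- function(db_set, universe) {
  out <- db_set[db_set %in% universe]
  if (!length(out)) {
    warning("marker set shares no genes with the universe", call. = FALSE)
  }
  out
}

#' Resampled null distribution of overlap sizes
#'
#' Repeatedly samples `n` genes without replacement from the universe and
#' records how many fall in the marker set; the distribution of that count
#' under "no association" between enrichment and the marker set.
#'
#' @param n number of genes per draw (the enriched-list size).
#' @param universe gene-id vector to sample from.
#' @param db_set marker set (pre-restricted to the universe).
#' @param B number of resamples (default 1000).
#' @param seed optional integer seed.
#' @return integer vector of length `B`.
#' @export
resample_null <- function(n, universe, db_set, B = 1000, seed = NULL) {
  N <- length(universe)
  if (n > N) input_error("cannot sample %d genes from a universe of %d", n, N)
  # canonical (sorted) order so results do not depend on how the universe
  # happens to be ordered
  in_db <- sort(universe) %in% db_set
  with_seed(seed, {
    vapply(seq_len(B), function(i) sum(in_db[sample.int(N, n)]), integer(1))
  })
}

#' Resampling test for overlap with a marker gene set
#'
#' Compares the observed overlap between an enriched gene list and a
#' marker set against `B` random draws of the same list size from the
#' filtered universe. The resampling mean is the "estimate"; with
#' `d = |observed - estimate|`, the two-sided p-value is
#' `(#\{x < estimate - d\} + #\{x > estimate + d\}) / B` (strict
#' inequalities, so p = 0 is attainable); a `(count+1)/(B+1)`-corrected
#' p is reported alongside. The 95% interval is the empirical 2.5/97.5
#' percentile band, and the overlap is flagged significant when the
#' observed value falls outside it (direction reported). An exact
#' hypergeometric mean and two-sided p are included as a closed-form
#' cross-check.
#'
#' @param enriched enriched gene list (subset of `universe`).
#' @param universe filtered-count gene universe.
#' @param db_set marker set (restricted to the universe internally).
#' @param B number of resamples (default 1000).
#' @param seed optional integer seed.
#' @return list of class `"tutag_overlap"`; see fields in the source.
#' @export
overlap_test <- function(enriched, universe, db_set, B = 1000, seed = NULL) {
  extra <- setdiff(enriched, universe)
  if (length(extra)) {
    input_error("enriched list contains %d gene(s) outside the universe (e.g. '%s')",
                length(extra), extra[1])
  }
  db <- restrict_to_universe(db_set, universe)
  n <- length(enriched)
  N <- length(universe)
  K <- length(db)
  observed <- sum(enriched %in% db)
  draws <- resample_null(n, universe, db, B = B, seed = seed)
  est <- mean(draws)
  d <- abs(observed - est)
  p <- (sum(draws < est - d) + sum(draws > est + d)) / B
  p_corrected <- (sum(draws <= est - d) + sum(draws >= est + d) + 1) / (B + 1)
  ci <- unname(stats::quantile(draws, c(0.025, 0.975)))
  significant <- observed < ci[1] || observed > ci[2]
  direction <- if (observed > ci[2]) "above" else if (observed < ci[1]) "below" else "none"
  hyper <- hypergeom_oracle(n, N, K, observed)
  degenerate <- stats::sd(draws) == 0
  structure(list(
    universe_size = N,
    db_in_universe = K,
    enriched_size = n,
    observed_overlap = observed,
    resample_mean = est,
    resample_sd = stats::sd(draws),
    ci95 = ci,
    p_resample = p,
    p_resample_corrected = p_corrected,
    significant = significant,
    direction = direction,
    degenerate_null = degenerate,
    hypergeom_mean = hyper$mean,
    hypergeom_p = hyper$p,
    n_resamples = B,
    seed = seed
  ), class = "tutag_overlap")
}

#' Hypergeometric mean and exact two-sided p for an overlap
#'
#' Closed-form twin of the resampling null: the overlap of a random
#' n-subset of an N-gene universe with a K-gene set is hypergeometric with
#' mean nK/N. The two-sided p sums the point masses not exceeding the
#' observed one.
#'
#' @param n subset (enriched-list) size.
#' @param N universe size.
#' @param K marker-set size within the universe.
#' @param observed observed overlap.
#' @return list with `mean` and `p`.
#' @export
hypergeom_oracle <- function(n, N, K, observed) {
  if (K < 0 || K > N || n < 0 || n > N) {
    input_error("need 0 <= K <= N and 0 <= n <= N (got n=%s, N=%s, K=%s)", n, N, K)
  }
  if (observed < 0 || observed > min(n, K)) {
    input_error("observed overlap %s outside [0, min(n, K)]", observed)
  }
  support <- max(0, n + K - N):min(n, K)
  mass <- stats::dhyper(support, K, N - K, n)
  p_obs <- stats::dhyper(observed, K, N - K, n)
  list(mean = n * K / N, p = min(1, sum(mass[mass <= p_obs * (1 + 1e-7)])))
}

#' Overlap tests for every marker set (layer-table analog)
#'
#' Runs [overlap_test()] for each set in a named list and binds the
#' results into a one-row-per-set data.frame, mirroring a per-layer
#' overlap summary table.
#'
#' @inheritParams overlap_test
#' @param gene_sets named list of marker sets.
#' @return data.frame, one row per set.
#' @export
overlap_table <- function(enriched, universe, gene_sets, B = 1000, seed = NULL) {
  rows <- lapply(seq_along(gene_sets), function(i) {
    res <- overlap_test(enriched, universe, gene_sets[[i]], B = B,
                        seed = if (is.null(seed)) NULL else derive_seed(seed, i))
    data.frame(
      set_name = names(gene_sets)[i],
      db_in_universe = res$db_in_universe,
      observed_overlap = res$observed_overlap,
      resample_mean = res$resample_mean,
      resample_sd = res$resample_sd,
      ci_low = res$ci95[1],
      ci_high = res$ci95[2],
      p_resample = res$p_resample,
      p_resample_corrected = res$p_resample_corrected,
      hypergeom_p = res$hypergeom_p,
      significant = res$significant,
      direction = res$direction,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Venn partition of two enriched gene lists
#'
#' Splits two enriched lists into exclusive and shared portions and
#' reports, per partition, the percentage of genes belonging to a marker
#' set (100 x overlap / partition size; 0 with a flag for an empty
#' partition).
#'
#' @param enriched_a,enriched_b enriched gene-id vectors.
#' @param db_set marker set used for the percentages.
#' @return list of class `"tutag_venn"` with `only_a`, `only_b`, `both`,
#'   per-partition sizes and marker percentages.
#' @export
venn_partition <- function(enriched_a, enriched_b, db_set) {
  enriched_a <- unique(enriched_a)
  enriched_b <- unique(enriched_b)
  both <- intersect(enriched_a, enriched_b)
  only_a <- setdiff(enriched_a, both)
  only_b <- setdiff(enriched_b, both)
  pct <- function(part) {
    if (!length(part)) return(c(pct = 0, empty = 1))
    c(pct = 100 * sum(part %in% db_set) / length(part), empty = 0)
  }
  structure(list(
    only_a = only_a, only_b = only_b, both = both,
    sizes = c(only_a = length(only_a), only_b = length(only_b),
              both = length(both)),
    pct_in_set = c(only_a = unname(pct(only_a)["pct"]),
                   only_b = unname(pct(only_b)["pct"]),
                   both = unname(pct(both)["pct"])),
    empty_partition = c(only_a = !length(only_a), only_b = !length(only_b),
                        both = !length(both))
  ), class = "tutag_venn")
}
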