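#' Rank genes by descending fold enrichment
#'
#' Assigns rank 1 to the gene with the strongest fold enrichment in a
#' differential-enrichment result and increasing ranks to weaker
#' enrichments. Ties in fold enrichment are broken by ascending adjusted
#' p-value, then by gene id (stable). Each gene is flagged as a member of
#' the supplied marker set (intersected with the ranked universe).
#'
#' @param de a [run_comparison()] result.
#' @param member_set gene-id vector (e.g. layer 2/3 markers).
#' @param enriched_only rank only the genes called enriched instead of the
#'   full filtered universe (default `FALSE`).
#' @return data.frame: `gene_id`, `rank`, `fold_enrichment`, `padj`,
#'   `is_member`.
#' @export
rank_by_fold_enrichment <- function(de, member_set, enriched_only = FALSE) {
  df <- as.data.frame(de)
  if (enriched_only) df <- df[df$enriched, , drop = FALSE]
  if (!nrow(df)) input_error("no genes to rank")
  ord <- order(-df$fold_enrichment, df$padj, df$gene_id, method = "radix")
  df <- df[ord, , drop = FALSE]
  data.frame(
    gene_id = df$gene_id,
    rank = seq_len(nrow(df)),
    fold_enrichment = df$fold_enrichment,
    padj = df$padj,
    is_member = df$gene_id %in% member_set,
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

# IRLS core: maximum-likelihood logistic regression of y on design X
irls_logistic <- function(X, y, max_iter = 50, tol = 1e-8) {
  beta <- rep(0, ncol(X))
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    p <- stats::plogis(eta)
    w <- pmax(p * (1 - p), 1e-12)
    z <- eta + (y - p) / w
    XtW <- t(X * w)
    beta_new <- tryCatch(drop(solve(XtW %*% X, XtW %*% z)),
                         error = function(e) NULL)
    if (is.null(beta_new) || any(!is.finite(beta_new))) break
    delta <- max(abs(beta_new - beta))
    beta <- beta_new
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  eta <- drop(X %*% beta)
  p <- stats::plogis(eta)
  w <- pmax(p * (1 - p), 1e-12)
  cov_beta <- tryCatch(solve(t(X * w) %*% X), error = function(e) {
    matrix(NA_real_, ncol(X), ncol(X))
  })
  eps <- 1e-12
  deviance <- -2 * sum(y * log(pmax(p, eps)) + (1 - y) * log(pmax(1 - p, eps)))
  list(beta = beta, cov = cov_beta, converged = converged,
       iterations = iter, deviance = deviance)
}

#' Binomial logistic regression of marker membership on enrichment rank
#'
#' Fits `is_member ~ rank` by iteratively reweighted least squares
#' (Fisher scoring on the binomial log-likelihood), the model behind the
#' "probability of finding a layer marker as a function of enrichment
#' rank" curve. Convergence when the largest coefficient change is below
#' 1e-8 or after 50 iterations; Wald standard errors come from the
#' inverse Fisher information. Complete separation yields a
#' non-converged fit with a warning, not an error.
#'
#' @param ranked a [rank_by_fold_enrichment()] result (or any data.frame
#'   with numeric `rank` and logical `is_member`).
#' @return list of class `"tutag_logistic"`: `intercept`, `slope`,
#'   `se`, `z`, `p`, `converged`, `n_obs`, `deviance`.
#' @export
fit_logistic <- function(ranked) {
  y <- as.numeric(ranked$is_member)
  if (length(unique(y)) < 2) {
    input_error("both member and non-member genes are required for the fit")
  }
  X <- cbind(intercept = 1, rank = as.numeric(ranked$rank))
  fit <- irls_logistic(X, y)
  if (!fit$converged) {
    warning("logistic fit did not converge (possible complete separation); coefficients may diverge",
            call. = FALSE)
  }
  se <- sqrt(diag(fit$cov))
  z <- fit$beta / se
  structure(list(
    intercept = unname(fit$beta[1]),
    slope = unname(fit$beta[2]),
    se = unname(se),
    z = unname(z),
    p = unname(2 * stats::pnorm(-abs(z))),
    converged = fit$converged,
    iterations = fit$iterations,
    n_obs = length(y),
    deviance = fit$deviance
  ), class = "tutag_logistic")
}

#' Predicted membership probability along the rank axis
#'
#' Inverse-logit of `intercept + slope * rank`; strictly monotone in rank
#' whenever the slope is nonzero.
#'
#' @param fit a converged [fit_logistic()] result.
#' @param ranks numeric vector of ranks.
#' @return probabilities in (0, 1).
#' @export
predict_curve <- function(fit, ranks) {
  if (!isTRUE(fit$converged)) {
    input_error("cannot predict from a non-converged logistic fit")
  }
  stats::plogis(fit$intercept + fit$slope * ranks)
}

#' Leading-fold-change multidimensional scaling of samples
#'
#' The distance between two samples is the root mean square of their
#' `top` largest absolute log2 ratios of normalized counts (0.5
#' pseudocount), i.e. the genes that most distinguish the pair; classical
#' (Torgerson) MDS of the resulting distance matrix gives per-sample 2-D
#' coordinates.
#'
#' @param counts count matrix with at least 3 samples.
#' @param top number of largest fold changes entering each pairwise
#'   distance (default 500, capped at the gene count).
#' @return list: `coordinates` (samples x 2), `distances` (dist matrix as
#'   a full symmetric matrix).
#' @export
mds_leading_foldchange <- function(counts, top = 500) {
  if (ncol(counts) < 3) input_error("MDS needs at least 3 samples, got %d", ncol(counts))
  sf <- size_factors(counts)
  l <- log2(sweep(counts, 2L, sf, `/`) + 0.5)
  top <- min(top, nrow(counts))
  n <- ncol(counts)
  d <- matrix(0, n, n, dimnames = list(colnames(counts), colnames(counts)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      lfc2 <- (l[, i] - l[, j])^2
      d[i, j] <- d[j, i] <- sqrt(mean(sort(lfc2, decreasing = TRUE)[seq_len(top)]))
    }
  }
  coords <- suppressWarnings(stats::cmdscale(stats::as.dist(d), k = 2))
  if (ncol(coords) < 2) {  # degenerate configurations span < 2 dimensions
    coords <- cbind(coords, matrix(0, nrow = n, ncol = 2 - ncol(coords)))
    rownames(coords) <- colnames(counts)
  }
  colnames(coords) <- c("dim1", "dim2")
  list(coordinates = coords, distances = d)
}
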