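# Shared fixture builders (all fixtures are constructed in code).

# a tiny labeled count matrix
tiny_counts <- function() {
  m <- matrix(c(1L, 3L,
                5L, 0L,
                2L, 2L), nrow = 3, byrow = TRUE,
              dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
  m
}

# small simulation config for fast tests
small_config <- function(...) {
  simulation_config(n_genes = 400, seed = 99, ...)
}

# NB matrix with constant dispersion for normalization/dispersion tests
nb_matrix <- function(n_genes, n_samples, mu_range = c(50, 2000), phi = 0.05,
                      seed = 1) {
  withr::with_seed(seed, {
    mu <- exp(stats::runif(n_genes, log(mu_range[1]), log(mu_range[2])))
    m <- sapply(seq_len(n_samples), function(j) {
      if (phi > 0) stats::rnbinom(n_genes, mu = mu, size = 1 / phi)
      else stats::rpois(n_genes, mu)
    })
    dimnames(m) <- list(paste0("g", seq_len(n_genes)),
                        paste0("s", seq_len(n_samples)))
    m
  })
}

# independent median-of-ratios computation (loop-based, no shared code)
brute_size_factors <- function(counts) {
  geo <- apply(counts, 1, function(r) exp(mean(log(r))))
  keep <- apply(counts, 1, function(r) all(r > 0))
  sapply(seq_len(ncol(counts)), function(j) {
    stats::median(counts[keep, j] / geo[keep])
  })
}

# independent NB exact test by explicit enumeration with lgamma-based pmfs
brute_nb_exact <- function(ka_sum, K, q_hat, sf_a, sf_b, phi) {
  nb_pmf <- function(k, mu, var) {
    if (var <= mu * (1 + 1e-8)) var <- mu * (1 + 1e-8)
    size <- mu^2 / (var - mu)
    p <- size / (size + mu)
    exp(lgamma(k + size) - lgamma(size) - lgamma(k + 1) +
          size * log(p) + k * log1p(-p))
  }
  mu_a <- q_hat * sum(sf_a); mu_b <- q_hat * sum(sf_b)
  var_a <- mu_a + phi * q_hat^2 * sum(sf_a^2)
  var_b <- mu_b + phi * q_hat^2 * sum(sf_b^2)
  probs <- vapply(0:K, function(a) {
    nb_pmf(a, mu_a, var_a) * nb_pmf(K - a, mu_b, var_b)
  }, numeric(1))
  sum(probs[probs <= probs[ka_sum + 1] * (1 + 1e-7)]) / sum(probs)
}

# independent Newton optimizer of the logistic log-likelihood
newton_logistic <- function(x, y, iters = 100) {
  beta <- c(0, 0)
  X <- cbind(1, x)
  for (i in seq_len(iters)) {
    p <- 1 / (1 + exp(-drop(X %*% beta)))
    grad <- drop(t(X) %*% (y - p))
    H <- -t(X) %*% (X * (p * (1 - p)))
    step <- drop(solve(H, grad))
    beta <- beta - step
    if (max(abs(step)) < 1e-12) break
  }
  unname(beta)
}
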