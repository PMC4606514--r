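# Small fixtures built in code, shared across test files.

tiny_geno <- function(codes = matrix(c(0, 2, 1, 1, 1, 2), nrow = 3),
                      ids = NULL, markers = NULL) {
  if (is.null(ids)) ids <- paste0("i", seq_len(nrow(codes)))
  if (is.null(markers)) markers <- paste0("m", seq_len(ncol(codes)))
  rownames(codes) <- ids
  colnames(codes) <- markers
  geno_matrix(codes)
}

# random valid genotype matrix under HWE at given frequencies
random_geno <- function(n, m, p = runif(m, 0.1, 0.5), seed = 1) {
  set.seed(seed)
  codes <- matrix(rbinom(n * m, 2, rep(p, each = n)), n, m)
  # guard against accidentally monomorphic columns in tiny fixtures
  mono <- apply(codes, 2, function(x) all(x == x[1]))
  for (j in which(mono)) codes[1, j] <- (codes[1, j] + 1) %% 3
  tiny_geno(codes)
}

fast_chain <- function(n_iterations = 600, burn_in = 150, mh_cycles = 5,
                       seed = 1) {
  chain_config(n_iterations, burn_in, mh_cycles = mh_cycles, seed = seed)
}

# dense-covariance log-likelihood of y ~ N(0, sigma2 * w w' + sigma2_e I),
# independent oracle for the rank-one identity used in the MH ratio
dense_loglik <- function(sigma2, w, y, sigma2_e) {
  V <- sigma2 * tcrossprod(w) + diag(sigma2_e, length(y))
  ch <- chol(V)
  -sum(log(diag(ch))) - 0.5 * sum(backsolve(ch, y, transpose = TRUE)^2)
}
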