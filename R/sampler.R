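#' Prior specification for the Bayesian marker models
#'
#' Marker-effect variances follow a scaled inverse chi-squared prior
#' `x^-2(v, S)` (a draw equals `S / chisq_v`, so its mean is `S / (v - 2)`);
#' the default `v = 4.234`, `S = 0.0429` is the classical genomic-selection
#' choice. The residual variance prior is `x^-2(-2, 0)`, i.e. flat on the
#' variance scale, so its full conditional is `x^-2(n - 2, e'e)`. `pi` is the
#' prior probability that a marker is non-effective: a scalar (BayesB,
#' default 0.95) or a per-marker vector (BayesB-pi).
#'
#' @param v_marker,S_marker Marker-variance prior degrees of freedom and
#'   scale (`S_marker > 0`).
#' @param v_resid,S_resid Residual-variance prior parameters (kept for
#'   provenance; the sampler's residual update implements the default flat
#'   prior).
#' @param pi Scalar or length-m vector in `[0, 1]`.
#' @return Object of class `prior_spec`.
#' @export
prior_spec <- function(v_marker = 4.234, S_marker = 0.0429,
                       v_resid = -2, S_resid = 0, pi = 0.95) {
  stopifnot(S_marker > 0, all(pi >= 0 & pi <= 1))
  structure(list(v_marker = v_marker, S_marker = S_marker,
                 v_resid = v_resid, S_resid = S_resid, pi = pi),
            class = "prior_spec")
}

#' MCMC chain configuration
#'
#' Defaults follow the standard protocol for these samplers: 10,000 sweeps
#' with the first 2,000 discarded as burn-in and 100 Metropolis-Hastings
#' cycles per locus per sweep. At desk scale far shorter chains (and 5-10 MH
#' cycles) give indistinguishable posterior means and are used in tests.
#'
#' @param n_iterations Total sweeps.
#' @param burn_in Discarded sweeps (`burn_in < n_iterations`).
#' @param mh_cycles Inner MH cycles per locus per sweep (`>= 1`).
#' @param seed Integer seed driving the chain's counter-based generator.
#' @param thinning Keep every `thinning`-th post-burn-in sweep.
#' @return Object of class `chain_config`.
#' @export
chain_config <- function(n_iterations = 10000L, burn_in = 2000L,
                         mh_cycles = 100L, seed = 1L, thinning = 1L) {
  stopifnot(burn_in >= 0, burn_in < n_iterations, mh_cycles >= 1,
            thinning >= 1)
  structure(list(n_iterations = as.integer(n_iterations),
                 burn_in = as.integer(burn_in),
                 mh_cycles = as.integer(mh_cycles),
                 seed = as.integer(seed),
                 thinning = as.integer(thinning)),
            class = "chain_config")
}

# ---------------------------------------------------------------------------
# Primitive conditional-sampling operations (reference R implementations,
# driven by R's RNG). The compiled chain reimplements these draws on its
# keyed generator; these functions document and unit-test the distributions.
# ---------------------------------------------------------------------------

#' Draw a marker-effect variance from its full conditional
#'
#' One draw from `x^-2(v + n_j, S + g_j' g_j)`, the scaled inverse
#' chi-squared full conditional of a locus variance given its current
#' effect(s).
#'
#' @param g_j Current effect at the locus (scalar for single-SNP loci).
#' @param n_j Number of effects at the locus (1 for single SNPs).
#' @param prior A [prior_spec()].
#' @param n Number of draws (vectorised for tests).
#' @return Numeric vector of variance draws.
#' @export
sample_marker_variance <- function(g_j, n_j = 1, prior = prior_spec(),
                                   n = 1) {
  (prior$S_marker + sum(g_j^2)) /
    stats::rchisq(n, df = prior$v_marker + n_j)
}

#' Draw the residual variance from its full conditional
#'
#' One draw from `x^-2(n - 2, e'e)`, i.e. `e'e / chisq_(n-2)`.
#'
#' @param e Current residual vector (length `n > 2`).
#' @param n_draws Number of draws.
#' @return Numeric vector of variance draws.
#' @export
sample_residual_variance <- function(e, n_draws = 1) {
  n <- length(e)
  if (n <= 2) stop("need more than 2 residuals, got ", n)
  sum(e^2) / stats::rchisq(n_draws, df = n - 2)
}

#' Draw the overall mean from its full conditional
#'
#' Gaussian centered at the mean of the genotype-adjusted phenotypes,
#' `(1'y - 1'Wg)/n`, with variance `sigma2_e / n`.
#'
#' @param y Response vector.
#' @param W Centered genotype matrix.
#' @param g Current marker effects.
#' @param sigma2_e Current residual variance.
#' @param n_draws Number of draws.
#' @return Numeric vector of draws.
#' @export
sample_overall_mean <- function(y, W, g, sigma2_e, n_draws = 1) {
  n <- length(y)
  center <- (sum(y) - sum(W %*% g)) / n
  if (sigma2_e == 0) return(rep(center, n_draws))
  stats::rnorm(n_draws, center, sqrt(sigma2_e / n))
}

#' Draw one marker effect from its conditional normal
#'
#' The conditional posterior of an in-model effect is
#' `N(w'y_adj / (w'w + sigma2_e/sigma2_g), sigma2_e / (w'w +
#' sigma2_e/sigma2_g))`, where `y_adj` is the data adjusted for everything
#' except locus `j`. The sampler state's residual vector is updated
#' consistently.
#'
#' @param j Locus index.
#' @param state Sampler state: list with `mu`, `g`, `sigma2_g`, `sigma2_e`,
#'   `e` satisfying `e = y - mu - W g`.
#' @param W Centered genotype matrix.
#' @param y Response vector.
#' @return The updated state (with new `g[j]` and residuals).
#' @export
sample_marker_effect <- function(j, state, W, y) {
  if (state$sigma2_g[j] <= 0)
    stop("sample_marker_effect called with sigma2_g[", j,
         "] = 0 (locus out of model)")
  w <- W[, j]
  wtw <- sum(w^2)
  wy <- sum(w * state$e) + wtw * state$g[j]
  denom <- wtw + state$sigma2_e / state$sigma2_g[j]
  g_new <- stats::rnorm(1, wy / denom, sqrt(state$sigma2_e / denom))
  state$e <- state$e + w * (state$g[j] - g_new)
  state$g[j] <- g_new
  state
}

#' Relative log marginal likelihood of a locus variance
#'
#' `log L(sigma2) - log L(0)` for `y_adj ~ N(0, sigma2 w w' + sigma2_e I)`,
#' evaluated with the rank-one determinant and Sherman-Morrison identities,
#' so it needs only `w'w` and `w'y_adj`. Used in the Metropolis-Hastings
#' acceptance ratio.
#'
#' @param sigma2 Proposed locus variance (0 allowed).
#' @param wtw,wy Scalars `w'w` and `w'y_adj`.
#' @param sigma2_e Residual variance.
#' @return Scalar log-likelihood difference.
#' @export
marginal_loglik_rel <- function(sigma2, wtw, wy, sigma2_e) {
  .loglik_rel_cpp(sigma2, wtw, wy, sigma2_e)
}

#' Metropolis-Hastings update of one locus (variance and effect)
#'
#' Reference R implementation of the BayesB/BayesB-pi per-locus update. Each
#' cycle draws `alpha ~ U(0,1)`; when `alpha < 1 - pi_j` a variance is
#' proposed from the slab `x^-2(v, S)`, otherwise the proposal is the point
#' mass at 0. Because the proposal is the mixture prior itself, the
#' acceptance probability reduces to the marginal likelihood ratio with the
#' effect integrated out. After the cycles, the effect is redrawn from its
#' conditional normal when the variance is positive, or set to 0.
#' `strict_gate = TRUE` gives the alternative reading in which a closed gate
#' skips the cycle entirely (no zero proposal).
#'
#' @inheritParams sample_marker_effect
#' @param prior A [prior_spec()]; `prior$pi` resolves to this locus's gate
#'   probability (scalar, or element `j` of a vector).
#' @param mh_cycles Number of MH cycles.
#' @param strict_gate Use the skip-entirely convention for a closed gate.
#' @return Updated state.
#' @export
mh_update_locus <- function(j, state, W, prior, mh_cycles = 100L,
                            strict_gate = FALSE) {
  pj <- if (length(prior$pi) > 1L) prior$pi[j] else prior$pi
  w <- W[, j]
  wtw <- sum(w^2)
  wy <- sum(w * state$e) + wtw * state$g[j]
  s2 <- state$sigma2_g[j]
  ll <- marginal_loglik_rel(s2, wtw, wy, state$sigma2_e)
  for (cyc in seq_len(mh_cycles)) {
    alpha <- stats::runif(1)
    if (alpha >= 1 - pj) {
      if (strict_gate) next
      s2_new <- 0
    } else {
      s2_new <- prior$S_marker / stats::rchisq(1, prior$v_marker)
    }
    ll_new <- marginal_loglik_rel(s2_new, wtw, wy, state$sigma2_e)
    if (log(stats::runif(1)) < ll_new - ll) {
      s2 <- s2_new
      ll <- ll_new
    }
  }
  state$sigma2_g[j] <- s2
  if (s2 > 0) {
    denom <- wtw + state$sigma2_e / s2
    g_new <- stats::rnorm(1, wy / denom, sqrt(state$sigma2_e / denom))
  } else {
    g_new <- 0
  }
  state$e <- state$e + w * (state$g[j] - g_new)
  state$g[j] <- g_new
  state
}

# ---------------------------------------------------------------------------
# Full chain
# ---------------------------------------------------------------------------

#' Run a BayesA / BayesB / BayesB-pi Gibbs chain
#'
#' Executes the full sampler on a centered genotype matrix: per sweep, each
#' locus's variance is updated (conjugate draw for BayesA; Metropolis-
#' Hastings with the pi gate for BayesB and BayesB-pi) and its effect
#' redrawn, then the residual variance and overall mean are refreshed.
#' Post-burn-in samples are averaged into the posterior summary. The chain is
#' driven by a counter-based generator keyed by (seed, sweep, locus), so runs
#' are reproducible for a given seed and invariant to marker reordering.
#'
#' @param y Numeric response (no NA).
#' @param W Numeric matrix of centered genotype codes (individuals x
#'   markers), column names = marker ids.
#' @param prior A [prior_spec()]; for `method = "bayesBpi"` its `pi` must be
#'   a length-m vector.
#' @param config A [chain_config()].
#' @param method `"bayesA"`, `"bayesB"` or `"bayesBpi"`.
#' @param strict_gate Closed-gate convention for the MH update, see
#'   [mh_update_locus()].
#' @param keep_effect_samples Return the post-burn-in effect draws (memory
#'   heavy; for diagnostics and tests).
#' @param update_resid_var,update_marker_var Internal switches that freeze
#'   the residual or marker variances at their initial values (used by the
#'   conjugate-posterior oracle tests).
#' @param locus_keys Integer keys identifying each locus's RNG stream
#'   (default `1:m`). Permuting markers together with their keys (and pi)
#'   reproduces the same chain up to the permutation.
#' @param sigma2_e_init,sigma2_g_init Initial values; defaults `var(y)/2`
#'   and 0.01 (parameters are initialised with small positive numbers).
#' @return Object of class `bayes_fit`: posterior-mean effects, per-marker
#'   inclusion frequencies (share of kept sweeps with the locus in the
#'   model), posterior means of `mu` and `sigma2_e`, sample count, and
#'   provenance (method, prior, config).
#' @export
run_mcmc <- function(y, W, prior = prior_spec(), config = chain_config(),
                     method = c("bayesA", "bayesB", "bayesBpi"),
                     strict_gate = FALSE, keep_effect_samples = FALSE,
                     update_resid_var = TRUE, update_marker_var = TRUE,
                     sigma2_e_init = NULL, sigma2_g_init = 0.01,
                     locus_keys = NULL) {
  method <- match.arg(method)
  y <- as.numeric(y)
  if (anyNA(y)) stop("y contains NA; mask individuals before calling")
  W <- as.matrix(W)
  if (nrow(W) != length(y)) stop("W rows must match length of y")
  m <- ncol(W)
  pi <- prior$pi
  if (method == "bayesBpi") {
    if (length(pi) != m)
      stop("method 'bayesBpi' needs a length-", m, " pi vector, got length ",
           length(pi))
  } else if (method == "bayesB") {
    if (length(pi) != 1L) stop("method 'bayesB' needs a scalar pi")
    pi <- rep(pi, m)
  } else {
    pi <- rep(0, m)  # BayesA: every locus always in the model
  }
  if (is.null(sigma2_e_init)) sigma2_e_init <- stats::var(y) / 2
  if (is.null(locus_keys)) locus_keys <- seq_len(m)
  stopifnot(length(locus_keys) == m, all(locus_keys >= 1))
  res <- .chain_run_cpp(
    y, W, method, pi, prior$v_marker, prior$S_marker,
    config$n_iterations, config$burn_in, config$mh_cycles, config$thinning,
    as.double(config$seed), strict_gate,
    as.integer(locus_keys), sigma2_e_init, sigma2_g_init,
    0.01, 0.01, update_resid_var, update_marker_var, keep_effect_samples)
  marker_id <- colnames(W) %||% paste0("m", seq_len(m))
  structure(
    list(method = method,
         effects = tibble::tibble(
           marker_id = marker_id,
           effect_mean = res$effect_means,
           effect_var = res$effect_vars,
           inclusion_freq = res$inclusion_freq),
         mu_mean = res$mu_mean,
         sigma2_e_mean = res$sigma2_e_mean,
         n_samples = res$n_samples,
         final_state = list(mu = res$final_mu, g = res$final_g,
                            sigma2_e = res$final_sigma2_e, e = res$final_e),
         effect_samples = res$effect_samples,
         prior = prior, config = config),
    class = "bayes_fit")
}

#' @export
print.bayes_fit <- function(x, ...) {
  cat("<bayes_fit> method = ", x$method, "; ", nrow(x$effects),
      " markers; ", x$n_samples, " kept samples\n",
      "  posterior mean sigma2_e = ", signif(x$sigma2_e_mean, 4),
      "; mean inclusion = ", signif(mean(x$effects$inclusion_freq), 3),
      "\n", sep = "")
  invisible(x)
}

#' @export
tidy.bayes_fit <- function(x, ...) x$effects

#' @export
glance.bayes_fit <- function(x, ...) {
  tibble::tibble(method = x$method, mu_mean = x$mu_mean,
                 sigma2_e_mean = x$sigma2_e_mean, n_samples = x$n_samples,
                 n_markers = nrow(x$effects),
                 seed = x$config$seed)
}

#' Plot posterior-mean effects along the genome
#'
#' @param object A `bayes_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bayes_fit <- function(object, ...) {
  df <- dplyr::mutate(object$effects, index = dplyr::row_number())
  ggplot2::ggplot(df, ggplot2::aes(x = .data$index,
                                   y = abs(.data$effect_mean))) +
    ggplot2::geom_point(size = 0.4, alpha = 0.6) +
    ggplot2::labs(x = "marker index", y = "|posterior mean effect|",
                  title = paste("Posterior marker effects:", object$method))
}

#' Genomic estimated breeding values from a fitted chain
#'
#' `GEBV = W_new %*% effect_means` (+ the posterior-mean intercept when
#' requested). `W_new` must be centered with the training-set allele
#' frequencies.
#'
#' @param fit A `bayes_fit`.
#' @param W_new Centered genotype matrix for the individuals to predict.
#' @param mu_included Add the posterior-mean overall mean.
#' @return Numeric GEBV vector.
#' @export
predict_gebv <- function(fit, W_new, mu_included = FALSE) {
  W_new <- as.matrix(W_new)
  if (ncol(W_new) != nrow(fit$effects))
    stop("W_new has ", ncol(W_new), " columns but the fit has ",
         nrow(fit$effects), " markers")
  out <- drop(W_new %*% fit$effects$effect_mean)
  if (mu_included) out <- out + fit$mu_mean
  out
}

#' Serialise a posterior summary
#'
#' Tab-separated `marker_id`, `effect_mean`, `inclusion_freq` preceded by a
#' small commented header of scalar posteriors and chain provenance.
#'
#' @param fit A `bayes_fit`.
#' @param path Output path.
#' @export
write_posterior <- function(fit, path) {
  hdr <- c(
    paste0("# method=", fit$method),
    paste0("# mu_mean=", format(fit$mu_mean, digits = 10)),
    paste0("# sigma2_e_mean=", format(fit$sigma2_e_mean, digits = 10)),
    paste0("# n_samples=", fit$n_samples),
    paste0("# seed=", fit$config$seed))
  writeLines(hdr, path)
  suppressWarnings(utils::write.table(
    fit$effects[, c("marker_id", "effect_mean", "inclusion_freq")],
    path, sep = "\t", quote = FALSE, row.names = FALSE, append = TRUE))
  invisible(path)
}

#' Fit a Bayesian marker model directly from a genotype matrix
#'
#' Convenience wrapper around [run_mcmc()]: imputes missing codes, centers
#' columns by twice the training-set allele frequency, fits on the
#' individuals with observed responses, and predicts GEBVs for everyone.
#' For `method = "bayesBpi"` with `pi = NULL`, the locus prior is computed
#' from the training individuals via [locus_pi()].
#'
#' @param genotypes A [geno_matrix()] over all individuals.
#' @param y Response with `NA` for individuals to predict.
#' @param method `"bayesA"`, `"bayesB"` or `"bayesBpi"`.
#' @param prior,config See [prior_spec()], [chain_config()].
#' @param pi Optional per-marker pi vector (overrides `prior$pi`).
#' @param center Center genotype columns by `2p` (recommended; a raw-coding
#'   mode is available for exact replication of the uncentered model).
#' @return A `bayes_fit` with an extra `gebv` element (all individuals) and
#'   `train` logical vector.
#' @export
bayes_fit <- function(genotypes, y, method = c("bayesB", "bayesA", "bayesBpi"),
                      prior = prior_spec(), config = chain_config(),
                      pi = NULL, center = TRUE) {
  method <- match.arg(method)
  g <- impute_missing(genotypes)
  train <- !is.na(y)
  if (sum(train) < 3L) stop("need at least 3 phenotyped individuals")
  p_train <- colMeans(g$codes[train, , drop = FALSE]) / 2
  W <- if (center) sweep(g$codes, 2L, 2 * p_train, "-") else g$codes
  if (method == "bayesBpi" && is.null(pi)) {
    pi <- locus_pi(g[which(train), ], y[train])$pi
  }
  if (!is.null(pi)) prior$pi <- pi
  fit <- run_mcmc(y[train], W[train, , drop = FALSE], prior, config, method)
  fit$gebv <- stats::setNames(predict_gebv(fit, W), individual_ids(g))
  fit$train <- train
  fit
}
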