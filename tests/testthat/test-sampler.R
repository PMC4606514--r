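test_that("marker-variance draws follow the scaled inverse chi-squared", {
  set.seed(61)
  draws <- sample_marker_variance(0, n = 1e5)
  # mean of S / chisq_(v+1) is S / (v + 1 - 2)
  expect_lt(abs(mean(draws) / (0.0429 / 3.234) - 1), 0.02)

  set.seed(62)
  d1 <- sample_marker_variance(0.3)
  set.seed(62)
  d2 <- sample_marker_variance(0.3)
  expect_identical(d1, d2)

  # a large current effect shifts the conditional upward (stochastic
  # dominance of the empirical CDF)
  set.seed(63)
  small <- sort(sample_marker_variance(0, n = 2000))
  set.seed(63)
  big <- sort(sample_marker_variance(10, n = 2000))
  expect_true(all(big >= small))
})

test_that("residual-variance draws scale with e'e", {
  expect_equal(sample_residual_variance(numeric(50)), 0)
  n <- 5000
  e <- rep(1, n) * sqrt((n - 4) / n)  # e'e = n - 4
  set.seed(64)
  draws <- sample_residual_variance(e, n_draws = 1e4)
  expect_lt(abs(mean(draws) - 1), 0.05)
  expect_error(sample_residual_variance(c(1, 2)), "more than 2")
})

test_that("overall-mean draws have the stated moments", {
  set.seed(65)
  n <- 400
  y <- rnorm(n); y <- y - mean(y)
  W <- matrix(rnorm(n * 3), n)
  draws <- sample_overall_mean(y, W, numeric(3), sigma2_e = 2, n_draws = 1e4)
  expect_lt(abs(mean(draws)), 0.01)  # MC error ~ sqrt(2/n)/100
  expect_lt(abs(var(draws) / (2 / n) - 1), 0.05)
  # degenerate case: zero residual variance returns the adjusted mean
  g <- c(0.5, -1, 2)
  exact <- (sum(y) - sum(W %*% g)) / n
  expect_identical(sample_overall_mean(y, W, g, 0), exact)
})

test_that("effect draws come from the conjugate ridge posterior", {
  set.seed(66)
  n <- 50
  W <- cbind(rnorm(n), rnorm(n))
  y <- rnorm(n)
  state <- list(mu = 0.3, g = c(0.2, -0.1), sigma2_g = c(0.5, 0.4),
                sigma2_e = 1.2)
  state$e <- y - state$mu - drop(W %*% state$g)

  w <- W[, 1]
  y_adj <- state$e + w * state$g[1]
  lambda <- state$sigma2_e / state$sigma2_g[1]
  mean_cf <- sum(w * y_adj) / (sum(w^2) + lambda)
  sd_cf <- sqrt(state$sigma2_e / (sum(w^2) + lambda))
  set.seed(67); expected_draw <- rnorm(1, mean_cf, sd_cf)
  set.seed(67); new_state <- sample_marker_effect(1, state, W, y)
  expect_equal(new_state$g[1], expected_draw, tolerance = 1e-10)
  # residuals stay consistent
  expect_equal(new_state$e, y - state$mu - drop(W %*% new_state$g),
               tolerance = 1e-10)

  # flat-prior limit reproduces least squares
  state_flat <- state; state_flat$sigma2_g[1] <- 1e12
  set.seed(68); flat <- sample_marker_effect(1, state_flat, W, y)$g[1]
  ls <- sum(w * y_adj) / sum(w^2)
  expect_lt(abs(flat - ls), 6 * sd_cf)
  expect_error(sample_marker_effect(2, within(state, sigma2_g[2] <- 0), W, y),
               "out of model")
})

test_that("the rank-one marginal likelihood matches dense evaluation", {
  set.seed(69)
  n <- 6
  w <- rnorm(n)
  y <- rnorm(n)
  for (s2 in c(0.01, 0.2, 1.5)) {
    rel <- marginal_loglik_rel(s2, sum(w^2), sum(w * y), 0.8)
    dense <- dense_loglik(s2, w, y, 0.8) - dense_loglik(0, w, y, 0.8)
    expect_equal(rel, dense, tolerance = 1e-8)
  }
  expect_identical(marginal_loglik_rel(0, 1, 1, 1), 0)
})

test_that("a closed gate (pi = 1) keeps a zeroed locus out of the model", {
  set.seed(70)
  W <- matrix(rnorm(40 * 3), 40)
  y <- rnorm(40)
  fit <- run_mcmc(y, W, prior = prior_spec(pi = rep(1, 3)),
                  config = fast_chain(), method = "bayesBpi",
                  sigma2_g_init = 0)
  expect_true(all(fit$effects$inclusion_freq == 0))
  expect_true(all(fit$effects$effect_mean == 0))
})

test_that("an open gate (pi = 0) keeps a major locus in the model", {
  ds <- simulate_dataset(arch_spec(500, 40, n_qtl = 5,
                                   major_qtl_fraction = 0.30,
                                   heritability = 0.5, seed = 71))
  major <- attr(ds, "qtl")[1]
  W <- sweep(ds$genotypes$codes, 2, 2 * ds$genotypes$allele_freq, "-")
  fit <- run_mcmc(ds$phenotypes[[2]], W,
                  prior = prior_spec(pi = rep(0, 40)),
                  config = fast_chain(seed = 72), method = "bayesBpi")
  expect_gt(fit$effects$inclusion_freq[major], 0.9)
})

test_that("null markers under pi = 0.95 are rarely included", {
  incl <- vapply(1:20, function(s) {
    set.seed(s)
    W <- scale(matrix(rbinom(500 * 4, 2, 0.3), 500), scale = FALSE)
    y <- rnorm(500)
    fit <- run_mcmc(y, W, prior = prior_spec(pi = 0.95),
                    config = fast_chain(300, 100, seed = s),
                    method = "bayesB")
    mean(fit$effects$inclusion_freq)
  }, numeric(1))
  expect_lt(mean(incl), 0.2)
})

test_that("BayesB-pi with a constant 0.95 vector reproduces BayesB exactly", {
  set.seed(73)
  W <- matrix(rnorm(60 * 10), 60)
  y <- rnorm(60) + W[, 4] * 0.8
  cfg <- fast_chain(seed = 74)
  fb <- run_mcmc(y, W, prior = prior_spec(pi = 0.95), cfg, "bayesB")
  fbpi <- run_mcmc(y, W, prior = prior_spec(pi = rep(0.95, 10)), cfg,
                   "bayesBpi")
  expect_identical(fb$effects$effect_mean, fbpi$effects$effect_mean)
  expect_identical(fb$sigma2_e_mean, fbpi$sigma2_e_mean)
})

test_that("chains are reproducible and permutation-equivariant", {
  set.seed(75)
  W <- matrix(rnorm(50 * 8), 50, dimnames = list(NULL, paste0("m", 1:8)))
  y <- rnorm(50) + W[, 2]
  cfg <- fast_chain(seed = 76)
  pi <- seq(0.1, 0.8, length.out = 8)
  f1 <- run_mcmc(y, W, prior_spec(pi = pi), cfg, "bayesBpi")
  f2 <- run_mcmc(y, W, prior_spec(pi = pi), cfg, "bayesBpi")
  expect_identical(f1$effects, f2$effects)

  perm <- sample(8)
  f3 <- run_mcmc(y, W[, perm], prior_spec(pi = pi[perm]), cfg, "bayesBpi",
                 locus_keys = perm)
  expect_equal(f3$effects$effect_mean, f1$effects$effect_mean[perm],
               tolerance = 1e-12)
})

test_that("residuals satisfy e = y - mu - Wg after the final sweep", {
  ds <- simulate_dataset(arch_spec(120, 60, n_qtl = 10,
                                   major_qtl_fraction = 0.3,
                                   heritability = 0.5, seed = 77))
  W <- sweep(ds$genotypes$codes, 2, 2 * ds$genotypes$allele_freq, "-")
  y <- ds$phenotypes[[2]]
  for (method in c("bayesA", "bayesB")) {
    fit <- run_mcmc(y, W, prior_spec(), fast_chain(seed = 78), method)
    st <- fit$final_state
    expect_lt(max(abs(st$e - (y - st$mu - drop(W %*% st$g)))), 1e-8)
  }
})

test_that("a noise-only response shrinks all posterior effects to nothing", {
  set.seed(79)
  W <- scale(matrix(rbinom(500 * 50, 2, 0.4), 500), scale = FALSE)
  y <- rnorm(500)
  fit <- run_mcmc(y, W, prior_spec(pi = 0.95),
                  fast_chain(2000, 500, seed = 80), "bayesB")
  expect_lt(max(abs(fit$effects$effect_mean)), 0.05 * sd(y))
})

test_that("the strict-gate variant also mixes but proposes less often", {
  set.seed(81)
  W <- matrix(rnorm(60 * 5), 60)
  y <- rnorm(60) + W[, 1]
  f <- run_mcmc(y, W, prior_spec(pi = 0.95), fast_chain(seed = 82),
                "bayesB", strict_gate = TRUE)
  expect_true(all(is.finite(f$effects$effect_mean)))
  expect_gt(f$effects$inclusion_freq[1], 0.5)  # real signal still found
})

test_that("the R reference MH update obeys the same gate logic", {
  set.seed(83)
  n <- 40
  W <- matrix(rnorm(n * 2), n)
  y <- rnorm(n) + W[, 1] * 1.5
  state <- list(mu = 0, g = c(0, 0), sigma2_g = c(0, 0), sigma2_e = 1,
                e = y)
  # pi = 1: gate always closed, zero proposals only
  s1 <- mh_update_locus(1, state, W, prior_spec(pi = 1), mh_cycles = 20)
  expect_identical(s1$sigma2_g[1], 0)
  expect_identical(s1$g[1], 0)
  # pi = 0: slab proposals every cycle; strong signal ends up in the model
  s0 <- mh_update_locus(1, state, W, prior_spec(pi = 0), mh_cycles = 20)
  expect_gt(s0$sigma2_g[1], 0)
  expect_equal(s0$e, y - s0$g[1] * W[, 1], tolerance = 1e-10)
})

test_that("GEBV prediction is linear with and without the intercept", {
  set.seed(84)
  W <- matrix(rnorm(30 * 6), 30)
  y <- rnorm(30)
  fit <- run_mcmc(y, W, prior_spec(), fast_chain(seed = 85), "bayesA")
  gebv <- predict_gebv(fit, W)
  expect_equal(predict_gebv(fit, W, mu_included = TRUE), gebv + fit$mu_mean)
  fit0 <- fit
  fit0$effects$effect_mean <- fit$effects$effect_mean * 2
  expect_equal(predict_gebv(fit0, W), 2 * gebv)
  fit0$effects$effect_mean <- numeric(6)
  expect_identical(predict_gebv(fit0, W), rep(0, 30))
  expect_error(predict_gebv(fit, W[, 1:3]), "columns")
})

test_that("posterior summaries serialise with provenance", {
  set.seed(86)
  W <- matrix(rnorm(30 * 4), 30, dimnames = list(NULL, paste0("snp", 1:4)))
  fit <- run_mcmc(rnorm(30), W, prior_spec(), fast_chain(seed = 87),
                  "bayesB")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_posterior(fit, path)
  lines <- readLines(path)
  expect_true(any(grepl("^# method=bayesB", lines)))
  body <- utils::read.delim(path, comment.char = "#")
  expect_equal(body$marker_id, paste0("snp", 1:4))
  expect_equal(body$effect_mean, fit$effects$effect_mean, tolerance = 1e-9)
})
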