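#' Genomic relationship matrix (VanRaden method 1)
#'
#' `G = W W' / (2 * sum(p_j * (1 - p_j)))` where `W` is the genotype matrix
#' centered by twice the allele frequency. Frequencies default to those
#' observed in the supplied matrix; supply training-set frequencies when
#' building a combined training + validation matrix. A small constant is
#' added to the diagonal so the matrix is safely positive definite.
#'
#' @param genotypes A [geno_matrix()] with no missing codes (run
#'   [impute_missing()] first if needed).
#' @param blend_epsilon Diagonal blend (default `1e-6`).
#' @param allele_freq Optional length-m frequency vector overriding the
#'   observed ones.
#' @return Object of class `g_rel`: list with `G` (n x n, symmetric,
#'   dimnames = individual ids), `blend_epsilon`, `allele_freq`, `denom`.
#' @export
build_g_matrix <- function(genotypes, blend_epsilon = 1e-6,
                           allele_freq = NULL) {
  stopifnot(inherits(genotypes, "geno_matrix"), blend_epsilon >= 0)
  if (anyNA(genotypes$codes))
    stop("genotypes contain missing codes; run impute_missing() first")
  p <- allele_freq %||% genotypes$allele_freq
  stopifnot(length(p) == ncol(genotypes$codes))
  denom <- 2 * sum(p * (1 - p))
  if (denom <= 0)
    stop("all markers monomorphic at the supplied frequencies: ",
         "relationship matrix undefined (zero denominator)")
  W <- sweep(genotypes$codes, 2L, 2 * p, "-")
  G <- tcrossprod(W) / denom
  G <- (G + t(G)) / 2
  diag(G) <- diag(G) + blend_epsilon
  dimnames(G) <- list(individual_ids(genotypes), individual_ids(genotypes))
  structure(list(G = G, blend_epsilon = blend_epsilon,
                 allele_freq = as.numeric(p), denom = denom),
            class = "g_rel")
}

#' @export
print.g_rel <- function(x, ...) {
  cat("<g_rel> ", nrow(x$G), " x ", ncol(x$G),
      " genomic relationship matrix; mean diagonal ",
      signif(mean(diag(x$G)), 4), "\n", sep = "")
  invisible(x)
}

#' REML variance components for the GBLUP model
#'
#' Fits `y = 1 mu + u + e` with `u ~ N(0, sigma2_u G)` and
#' `e ~ N(0, sigma2_e I)` by restricted maximum likelihood. The restricted
#' likelihood is profiled down to the single variance ratio
#' `delta = sigma2_e / sigma2_u` using one eigendecomposition of `G`, then
#' maximised by one-dimensional optimisation — deterministic for fixed
#' input.
#'
#' @param y Numeric response aligned with `G` (NA entries are dropped along
#'   with their G rows/columns).
#' @param G A `g_rel` or a plain symmetric matrix.
#' @param fixed_h2 Optional override: skip REML and set the ratio from a
#'   given heritability (useful in tests and degenerate settings).
#' @param interval Search interval for `log(delta)`.
#' @return Object of class `var_comp`: list with `sigma2_u`, `sigma2_e`,
#'   `lambda` (= `sigma2_e / sigma2_u`), `h2` (= `sigma2_u /
#'   (sigma2_u + sigma2_e)`), `loglik`, `boundary` (TRUE when the optimum
#'   sits on the edge of the search interval, e.g. `sigma2_u` essentially 0).
#' @export
estimate_variance_components <- function(y, G, fixed_h2 = NULL,
                                         interval = c(-12, 12)) {
  Gm <- if (inherits(G, "g_rel")) G$G else as.matrix(G)
  keep <- !is.na(y)
  y <- y[keep]
  Gm <- Gm[keep, keep, drop = FALSE]
  n <- length(y)
  if (n < 10L) stop("need at least 10 observed individuals for REML, got ", n)
  if (stats::sd(y) == 0) stop("response is constant; REML undefined")
  eg <- eigen(Gm, symmetric = TRUE)
  ys <- drop(crossprod(eg$vectors, y))
  xs <- drop(crossprod(eg$vectors, rep(1, n)))
  d0 <- pmax(eg$values, 0)

  reml_ll <- function(log_delta) {
    d <- d0 + exp(log_delta)
    sxx <- sum(xs^2 / d)
    mu <- sum(xs * ys / d) / sxx
    r <- ys - xs * mu
    q <- sum(r^2 / d)
    s2u <- q / (n - 1)
    -0.5 * ((n - 1) * log(s2u) + sum(log(d)) + log(sxx) + (n - 1))
  }

  if (!is.null(fixed_h2)) {
    stopifnot(fixed_h2 > 0, fixed_h2 < 1)
    log_delta <- log((1 - fixed_h2) / fixed_h2)
    boundary <- FALSE
    ll <- reml_ll(log_delta)
  } else {
    opt <- stats::optimize(reml_ll, interval = interval, maximum = TRUE,
                           tol = 1e-8)
    if (!is.finite(opt$objective))
      stop("REML optimisation failed to evaluate; last ratio log(delta) = ",
           signif(opt$maximum, 4))
    log_delta <- opt$maximum
    ll <- opt$objective
    boundary <- min(abs(log_delta - interval)) < 1e-3
  }
  delta <- exp(log_delta)
  d <- d0 + delta
  sxx <- sum(xs^2 / d)
  mu <- sum(xs * ys / d) / sxx
  s2u <- sum((ys - xs * mu)^2 / d) / (n - 1)
  structure(list(sigma2_u = s2u, sigma2_e = delta * s2u, lambda = delta,
                 h2 = 1 / (1 + delta), loglik = ll, mu = mu,
                 boundary = boundary),
            class = "var_comp")
}

#' @export
print.var_comp <- function(x, ...) {
  cat("<var_comp> sigma2_u = ", signif(x$sigma2_u, 4),
      ", sigma2_e = ", signif(x$sigma2_e, 4),
      ", h2 = ", signif(x$h2, 3),
      if (x$boundary) " (boundary estimate)", "\n", sep = "")
  invisible(x)
}

#' Solve the GBLUP mixed-model equations
#'
#' Computes best linear unbiased predictions of the additive genetic merit
#' for all individuals, training on those with observed responses and
#' propagating to the rest through the corresponding blocks of `G`:
#' `u_hat = sigma2_u * G[, obs] %*% solve(V_oo, y_obs - mu_hat)` with
#' `V_oo = sigma2_u G_oo + sigma2_e I` and `mu_hat` the GLS mean.
#'
#' @param y Numeric response of length n; `NA` marks individuals to predict
#'   (masked/validation individuals).
#' @param G A `g_rel` or symmetric matrix over all n individuals.
#' @param vc A `var_comp` (or list with `sigma2_u`, `sigma2_e`).
#' @return Named numeric GEBV vector for all n individuals, with the GLS
#'   mean in attribute `"mu"`.
#' @export
solve_gblup <- function(y, G, vc) {
  Gm <- if (inherits(G, "g_rel")) G$G else as.matrix(G)
  n <- nrow(Gm)
  stopifnot(length(y) == n)
  obs <- which(!is.na(y))
  if (length(obs) < 2L) stop("need at least 2 observed individuals")
  Voo <- vc$sigma2_u * Gm[obs, obs, drop = FALSE] +
    diag(vc$sigma2_e, length(obs))
  ch <- tryCatch(chol(Voo), error = function(e)
    stop("singular coefficient matrix in the mixed-model equations: ",
         conditionMessage(e)))
  Vinv_y <- backsolve(ch, forwardsolve(t(ch), y[obs]))
  Vinv_1 <- backsolve(ch, forwardsolve(t(ch), rep(1, length(obs))))
  mu <- sum(Vinv_y) / sum(Vinv_1)
  u <- drop(vc$sigma2_u * Gm[, obs, drop = FALSE] %*% (Vinv_y - mu * Vinv_1))
  names(u) <- rownames(Gm)
  attr(u, "mu") <- mu
  u
}

#' GBLUP in one call
#'
#' Builds the VanRaden relationship matrix from all genotypes (genotypes of
#' validation individuals carry no phenotype information, so using them in G
#' is standard cross-validation practice), estimates variance components by
#' REML on the training individuals, and solves the mixed-model equations.
#'
#' @param genotypes A [geno_matrix()] for all individuals.
#' @param y Response with `NA` for individuals to predict.
#' @param fixed_h2 Optional REML override, see
#'   [estimate_variance_components()].
#' @param blend_epsilon Passed to [build_g_matrix()].
#' @return Object of class `gblup_fit`: list with `gebv`, `mu`, `vc`,
#'   `g_rel`.
#' @export
gblup <- function(genotypes, y, fixed_h2 = NULL, blend_epsilon = 1e-6) {
  g <- impute_missing(genotypes)
  G <- build_g_matrix(g, blend_epsilon = blend_epsilon)
  vc <- estimate_variance_components(y, G, fixed_h2 = fixed_h2)
  u <- solve_gblup(y, G, vc)
  structure(list(gebv = u, mu = attr(u, "mu"), vc = vc, g_rel = G,
                 n_train = sum(!is.na(y))),
            class = "gblup_fit")
}

#' @export
print.gblup_fit <- function(x, ...) {
  cat("<gblup_fit> ", length(x$gebv), " individuals (",
      x$n_train, " phenotyped); h2 = ", signif(x$vc$h2, 3), "\n", sep = "")
  invisible(x)
}

#' @export
tidy.gblup_fit <- function(x, ...) {
  tibble::tibble(id = names(x$gebv), gebv = as.numeric(x$gebv))
}

#' @export
glance.gblup_fit <- function(x, ...) {
  tibble::tibble(sigma2_u = x$vc$sigma2_u, sigma2_e = x$vc$sigma2_e,
                 h2 = x$vc$h2, loglik = x$vc$loglik, mu = x$mu,
                 n_train = x$n_train, boundary = x$vc$boundary)
}

#' Export or import a relationship matrix as dense TSV
#'
#' @param G A `g_rel`.
#' @param path Path; written as a dense tab-separated matrix with an id
#'   header row and a leading id column.
#' @export
write_g_matrix <- function(G, path) {
  df <- data.frame(id = rownames(G$G), G$G, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_g_matrix
#' @export
read_g_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  ids <- as.character(df[[1L]])
  M <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(M) <- "double"
  dimnames(M) <- list(ids, ids)
  structure(list(G = M, blend_epsilon = NA_real_,
                 allele_freq = NULL, denom = NA_real_),
            class = "g_rel")
}
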