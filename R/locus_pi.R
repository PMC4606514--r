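#' Single-marker ANOVA scan
#'
#' Fits, for every polymorphic marker, the one-way fixed-effect model
#' `y = Xb + Zg + e` with the marker's genotype classes (0/1/2) as factor
#' levels, and returns the F-test p-value for the marker term. With no
#' covariates, `X` is the overall mean and the scan is computed by vectorised
#' group-sum identities; with covariates it falls back to per-marker
#' [stats::lm()] fits. Entries flagged missing in the genotype matrix are
#' excluded marker-by-marker, so the scan is valid before or after
#' imputation. Monomorphic markers get an undefined sentinel (`NA`) rather
#' than a p-value.
#'
#' @param genotypes A [geno_matrix()].
#' @param y Numeric response vector aligned with the genotype rows
#'   (phenotypes, EBVs or deregressed proofs); must be non-constant.
#' @param covariates Optional numeric matrix of fixed-effect covariates
#'   (no intercept column; one is added internally).
#' @param model `"genotype"` (default; genotype classes as factor levels) or
#'   `"additive"` (single-df regression on allele dosage).
#' @return A tibble `marker_id`, `p_value`, `df1`, `df2`, `n_used`.
#'   `p_value` is `NA` for markers with fewer than two observed genotype
#'   classes.
#' @export
single_marker_anova <- function(genotypes, y, covariates = NULL,
                                model = c("genotype", "additive")) {
  model <- match.arg(model)
  stopifnot(inherits(genotypes, "geno_matrix"))
  y <- as.numeric(y)
  n <- nrow(genotypes$codes)
  if (length(y) != n) stop("y must have one entry per individual (", n, ")")
  if (anyNA(y)) stop("y contains NA")
  if (stats::sd(y) == 0) stop("y is constant; ANOVA undefined")
  mk <- marker_ids(genotypes)

  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    stopifnot(nrow(covariates) == n)
    res <- purrr::map(seq_along(mk), function(j) {
      use <- !genotypes$missing_mask[, j]
      gj <- genotypes$codes[use, j]
      if (length(unique(gj)) < 2L)
        return(list(p = NA_real_, df1 = NA_real_, df2 = NA_real_,
                    n_used = sum(use)))
      f <- if (model == "genotype") factor(gj) else gj
      fit <- stats::lm(y[use] ~ covariates[use, , drop = FALSE] + f)
      av <- stats::anova(fit)
      row <- nrow(av) - 1L  # marker term is last before residuals
      list(p = av[row, "Pr(>F)"], df1 = av[row, "Df"],
           df2 = av[nrow(av), "Df"], n_used = sum(use))
    })
    out <- tibble::tibble(
      marker_id = mk,
      p_value = purrr::map_dbl(res, "p"),
      df1 = purrr::map_dbl(res, "df1"),
      df2 = purrr::map_dbl(res, "df2"),
      n_used = purrr::map_dbl(res, "n_used"))
    out$p_value <- pmin(pmax(out$p_value, 1e-320), 1)  # NA passes through
    return(out)
  }

  M <- !genotypes$missing_mask
  storage.mode(M) <- "double"
  n_used <- colSums(M)
  sum_y <- drop(crossprod(M, y))
  sum_y2 <- drop(crossprod(M, y^2))
  sst <- sum_y2 - sum_y^2 / n_used

  if (model == "genotype") {
    ssb <- -sum_y^2 / n_used
    k <- rep(0, length(mk))
    for (cls in c(0, 1, 2)) {
      Ic <- (genotypes$codes == cls) & M
      storage.mode(Ic) <- "double"
      nc <- colSums(Ic)
      sc <- drop(crossprod(Ic, y))
      pos <- nc > 0
      ssb[pos] <- ssb[pos] + sc[pos]^2 / nc[pos]
      k <- k + pos
    }
    df1 <- k - 1
    df2 <- n_used - k
  } else {
    C0 <- genotypes$codes
    C0[!M] <- 0
    sum_x <- colSums(C0)
    sum_x2 <- colSums(C0^2)
    sum_xy <- drop(crossprod(C0, y))
    sxx <- sum_x2 - sum_x^2 / n_used
    sxy <- sum_xy - sum_x * sum_y / n_used
    ssb <- ifelse(sxx > 0, sxy^2 / sxx, 0)
    k <- 1 + (sxx > 0)
    df1 <- rep(1, length(mk))
    df2 <- n_used - 2
  }

  ssw <- pmax(sst - ssb, 0)
  fstat <- (ssb / df1) / (ssw / df2)
  p <- stats::pf(fstat, df1, df2, lower.tail = FALSE)
  p <- pmin(pmax(p, 1e-320), 1)
  undefined <- k < 2 | df2 < 1
  p[undefined] <- NA_real_
  if (any(!undefined & (n_used < df1 + 2)[!undefined]))
    stop("fewer observations than model parameters for some markers")
  tibble::tibble(marker_id = mk, p_value = unname(p),
                 df1 = unname(ifelse(undefined, NA_real_, df1)),
                 df2 = unname(ifelse(undefined, NA_real_, df2)),
                 n_used = unname(n_used))
}

#' Transform p-values to the -log10 scale
#'
#' `omega = -log10(max(p, floor))`. The floor guards against underflow to
#' infinity for astronomically small p-values. Undefined sentinels (`NA`,
#' from monomorphic markers) map to `omega = 0`, i.e. are treated as p = 1:
#' a marker carrying no information gets the weakest possible evidence.
#'
#' @param p Numeric vector of p-values in `(0, 1]`, `NA` allowed.
#' @param floor Positive numerical floor for p (default `1e-300`).
#' @return Numeric vector of finite, non-negative omega values.
#' @export
pvalues_to_omega <- function(p, floor = 1e-300) {
  stopifnot(floor > 0)
  if (any(p <= 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in (0, 1]")
  w <- -log10(pmax(p, floor))
  w[is.na(p)] <- 0
  w
}

#' Locus-specific prior probability of no effect
#'
#' Min-max rescales the evidence vector omega into a per-marker prior
#' probability of being non-effective:
#' `pi_i = (max(omega) - omega_i) / (max(omega) - min(omega))`.
#' The most significant marker(s) receive pi = 0 (always proposed for
#' inclusion), the least significant pi = 1 (never proposed). When all omega
#' are equal the rescale is undefined; the documented fallback is a constant
#' pi = 0.95, the conventional BayesB default, with a warning.
#'
#' @param omega Finite numeric vector (from [pvalues_to_omega()]).
#' @param marker_ids Optional identifiers.
#' @param degenerate_pi Constant used when `max(omega) == min(omega)`.
#' @return A tibble of class `locus_prior` with columns `marker_id`, `omega`,
#'   `pi`.
#' @export
compute_locus_pi <- function(omega, marker_ids = NULL, degenerate_pi = 0.95) {
  if (!all(is.finite(omega))) stop("omega must be finite")
  if (is.null(marker_ids)) marker_ids <- paste0("m", seq_along(omega))
  rng <- range(omega)
  if (rng[1L] == rng[2L]) {
    warning("all omega equal (degenerate architecture); ",
            "falling back to constant pi = ", degenerate_pi)
    pi <- rep(degenerate_pi, length(omega))
  } else {
    pi <- (rng[2L] - omega) / (rng[2L] - rng[1L])
  }
  out <- tibble::tibble(marker_id = as.character(marker_ids),
                        omega = as.numeric(omega), pi = pi)
  class(out) <- c("locus_prior", class(out))
  out
}

#' Binned alternative transform for the locus prior
#'
#' Instead of rescaling raw omega values, markers are first divided into
#' classes by p-value thresholds and every marker in a class receives the
#' class's pi, obtained by min-max rescaling the class-mean omega. This
#' dampens the sensitivity of the denominator to a single extreme marker.
#' Off by default throughout the package.
#'
#' @param p Numeric p-value vector (`NA` treated as p = 1).
#' @param thresholds Increasing p-value cut points in (0, 1), e.g.
#'   `c(1e-8, 1e-4, 0.01, 0.05)`.
#' @param marker_ids Optional identifiers.
#' @inheritParams compute_locus_pi
#' @return A `locus_prior` tibble.
#' @export
compute_locus_pi_binned <- function(p, thresholds, marker_ids = NULL,
                                    degenerate_pi = 0.95) {
  stopifnot(all(diff(thresholds) > 0), all(thresholds > 0 & thresholds < 1))
  w <- pvalues_to_omega(p)
  cls <- findInterval(ifelse(is.na(p), 1, p), c(0, thresholds, 1),
                      rightmost.closed = TRUE)
  w_cls <- tapply(w, cls, mean)
  rng <- range(w_cls)
  pi_cls <- if (rng[1L] == rng[2L]) {
    warning("all omega classes equal; falling back to constant pi = ",
            degenerate_pi)
    stats::setNames(rep(degenerate_pi, length(w_cls)), names(w_cls))
  } else {
    (rng[2L] - w_cls) / (rng[2L] - rng[1L])
  }
  if (is.null(marker_ids)) marker_ids <- paste0("m", seq_along(p))
  out <- tibble::tibble(marker_id = as.character(marker_ids),
                        omega = w, pi = as.numeric(pi_cls[as.character(cls)]))
  class(out) <- c("locus_prior", class(out))
  out
}

#' One-call locus prior from genotypes and a response
#'
#' Convenience pipeline: [single_marker_anova()] on the supplied (training)
#' individuals, then [pvalues_to_omega()] and [compute_locus_pi()]. In
#' cross-validation this is recomputed inside every training fold so no
#' information leaks from validation individuals.
#'
#' @inheritParams single_marker_anova
#' @param floor Passed to [pvalues_to_omega()].
#' @return A `locus_prior` tibble with the scan's `p_value` column attached.
#' @export
locus_pi <- function(genotypes, y, covariates = NULL,
                     model = c("genotype", "additive"), floor = 1e-300) {
  pv <- single_marker_anova(genotypes, y, covariates, model)
  w <- pvalues_to_omega(pv$p_value, floor)
  out <- compute_locus_pi(w, marker_ids = pv$marker_id)
  out$p_value <- pv$p_value
  out
}

#' Read or write a locus prior as a two-column table
#'
#' @param prior A `locus_prior` tibble (only `marker_id` and `pi` are
#'   serialised).
#' @param path File path (tab-separated, header `marker_id<TAB>pi`).
#' @export
write_locus_pi <- function(prior, path) {
  utils::write.table(prior[, c("marker_id", "pi")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_locus_pi
#' @return `read_locus_pi()` returns a tibble `marker_id`, `pi`.
#' @export
read_locus_pi <- function(path) {
  df <- utils::read.delim(path, colClasses = c("character", "numeric"))
  if (!identical(names(df), c("marker_id", "pi")))
    stop("expected columns marker_id, pi in ", path)
  if (any(df$pi < 0 | df$pi > 1)) stop("pi outside [0,1] in ", path)
  tibble::as_tibble(df)
}

#' Plot the genome-wide evidence and prior profiles
#'
#' Manhattan-style panels of omega (association evidence) and the derived
#' locus-specific pi along the marker index.
#'
#' @param object A `locus_prior` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.locus_prior <- function(object, ...) {
  df <- dplyr::mutate(object, index = dplyr::row_number())
  long <- tidyr::pivot_longer(df, c("omega", "pi"),
                              names_to = "quantity", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$index, y = .data$value)) +
    ggplot2::geom_point(size = 0.4, alpha = 0.6) +
    ggplot2::facet_wrap(~quantity, ncol = 1L, scales = "free_y") +
    ggplot2::labs(x = "marker index", y = NULL,
                  title = "Association evidence and locus-specific prior")
}
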