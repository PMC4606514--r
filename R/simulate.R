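#' Specify a simulated genetic architecture
#'
#' Defines the generating conditions for a synthetic genomic-selection
#' dataset: population size, marker panel, minor-allele-frequency range,
#' number of QTL, the share of genetic variance carried by one designated
#' major locus, and the narrow-sense heritability of the trait.
#'
#' @param n_individuals,n_markers Positive integers.
#' @param maf_range Interval within (0, 0.5]; each marker's counted-allele
#'   frequency is drawn uniformly from it.
#' @param n_qtl Number of causal markers (0 gives a pure-noise trait and
#'   `heritability` is ignored).
#' @param major_qtl_fraction Share of total genetic variance assigned to one
#'   designated major QTL, in `[0, 1]`; 0 means no designated major locus
#'   (all QTL effects are exchangeable Gaussian draws).
#' @param heritability Narrow-sense h2 in (0, 1).
#' @param seed Integer seed; the whole simulation pipeline is deterministic
#'   given the spec.
#' @param ld Optional list `list(block_size =, rho =)` switching on a
#'   block-correlated genotype mode (equicorrelated latent gametes within
#'   consecutive blocks); default `NULL` simulates linkage equilibrium.
#' @return An object of class `arch_spec`.
#' @export
arch_spec <- function(n_individuals, n_markers, maf_range = c(0.05, 0.5),
                      n_qtl = 0L, major_qtl_fraction = 0,
                      heritability = 0.5, seed = 1L, ld = NULL) {
  stopifnot(n_individuals >= 2, n_markers >= 1,
            length(maf_range) == 2L, maf_range[1L] > 0,
            maf_range[2L] <= 0.5, maf_range[1L] <= maf_range[2L],
            n_qtl >= 0, n_qtl <= n_markers,
            major_qtl_fraction >= 0, major_qtl_fraction <= 1,
            heritability > 0, heritability < 1)
  if (major_qtl_fraction > 0 && n_qtl == 0)
    stop("major_qtl_fraction > 0 requires n_qtl >= 1")
  if (!is.null(ld))
    stopifnot(is.list(ld), ld$block_size >= 1, ld$rho >= 0, ld$rho < 1)
  structure(
    list(n_individuals = as.integer(n_individuals),
         n_markers = as.integer(n_markers),
         maf_range = as.numeric(maf_range),
         n_qtl = as.integer(n_qtl),
         major_qtl_fraction = as.numeric(major_qtl_fraction),
         heritability = as.numeric(heritability),
         seed = as.integer(seed), ld = ld),
    class = "arch_spec"
  )
}

#' Architecture presets mirroring contrasting dairy-trait architectures
#'
#' `"mfp_like"` emulates a trait with one major QTL carrying 30% of the
#' genetic variance on top of a polygenic background (as for milk fat
#' percentage, where a single gene is known to account for roughly 30% of
#' genetic variation), h2 = 0.5. `"my_like"` has one moderate QTL (10% of
#' genetic variance) plus many small ones, h2 = 0.5. `"scs_like"` is purely
#' polygenic — many small QTL, no designated major locus — with h2 = 0.30.
#'
#' @param preset One of `"mfp_like"`, `"my_like"`, `"scs_like"`.
#' @param n_individuals,n_markers,seed Passed to [arch_spec()].
#' @return An `arch_spec`.
#' @export
arch_preset <- function(preset = c("mfp_like", "my_like", "scs_like"),
                        n_individuals = 1000L, n_markers = 2000L, seed = 1L) {
  preset <- match.arg(preset)
  pars <- switch(preset,
    mfp_like = list(n_qtl = 50L, major = 0.30, h2 = 0.5),
    my_like  = list(n_qtl = 100L, major = 0.10, h2 = 0.5),
    scs_like = list(n_qtl = 200L, major = 0, h2 = 0.30))
  spec <- arch_spec(n_individuals, n_markers,
                    n_qtl = min(pars$n_qtl, n_markers),
                    major_qtl_fraction = pars$major,
                    heritability = pars$h2, seed = seed)
  spec$preset <- preset
  spec
}

# equicorrelated latent normals within consecutive blocks of markers
latent_block_normals <- function(n, m, block_size, rho) {
  blocks <- rep(seq_len(ceiling(m / block_size)), each = block_size)[seq_len(m)]
  shared <- matrix(stats::rnorm(n * max(blocks)), n)
  indep <- matrix(stats::rnorm(n * m), n)
  sqrt(rho) * shared[, blocks, drop = FALSE] + sqrt(1 - rho) * indep
}

#' Simulate genotypes in Hardy-Weinberg proportions
#'
#' For each marker an allele frequency is drawn uniformly from
#' `spec$maf_range`; genotype codes are Binomial(2, p) draws per individual
#' (Hardy-Weinberg, linkage equilibrium). With `spec$ld` set, the two gametes
#' are thresholded block-equicorrelated latent normals instead, giving a
#' fixed within-block genotype correlation while preserving the marginal HWE
#' frequencies.
#'
#' @param spec An [arch_spec()].
#' @return A [geno_matrix()], reproducible from `spec$seed`.
#' @export
simulate_genotypes <- function(spec) {
  stopifnot(inherits(spec, "arch_spec"))
  set.seed(spec$seed)
  n <- spec$n_individuals
  m <- spec$n_markers
  p <- stats::runif(m, spec$maf_range[1L], spec$maf_range[2L])
  if (is.null(spec$ld)) {
    codes <- matrix(stats::rbinom(n * m, 2L, rep(p, each = n)), n, m)
  } else {
    thr <- stats::qnorm(p)
    g1 <- sweep(latent_block_normals(n, m, spec$ld$block_size, spec$ld$rho),
                2L, thr, "<")
    g2 <- sweep(latent_block_normals(n, m, spec$ld$block_size, spec$ld$rho),
                2L, thr, "<")
    codes <- g1 + g2
  }
  rownames(codes) <- paste0("ind", seq_len(n))
  colnames(codes) <- paste0("m", seq_len(m))
  out <- geno_matrix(codes)
  attr(out, "drawn_freq") <- p
  out
}

#' Simulate marker effects for a given architecture
#'
#' Chooses `n_qtl` marker indices without replacement. When a major locus is
#' requested (`major_qtl_fraction > 0`), the remaining QTL receive standard
#' Gaussian effects and the major locus's effect is sized so that its
#' variance contribution `2 p q a^2` equals the requested fraction of the
#' total genetic variance at the (realized, if genotypes are supplied)
#' allele frequencies. Non-QTL markers have effect exactly 0.
#'
#' @param spec An [arch_spec()].
#' @param genotypes Optional [geno_matrix()] whose observed allele
#'   frequencies are used for effect sizing; if `NULL`, frequencies are drawn
#'   from `spec$maf_range` under the spec seed.
#' @return Numeric length-m effect vector with a `"qtl"` attribute (indices;
#'   first entry is the major locus when one exists).
#' @export
simulate_effects <- function(spec, genotypes = NULL) {
  stopifnot(inherits(spec, "arch_spec"))
  m <- spec$n_markers
  if (spec$n_qtl == 0L) {
    out <- numeric(m)
    attr(out, "qtl") <- integer(0)
    return(out)
  }
  if (!is.null(genotypes)) {
    stopifnot(ncol(genotypes$codes) == m)
    p <- genotypes$allele_freq
  } else {
    set.seed(spec$seed)
    p <- stats::runif(m, spec$maf_range[1L], spec$maf_range[2L])
  }
  set.seed(spec$seed + 1L)
  qtl <- sample.int(m, spec$n_qtl)
  a <- numeric(m)
  frac <- spec$major_qtl_fraction
  if (frac == 0) {
    a[qtl] <- stats::rnorm(spec$n_qtl)
  } else {
    major <- qtl[1L]
    rest <- qtl[-1L]
    a[rest] <- stats::rnorm(length(rest))
    v_rest <- sum(2 * p[rest] * (1 - p[rest]) * a[rest]^2)
    v_major_unit <- 2 * p[major] * (1 - p[major])
    if (v_major_unit <= 0)
      stop("major QTL landed on a monomorphic marker; choose another seed")
    if (frac == 1 || length(rest) == 0L) {
      a[rest] <- 0
      a[major] <- 1
    } else {
      a[major] <- sqrt(frac / (1 - frac) * v_rest / v_major_unit)
    }
  }
  attr(a, "qtl") <- qtl
  a
}

#' Simulate phenotypes from genotypes and marker effects
#'
#' True breeding values are centered genotype codes times the effects;
#' Gaussian noise is added with variance `var(tbv) * (1 - h2) / h2` so the
#' trait has the requested heritability in expectation.
#'
#' @param genotypes A [geno_matrix()] (no missing codes).
#' @param effects Length-m effect vector.
#' @param h2 Heritability in (0, 1).
#' @param seed Integer seed for the noise draw.
#' @param trait Name for the simulated trait column.
#' @return An object of class `sim_dataset`: list with `genotypes`,
#'   `phenotypes` (tibble `id`, trait), `true_effects`,
#'   `true_breeding_values` and `realized_h2`.
#' @export
simulate_phenotypes <- function(genotypes, effects, h2, seed = 1L,
                                trait = "trait") {
  stopifnot(inherits(genotypes, "geno_matrix"),
            length(effects) == ncol(genotypes$codes),
            h2 > 0, h2 < 1)
  if (all(effects == 0))
    stop("all effects are zero: heritability is undefined; ",
         "use simulate_dataset() for a null trait")
  W <- sweep(genotypes$codes, 2L, colMeans(genotypes$codes), "-")
  tbv <- drop(W %*% effects)
  v_g <- stats::var(tbv)
  set.seed(seed)
  e <- stats::rnorm(length(tbv), 0, sqrt(v_g * (1 - h2) / h2))
  y <- tbv + e
  phen <- tibble::tibble(id = individual_ids(genotypes), !!trait := y)
  structure(
    list(genotypes = genotypes, phenotypes = phen,
         true_effects = as.numeric(effects),
         true_breeding_values = tbv,
         realized_h2 = v_g / stats::var(y)),
    class = "sim_dataset"
  )
}

#' Simulate a complete dataset from an architecture spec
#'
#' Runs [simulate_genotypes()], [simulate_effects()] (sized at the realized
#' allele frequencies) and [simulate_phenotypes()] under seeds derived from
#' `spec$seed`, so identical specs give bit-identical datasets. A spec with
#' `n_qtl = 0` yields a pure-noise standard-normal trait and
#' `realized_h2 = 0`.
#'
#' @param spec An [arch_spec()].
#' @param trait Trait column name; defaults to the preset name if any.
#' @return A `sim_dataset` (see [simulate_phenotypes()]) with the QTL indices
#'   in attribute `"qtl"`.
#' @export
simulate_dataset <- function(spec, trait = NULL) {
  stopifnot(inherits(spec, "arch_spec"))
  if (is.null(trait)) trait <- spec$preset %||% "trait"
  g <- simulate_genotypes(spec)
  a <- simulate_effects(spec, g)
  if (spec$n_qtl == 0L) {
    set.seed(spec$seed + 2L)
    y <- stats::rnorm(spec$n_individuals)
    phen <- tibble::tibble(id = individual_ids(g), !!trait := y)
    out <- structure(
      list(genotypes = g, phenotypes = phen,
           true_effects = as.numeric(a),
           true_breeding_values = numeric(spec$n_individuals),
           realized_h2 = 0),
      class = "sim_dataset")
  } else {
    out <- simulate_phenotypes(g, a, spec$heritability,
                               seed = spec$seed + 2L, trait = trait)
  }
  attr(out, "qtl") <- attr(a, "qtl")
  out$spec <- spec
  out
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat("<sim_dataset> ", nrow(x$genotypes$codes), " individuals x ",
      ncol(x$genotypes$codes), " markers; ",
      sum(x$true_effects != 0), " causal markers; realized h2 = ",
      signif(x$realized_h2, 3), "\n", sep = "")
  invisible(x)
}
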