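#' Construct a genotype matrix object
#'
#' Container for additive-coded SNP genotypes (0/1/2 = count of the "2"
#' allele, i.e. genotypes 11, 12, 22). Rows are individuals, columns are
#' markers. Missing entries are recorded in a mask so that imputation can be
#' audited afterwards; allele frequencies are always computed from the
#' non-missing entries only.
#'
#' @param codes Numeric matrix (individuals x markers). Non-missing values
#'   must be 0, 1 or 2 unless `validate_codes = FALSE` (used internally after
#'   mean imputation, which produces fractional dosages in `[0, 2]`).
#' @param individual_ids,marker_ids Character vectors of unique identifiers;
#'   default to the dimnames of `codes`.
#' @param validate_codes Check that non-missing codes are in `{0,1,2}`.
#' @return An object of class `geno_matrix`: a list with elements `codes`,
#'   `missing_mask`, `allele_freq` (frequency of the counted allele, column
#'   mean of non-missing codes divided by 2), `monomorphic` (logical; markers
#'   whose non-missing codes are all identical carry no information and are
#'   flagged, not dropped) and `imputed`.
#' @export
geno_matrix <- function(codes, individual_ids = rownames(codes),
                        marker_ids = colnames(codes), validate_codes = TRUE) {
  codes <- as.matrix(codes)
  storage.mode(codes) <- "double"
  n <- nrow(codes)
  m <- ncol(codes)
  if (n < 2L) stop("need at least 2 individuals, got ", n)
  if (m < 1L) stop("need at least 1 marker")
  if (is.null(individual_ids)) individual_ids <- paste0("ind", seq_len(n))
  if (is.null(marker_ids)) marker_ids <- paste0("m", seq_len(m))
  individual_ids <- as.character(individual_ids)
  marker_ids <- as.character(marker_ids)
  if (length(individual_ids) != n) stop("individual_ids length mismatch")
  if (length(marker_ids) != m) stop("marker_ids length mismatch")
  if (anyDuplicated(individual_ids))
    stop("duplicated individual ids: ",
         paste(unique(individual_ids[duplicated(individual_ids)]), collapse = ", "))
  if (anyDuplicated(marker_ids))
    stop("duplicated marker ids: ",
         paste(unique(marker_ids[duplicated(marker_ids)]), collapse = ", "))
  missing_mask <- is.na(codes)
  if (validate_codes) {
    bad <- !missing_mask & !(codes %in% c(0, 1, 2))
    if (any(bad)) {
      idx <- which(bad, arr.ind = TRUE)[1L, ]
      stop("invalid genotype code ", codes[idx[1L], idx[2L]],
           " for individual '", individual_ids[idx[1L]],
           "', marker '", marker_ids[idx[2L]],
           "' (row ", idx[1L], ", column ", idx[2L],
           "): codes must be 0, 1, 2 or missing")
    }
  }
  dimnames(codes) <- list(individual_ids, marker_ids)
  dimnames(missing_mask) <- dimnames(codes)
  af <- colMeans(codes, na.rm = TRUE) / 2
  af[is.nan(af)] <- NA_real_  # fully missing column
  mono <- apply(codes, 2L, function(x) {
    x <- x[!is.na(x)]
    length(x) == 0L || all(x == x[1L])
  })
  structure(
    list(codes = codes, missing_mask = missing_mask,
         allele_freq = af, monomorphic = mono,
         imputed = FALSE),
    class = "geno_matrix"
  )
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat("<geno_matrix> ", nrow(x$codes), " individuals x ", ncol(x$codes),
      " markers\n", sep = "")
  cat("  missing: ", sum(x$missing_mask),
      if (x$imputed) " (mean-imputed)" else "",
      "; monomorphic markers: ", sum(x$monomorphic), "\n", sep = "")
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$codes)

#' Individual and marker identifiers
#' @param g A [geno_matrix()].
#' @return Character vector of ids.
#' @export
individual_ids <- function(g) rownames(g$codes)

#' @rdname individual_ids
#' @export
marker_ids <- function(g) colnames(g$codes)

#' Subset a genotype matrix by individuals and/or markers
#' @param x A [geno_matrix()].
#' @param i,j Row (individual) and column (marker) indices.
#' @param ... Unused.
#' @export
`[.geno_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$codes))
  if (missing(j)) j <- seq_len(ncol(x$codes))
  codes <- x$codes[i, j, drop = FALSE]
  codes[x$missing_mask[i, j, drop = FALSE]] <- NA_real_
  out <- geno_matrix(codes, validate_codes = !x$imputed)
  if (x$imputed) {
    # re-impute so the subset is again complete, from the subset's own means
    out <- impute_missing(out)
  }
  out
}

read_lines_checked <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines[nzchar(lines)]
}

parse_code_token <- function(tok) {
  out <- suppressWarnings(as.numeric(tok))
  out[tok %in% c("", "NA", "na", ".")] <- NA_real_
  out
}

#' Read genotypes from a delimited file
#'
#' Two dialects are supported. `tabular`: UTF-8, tab-separated, header
#' `id<TAB>marker1<TAB>...`, one row per individual, missing entries empty or
#' `NA`. `plink_raw`: whitespace-separated with the six leading pedigree
#' columns (`FID IID PAT MAT SEX PHENOTYPE`) followed by per-SNP allele
#' counts, as produced by a standard additive recode export; only `IID` and
#' the counts are consumed and trailing allele suffixes (`snp_A`) are kept as
#' part of the marker name.
#'
#' @param path Path to the file.
#' @param dialect `"tabular"` or `"plink_raw"`.
#' @return A [geno_matrix()]; the missing mask marks the dialect's missing
#'   token and allele frequencies are computed from non-missing entries.
#' @export
read_genotypes <- function(path, dialect = c("tabular", "plink_raw")) {
  dialect <- match.arg(dialect)
  lines <- read_lines_checked(path)
  if (length(lines) < 2L) stop("no data rows in ", path)
  if (dialect == "tabular") {
    header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
    mk <- header[-1L]
    ncol_expect <- length(header)
    rows <- strsplit(lines[-1L], "\t", fixed = TRUE)
    lens <- lengths(rows)
    if (any(lens != ncol_expect)) {
      bad <- which(lens != ncol_expect)[1L]
      stop("malformed row at line ", bad + 1L, " of ", path, ": expected ",
           ncol_expect, " fields, found ", lens[bad])
    }
    ids <- vapply(rows, `[[`, character(1L), 1L)
    codes <- matrix(parse_code_token(unlist(lapply(rows, `[`, -1L))),
                    nrow = length(rows), ncol = length(mk), byrow = TRUE)
  } else {
    fields <- strsplit(trimws(lines), "[ \t]+")
    header <- fields[[1L]]
    if (length(header) < 7L || toupper(header[2L]) != "IID")
      stop("not a plink additive-recode file: ", path)
    mk <- header[-(1:6)]
    ncol_expect <- length(header)
    rows <- fields[-1L]
    lens <- lengths(rows)
    if (any(lens != ncol_expect)) {
      bad <- which(lens != ncol_expect)[1L]
      stop("malformed row at line ", bad + 1L, " of ", path, ": expected ",
           ncol_expect, " fields, found ", lens[bad])
    }
    ids <- vapply(rows, `[[`, character(1L), 2L)
    codes <- matrix(parse_code_token(unlist(lapply(rows, `[`, -(1:6)))),
                    nrow = length(rows), ncol = length(mk), byrow = TRUE)
  }
  bad_tok <- !is.na(codes) & !(codes %in% c(0, 1, 2))
  if (any(bad_tok)) {
    idx <- which(bad_tok, arr.ind = TRUE)[1L, ]
    stop("invalid genotype code at data row ", idx[1L], ", marker '",
         mk[idx[2L]], "' in ", path, ": codes must be 0, 1, 2 or missing")
  }
  rownames(codes) <- ids
  colnames(codes) <- mk
  geno_matrix(codes)
}

#' Write genotypes to a delimited file
#'
#' Inverse of [read_genotypes()]; a read-write-read round trip reproduces
#' codes, ids and missing mask exactly (imputed values are written back as
#' missing so the on-disk record stays faithful to the original calls).
#'
#' @param g A [geno_matrix()].
#' @param path Output path.
#' @param dialect `"tabular"` or `"plink_raw"`.
#' @export
write_genotypes <- function(g, path, dialect = c("tabular", "plink_raw")) {
  dialect <- match.arg(dialect)
  codes <- g$codes
  codes[g$missing_mask] <- NA_real_
  fmt <- function(x) ifelse(is.na(x), "NA", format(x, trim = TRUE))
  if (dialect == "tabular") {
    header <- paste(c("id", marker_ids(g)), collapse = "\t")
    body <- vapply(seq_len(nrow(codes)), function(i) {
      paste(c(individual_ids(g)[i], fmt(codes[i, ])), collapse = "\t")
    }, character(1L))
  } else {
    header <- paste(c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE",
                      marker_ids(g)), collapse = " ")
    body <- vapply(seq_len(nrow(codes)), function(i) {
      paste(c("0", individual_ids(g)[i], "0", "0", "0", "-9",
              fmt(codes[i, ])), collapse = " ")
    }, character(1L))
  }
  writeLines(c(header, body), path)
  invisible(path)
}

#' Mean-impute missing genotype codes
#'
#' Missing cells are replaced by the column mean of the non-missing codes
#' (the dosage expectation under the observed allele frequency), which leaves
#' allele frequencies unchanged. The missing mask is preserved for audit and
#' non-missing cells are never touched.
#'
#' @param g A [geno_matrix()].
#' @return A `geno_matrix` with no `NA` codes and `imputed = TRUE`.
#' @export
impute_missing <- function(g) {
  stopifnot(inherits(g, "geno_matrix"))
  codes <- g$codes
  if (anyNA(codes)) {
    all_missing <- colSums(!g$missing_mask) == 0L
    if (any(all_missing))
      stop("marker(s) fully missing, cannot impute: ",
           paste(marker_ids(g)[all_missing], collapse = ", "))
    col_means <- colMeans(codes, na.rm = TRUE)
    idx <- which(is.na(codes), arr.ind = TRUE)
    codes[idx] <- col_means[idx[, 2L]]
  }
  out <- g
  out$codes <- codes
  out$imputed <- TRUE
  out
}

#' Read or write a phenotype table
#'
#' Phenotypes (EBVs, deregressed proofs or raw records) are kept as a tibble
#' whose first column `id` identifies individuals and whose remaining columns
#' are traits. Format on disk: tab-separated with header
#' `id<TAB>trait1<TAB>...`.
#'
#' @param path Path to a tab-separated phenotype file.
#' @return A tibble with an `id` character column and one numeric column per
#'   trait.
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, check.names = FALSE,
                          colClasses = c("character"), sep = "\t")
  if (!identical(names(df)[1L], "id"))
    stop("phenotype file must have 'id' as its first column: ", path)
  for (j in seq_along(df)[-1L]) df[[j]] <- as.numeric(df[[j]])
  if (anyDuplicated(df$id)) stop("duplicated individual ids in ", path)
  tibble::as_tibble(df)
}

#' @rdname read_phenotypes
#' @param phenotypes A phenotype tibble (first column `id`).
#' @export
write_phenotypes <- function(phenotypes, path) {
  utils::write.table(phenotypes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Rescale trait columns to a standard normal scale
#'
#' Default is the z-score: subtract the mean and divide by the sample
#' standard deviation (n-1 denominator), which preserves ordering and is
#' reversible. A rank-based inverse-normal transform (Blom offsets) is
#' available for heavily skewed records.
#'
#' @param phenotypes A phenotype tibble (first column `id`).
#' @param traits Character vector of trait columns to transform; default all
#'   non-id columns.
#' @param method `"zscore"` (default) or `"inverse_normal"`.
#' @return The tibble with transformed trait columns; the set of standardized
#'   traits is recorded in the `"standardized"` attribute.
#' @export
standardize_phenotypes <- function(phenotypes, traits = NULL,
                                   method = c("zscore", "inverse_normal")) {
  method <- match.arg(method)
  if (is.null(traits)) traits <- setdiff(names(phenotypes), "id")
  for (tr in traits) {
    y <- phenotypes[[tr]]
    if (is.null(y)) stop("no trait column '", tr, "'")
    s <- stats::sd(y, na.rm = TRUE)
    if (!is.finite(s) || s == 0)
      stop("trait '", tr, "' has zero variance; cannot standardize")
    phenotypes[[tr]] <- switch(
      method,
      zscore = (y - mean(y, na.rm = TRUE)) / s,
      inverse_normal = {
        r <- rank(y, na.last = "keep")
        z <- stats::qnorm((r - 0.375) / (sum(!is.na(y)) + 0.25))
        (z - mean(z, na.rm = TRUE)) / stats::sd(z, na.rm = TRUE)
      }
    )
  }
  attr(phenotypes, "standardized") <-
    union(attr(phenotypes, "standardized"), traits)
  phenotypes
}

#' Align a phenotype table with a genotype matrix
#'
#' @param g A [geno_matrix()].
#' @param phenotypes Phenotype tibble with an `id` column.
#' @return The phenotype rows reordered to match `individual_ids(g)`;
#'   errors if any genotyped individual lacks a phenotype row.
#' @export
align_phenotypes <- function(g, phenotypes) {
  ids <- individual_ids(g)
  pos <- match(ids, phenotypes$id)
  if (anyNA(pos))
    stop("individuals missing from phenotype table: ",
         paste(utils::head(ids[is.na(pos)], 5L), collapse = ", "))
  phenotypes[pos, , drop = FALSE]
}
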