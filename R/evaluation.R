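#' Build a repeated k-fold cross-validation plan
#'
#' Optionally draws a simple random subpopulation without replacement, then
#' for each repeat partitions it into k folds that are exhaustive, disjoint
#' and balanced (sizes differ by at most one). The standard designs are
#' 5-fold repeated 20 times (cattle-scale) and 10-fold repeated 10 times
#' (pine-scale), both giving 100 validation sets.
#'
#' @param n Number of individuals in the full dataset.
#' @param k Folds per repeat (`>= 2`).
#' @param repeats Number of independent random partitions.
#' @param subpopulation_size Optional subsample size (`<= n`).
#' @param seed Integer seed; plans are reproducible.
#' @return Object of class `cv_plan`: list with `individuals` (indices into
#'   the full dataset), `folds` (tibble `rep`, `fold`, `index`), and the
#'   design parameters.
#' @export
make_cv_plan <- function(n, k, repeats = 1L, subpopulation_size = NULL,
                         seed = 1L) {
  stopifnot(k >= 2, repeats >= 1, n >= 2)
  size <- subpopulation_size %||% n
  if (size > n) stop("subpopulation_size (", size, ") exceeds n (", n, ")")
  if (k > size) stop("k (", k, ") exceeds subpopulation size (", size, ")")
  set.seed(seed)
  individuals <- if (size < n) sort(sample.int(n, size)) else seq_len(n)
  folds <- purrr::map_dfr(seq_len(repeats), function(r) {
    shuffled <- sample(individuals)
    tibble::tibble(rep = r,
                   fold = rep(seq_len(k), length.out = size),
                   index = shuffled)
  })
  structure(list(individuals = individuals, folds = folds, n = n, k = k,
                 repeats = repeats, subpopulation_size = size, seed = seed),
            class = "cv_plan")
}

#' @export
print.cv_plan <- function(x, ...) {
  cat("<cv_plan> ", x$subpopulation_size, " of ", x$n, " individuals; ",
      x$k, "-fold x ", x$repeats, " repeats = ", x$k * x$repeats,
      " validation sets\n", sep = "")
  invisible(x)
}

metric_defined <- function(a, b) {
  length(a) >= 3L && length(a) == length(b) &&
    stats::sd(a) > 0 && stats::sd(b) > 0
}

#' Prediction accuracy
#'
#' Pearson correlation between GEBVs and the response variable in the
#' validation set. Returns `NA` (undefined-metric sentinel) when either
#' vector is constant or fewer than three pairs are available.
#'
#' @param gebv,response Equal-length numeric vectors.
#' @return Scalar correlation, or `NA`.
#' @export
accuracy <- function(gebv, response) {
  if (!metric_defined(gebv, response)) return(NA_real_)
  stats::cor(gebv, response)
}

#' Prediction unbiasedness (regression slope)
#'
#' Ordinary least-squares slope relating GEBVs and responses; 1 indicates a
#' calibrated prediction scale. The default direction regresses the GEBVs on
#' the response (the protocol's literal definition); the field's conventional
#' direction (response on GEBVs) is also available, and [run_crossval()]
#' records both.
#'
#' @param gebv,response Equal-length numeric vectors.
#' @param direction `"gebv_on_response"` (default) or `"response_on_gebv"`.
#' @return Scalar OLS slope, or `NA` when the regressor is constant.
#' @export
unbiasedness <- function(gebv, response,
                         direction = c("gebv_on_response",
                                       "response_on_gebv")) {
  direction <- match.arg(direction)
  if (!metric_defined(gebv, response)) return(NA_real_)
  if (direction == "gebv_on_response") {
    stats::cov(gebv, response) / stats::var(response)
  } else {
    stats::cov(gebv, response) / stats::var(gebv)
  }
}

#' Relative accuracy improvement (percent)
#'
#' `beta = (acc_new - acc_base) / acc_base * 100`, the headline statistic
#' for comparing a new predictor against a baseline.
#'
#' @param acc_new,acc_base Accuracies; `acc_base` must be non-zero.
#' @return Percent improvement.
#' @export
improvement_beta <- function(acc_new, acc_base) {
  if (any(acc_base == 0)) stop("baseline accuracy is zero; beta undefined")
  (acc_new - acc_base) / acc_base * 100
}

fit_one_method <- function(method, genotypes, y_masked, y_full, valid_pos,
                           prior, config, pi_mode, full_pi) {
  if (method == "oracle") {
    return(y_full[valid_pos])
  }
  if (method == "gblup") {
    fit <- gblup(genotypes, y_masked)
    return(as.numeric(fit$gebv[valid_pos]))
  }
  pi <- if (method == "bayesBpi" && pi_mode == "full_data") full_pi else NULL
  fit <- bayes_fit(genotypes, y_masked, method = method, prior = prior,
                   config = config, pi = pi)
  as.numeric(fit$gebv[valid_pos])
}

#' Run the repeated cross-validation protocol
#'
#' For every repeat x fold: mask the validation individuals' responses,
#' train each requested method on the remaining individuals (for BayesB-pi
#' the locus prior is recomputed from the training fold only, so no
#' information leaks from validation responses), predict the held-out GEBVs,
#' and score accuracy and unbiasedness against the held-out responses. A
#' method failure in a fold is recorded and flagged; aggregation proceeds on
#' the remaining folds with a warning.
#'
#' @param genotypes A [geno_matrix()] for the full dataset.
#' @param y Numeric response aligned with the genotype rows.
#' @param methods Subset of `"gblup"`, `"bayesA"`, `"bayesB"`, `"bayesBpi"`
#'   (plus `"oracle"`, a harness check that predicts the true response).
#' @param plan A [make_cv_plan()].
#' @param prior,config Passed to the Bayesian fits; each fold's chain seed is
#'   derived from `config$seed` and the fold counter.
#' @param trait Label recorded in the report.
#' @param pi_mode `"per_fold"` (default; the locus prior is computed inside
#'   each training fold) or `"full_data"` (computed once from all phenotyped
#'   individuals of the subpopulation — deliberately leaky, for probing the
#'   difference).
#' @param keep_predictions Attach each fold's held-out predictions as a
#'   list column (used by leakage diagnostics; off by default so records
#'   stay writable as flat TSV).
#' @return Object of class `eval_report`: per-fold records tibble with
#'   columns `method`, `trait`, `size`, `rep`, `fold`, `n_train`, `n_valid`,
#'   `accuracy`, `unbiasedness` (GEBVs on response),
#'   `unbiasedness_conventional` (response on GEBVs) and `failed`.
#' @export
run_crossval <- function(genotypes, y, methods = c("gblup", "bayesB"),
                         plan, prior = prior_spec(), config = chain_config(),
                         trait = "trait", pi_mode = c("per_fold", "full_data"),
                         keep_predictions = FALSE) {
  pi_mode <- match.arg(pi_mode)
  stopifnot(inherits(genotypes, "geno_matrix"), inherits(plan, "cv_plan"))
  methods <- match.arg(methods,
                       c("gblup", "bayesA", "bayesB", "bayesBpi", "oracle"),
                       several.ok = TRUE)
  y <- as.numeric(y)
  stopifnot(length(y) == nrow(genotypes$codes))
  sub <- plan$individuals
  g_sub <- genotypes[sub, ]
  y_sub <- y[sub]

  full_pi <- NULL
  if ("bayesBpi" %in% methods && pi_mode == "full_data")
    full_pi <- locus_pi(g_sub, y_sub)$pi

  grid <- dplyr::distinct(plan$folds[, c("rep", "fold")])
  records <- purrr::map_dfr(seq_len(nrow(grid)), function(i) {
    r <- grid$rep[i]
    f <- grid$fold[i]
    valid_orig <- plan$folds$index[plan$folds$rep == r & plan$folds$fold == f]
    valid_pos <- match(valid_orig, sub)
    y_masked <- y_sub
    y_masked[valid_pos] <- NA_real_
    y_valid <- y_sub[valid_pos]
    purrr::map_dfr(methods, function(mth) {
      cfg <- config
      cfg$seed <- as.integer((config$seed + 131L * i + 7919L *
                                match(mth, methods)) %% .Machine$integer.max)
      pred <- tryCatch(
        fit_one_method(mth, g_sub, y_masked, y_sub, valid_pos,
                       prior, cfg, pi_mode, full_pi),
        error = function(e) e)
      if (inherits(pred, "error")) {
        warning("method '", mth, "' failed in rep ", r, " fold ", f, ": ",
                conditionMessage(pred))
        return(tibble::tibble(
          method = mth, trait = trait, size = plan$subpopulation_size,
          rep = r, fold = f, n_train = sum(!is.na(y_masked)),
          n_valid = length(valid_pos), accuracy = NA_real_,
          unbiasedness = NA_real_, unbiasedness_conventional = NA_real_,
          failed = TRUE))
      }
      out <- tibble::tibble(
        method = mth, trait = trait, size = plan$subpopulation_size,
        rep = r, fold = f, n_train = sum(!is.na(y_masked)),
        n_valid = length(valid_pos),
        accuracy = accuracy(pred, y_valid),
        unbiasedness = unbiasedness(pred, y_valid, "gebv_on_response"),
        unbiasedness_conventional =
          unbiasedness(pred, y_valid, "response_on_gebv"),
        failed = FALSE)
      if (keep_predictions) out$predictions <- list(pred)
      out
    })
  })
  structure(list(records = records, plan = plan, methods = methods,
                 trait = trait, pi_mode = pi_mode),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report> ", nrow(x$records), " fold records (",
      paste(x$methods, collapse = ", "), "); trait = ", x$trait, "\n",
      sep = "")
  print(cv_summary(x))
  invisible(x)
}

#' @export
tidy.eval_report <- function(x, ...) x$records

#' @export
glance.eval_report <- function(x, ...) {
  tibble::tibble(n_records = nrow(x$records),
                 n_failed = sum(x$records$failed),
                 k = x$plan$k, repeats = x$plan$repeats,
                 size = x$plan$subpopulation_size, trait = x$trait)
}

#' Aggregate a cross-validation report
#'
#' Mean and standard error (SD over fold records divided by the square root
#' of the number of validation sets aggregated) of accuracy and unbiasedness
#' per method, within trait and subpopulation size.
#'
#' @param report An `eval_report`, or a tibble of fold records (possibly
#'   several reports bound together).
#' @return Tibble with one row per trait x size x method.
#' @export
cv_summary <- function(report) {
  rec <- if (inherits(report, "eval_report")) report$records else report
  rec <- dplyr::filter(rec, !.data$failed)
  dplyr::summarise(
    dplyr::group_by(rec, .data$trait, .data$size, .data$method),
    mean_accuracy = mean(.data$accuracy, na.rm = TRUE),
    se_accuracy = stats::sd(.data$accuracy, na.rm = TRUE) / sqrt(dplyr::n()),
    mean_unbiasedness = mean(.data$unbiasedness, na.rm = TRUE),
    se_unbiasedness = stats::sd(.data$unbiasedness, na.rm = TRUE) /
      sqrt(dplyr::n()),
    n_folds = dplyr::n(), .groups = "drop")
}

#' Summary table across subpopulation sizes
#'
#' Reproduces the standard layout for size-ladder experiments: one row per
#' trait x size x method plus, per trait x method, a `"Mean"` row whose
#' accuracy is the arithmetic mean of the per-size mean accuracies (sizes
#' are averaged, not pooled fold records). A `best` flag marks the
#' highest-mean-accuracy method within each trait x size row group.
#'
#' @param records Fold-record tibble (bind the `tidy()` output of several
#'   reports).
#' @return Tibble with `size` as character (including `"Mean"` rows) and a
#'   logical `best` column.
#' @export
cv_summary_table <- function(records) {
  base <- cv_summary(records)
  mean_rows <- dplyr::summarise(
    dplyr::group_by(base, .data$trait, .data$method),
    mean_accuracy = mean(.data$mean_accuracy),
    se_accuracy = mean(.data$se_accuracy),
    mean_unbiasedness = mean(.data$mean_unbiasedness),
    se_unbiasedness = mean(.data$se_unbiasedness),
    n_folds = sum(.data$n_folds), .groups = "drop")
  mean_rows$size <- "Mean"
  base$size <- as.character(base$size)
  out <- dplyr::bind_rows(base, mean_rows)
  out <- dplyr::mutate(
    dplyr::group_by(out, .data$trait, .data$size),
    best = .data$mean_accuracy == max(.data$mean_accuracy))
  dplyr::arrange(dplyr::ungroup(out), .data$trait,
                 .data$size != "Mean", .data$size, .data$method)
}

#' Plot per-fold accuracies by method
#'
#' @param object An `eval_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.eval_report <- function(object, ...) {
  rec <- dplyr::filter(object$records, !.data$failed)
  ggplot2::ggplot(rec, ggplot2::aes(x = .data$method, y = .data$accuracy)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::labs(x = NULL, y = "validation accuracy (Pearson r)",
                  title = paste0("Cross-validated accuracy: ", object$trait,
                                 " (n = ", object$plan$subpopulation_size,
                                 ")"))
}
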