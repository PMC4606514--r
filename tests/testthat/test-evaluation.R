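test_that("cross-validation folds partition the individuals", {
  plan <- make_cv_plan(10, 5, repeats = 1, seed = 91)
  sizes <- table(plan$folds$fold)
  expect_true(all(sizes == 2))
  expect_setequal(plan$folds$index, 1:10)
  expect_equal(anyDuplicated(plan$folds$index), 0L)
})

test_that("plans are reproducible and fold sizes stay balanced", {
  p1 <- make_cv_plan(103, 5, repeats = 3, seed = 92)
  p2 <- make_cv_plan(103, 5, repeats = 3, seed = 92)
  expect_identical(p1$folds, p2$folds)
  for (r in 1:3) {
    f <- p1$folds[p1$folds$rep == r, ]
    expect_setequal(f$index, 1:103)
    expect_lte(diff(range(table(f$fold))), 1)
  }
})

test_that("subpopulation sampling reproduces the stated design arithmetic", {
  plan <- make_cv_plan(5024, 5, repeats = 20, subpopulation_size = 200,
                       seed = 93)
  expect_equal(length(plan$individuals), 200)
  grid <- unique(plan$folds[, c("rep", "fold")])
  expect_equal(nrow(grid), 100)  # 100 validation sets
  per_fold <- table(plan$folds$rep, plan$folds$fold)
  expect_true(all(per_fold == 40))
  expect_error(make_cv_plan(100, 5, subpopulation_size = 3, seed = 1),
               "exceeds")
  expect_error(make_cv_plan(100, 5, subpopulation_size = 200, seed = 1),
               "exceeds")
})

test_that("accuracy is the Pearson correlation with undefined sentinels", {
  x <- c(1, 2, 3, 4)
  expect_equal(accuracy(x, x), 1)
  expect_equal(accuracy(x, -x), -1)
  y <- c(1, 2, 3, 100)
  # brute-force Pearson from first principles
  brute <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(accuracy(x, y), brute, tolerance = 1e-12)
  expect_true(is.na(accuracy(c(1, 1, 1), c(1, 2, 3))))
  expect_true(is.na(accuracy(c(1, 2), c(1, 2))))
})

test_that("unbiasedness is the OLS slope in the configured direction", {
  x <- c(1, 2, 3, 4.5)
  expect_equal(unbiasedness(x, x), 1)
  expect_equal(unbiasedness(2 * x, x), 2)  # literal: GEBVs on response
  expect_equal(unbiasedness(2 * x, x, "response_on_gebv"), 0.5)
  set.seed(94)
  a <- rnorm(30); b <- rnorm(30)
  expect_equal(unbiasedness(a, b), cov(a, b) / var(b), tolerance = 1e-10)
  expect_equal(unbiasedness(a, b, "response_on_gebv"),
               cov(a, b) / var(a), tolerance = 1e-10)
  expect_true(is.na(unbiasedness(rep(1, 5), rnorm(5))))
})

test_that("improvement beta is the percent gain over the baseline", {
  expect_equal(improvement_beta(0.5, 0.5), 0)
  expect_equal(improvement_beta(0.55, 0.5), 10)
  expect_error(improvement_beta(0.5, 0), "zero")
})

test_that("the protocol records the right bookkeeping per fold and method", {
  ds <- simulate_dataset(arch_spec(60, 40, n_qtl = 10,
                                   major_qtl_fraction = 0.3,
                                   heritability = 0.5, seed = 95))
  plan <- make_cv_plan(60, 5, repeats = 4, seed = 96)
  rep <- run_crossval(ds$genotypes, ds$phenotypes[[2]],
                      methods = c("oracle", "gblup"), plan = plan,
                      config = fast_chain(seed = 97))
  rec <- tidy(rep)
  expect_equal(nrow(rec), 2 * 5 * 4)
  expect_equal(rec$accuracy[rec$method == "oracle"], rep(1, 20),
               tolerance = 1e-12)
  expect_equal(rec$unbiasedness[rec$method == "oracle"], rep(1, 20),
               tolerance = 1e-12)
  expect_true(all(rec$n_valid == 12))
  smry <- cv_summary(rep)
  or <- smry[smry$method == "oracle", ]
  expect_equal(or$n_folds, 20L)
  sub <- rec[rec$method == "gblup", ]
  expect_equal(smry$se_accuracy[smry$method == "gblup"],
               sd(sub$accuracy) / sqrt(20), tolerance = 1e-12)
})

test_that("the summary table averages per-size means into the Mean row", {
  # synthetic fold records: aggregation contract only
  rec <- tidyr::expand_grid(method = c("A", "B"), size = c(100L, 200L),
                            rep = 1:2, fold = 1:3)
  rec$trait <- "tr"
  set.seed(98)
  rec$accuracy <- runif(nrow(rec), 0.2, 0.8)
  rec$unbiasedness <- rnorm(nrow(rec), 1, 0.1)
  rec$unbiasedness_conventional <- rec$unbiasedness
  rec$failed <- FALSE
  tab <- cv_summary_table(rec)
  for (mth in c("A", "B")) {
    sizes <- tab[tab$method == mth & tab$size != "Mean", ]
    mean_row <- tab[tab$method == mth & tab$size == "Mean", ]
    expect_equal(mean_row$mean_accuracy, mean(sizes$mean_accuracy),
                 tolerance = 1e-12)
  }
  # best flag marks the maximum within each trait x size group
  for (sz in unique(tab$size)) {
    gr <- tab[tab$size == sz, ]
    expect_equal(gr$best, gr$mean_accuracy == max(gr$mean_accuracy))
  }
})

test_that("method failures are flagged and aggregation continues", {
  ds <- simulate_dataset(arch_spec(30, 10, n_qtl = 3,
                                   major_qtl_fraction = 0.3,
                                   heritability = 0.5, seed = 99))
  plan <- make_cv_plan(30, 3, repeats = 1, seed = 100)
  # a constant response makes REML impossible in every fold
  y_bad <- rep(1, 30)
  rep <- suppressWarnings(
    run_crossval(ds$genotypes, y_bad, methods = "gblup", plan = plan))
  expect_true(all(tidy(rep)$failed))
  expect_equal(nrow(cv_summary(rep)), 0L)
  w <- testthat::capture_warnings(
    run_crossval(ds$genotypes, y_bad, methods = "gblup",
                 plan = make_cv_plan(30, 2, seed = 1)))
  expect_true(any(grepl("failed in rep", w)))
})

test_that("training folds never see validation responses", {
  ds <- simulate_dataset(arch_spec(50, 30, n_qtl = 5,
                                   major_qtl_fraction = 0.3,
                                   heritability = 0.5, seed = 101))
  y <- ds$phenotypes[[2]]
  plan <- make_cv_plan(50, 5, repeats = 1, seed = 102)
  cfg <- fast_chain(200, 50, seed = 103)
  rep1 <- run_crossval(ds$genotypes, y, methods = c("gblup", "bayesBpi"),
                       plan = plan, config = cfg, keep_predictions = TRUE)
  # corrupt the responses of fold 1's validation individuals only
  v1 <- plan$folds$index[plan$folds$fold == 1]
  y2 <- y
  y2[v1] <- y[v1] + 100
  rep2 <- run_crossval(ds$genotypes, y2, methods = c("gblup", "bayesBpi"),
                       plan = plan, config = cfg, keep_predictions = TRUE)
  r1 <- tidy(rep1); r2 <- tidy(rep2)
  for (mth in c("gblup", "bayesBpi")) {
    p1 <- r1$predictions[r1$fold == 1 & r1$method == mth][[1]]
    p2 <- r2$predictions[r2$fold == 1 & r2$method == mth][[1]]
    expect_identical(p1, p2)  # training stage untouched by validation y
  }
})

test_that("per-fold and full-data pi modes differ when leakage matters", {
  ds <- simulate_dataset(arch_spec(50, 30, n_qtl = 5,
                                   major_qtl_fraction = 0.3,
                                   heritability = 0.5, seed = 104))
  plan <- make_cv_plan(50, 5, repeats = 1, seed = 105)
  cfg <- fast_chain(200, 50, seed = 106)
  r_fold <- run_crossval(ds$genotypes, ds$phenotypes[[2]],
                         methods = "bayesBpi", plan = plan, config = cfg,
                         keep_predictions = TRUE)
  r_full <- run_crossval(ds$genotypes, ds$phenotypes[[2]],
                         methods = "bayesBpi", plan = plan, config = cfg,
                         pi_mode = "full_data", keep_predictions = TRUE)
  p_fold <- tidy(r_fold)$predictions[[1]]
  p_full <- tidy(r_full)$predictions[[1]]
  expect_false(identical(p_fold, p_full))
})
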