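# Discrimination models: EM imputation, stratified split, random-forest
# fit/evaluate and the four-dataset suite.

sim_mvn <- function(n, p, rho = 0.5, seed = 1) {
  set.seed(seed)
  sigma <- rho^abs(outer(1:p, 1:p, "-"))
  l <- chol(sigma)
  matrix(rnorm(n * p), n, p) %*% l
}

test_that("imputation is a no-op on complete tables", {
  x <- sim_mvn(30, 4, seed = 1)
  colnames(x) <- paste0("f", 1:4)
  out <- impute_missing(x)
  expect_equal(unclass(out), unclass(x), ignore_attr = TRUE)
  expect_identical(attr(out, "n_imputed_cells"), 0L)
})

test_that("a fully-missing feature is rejected by name", {
  x <- sim_mvn(20, 3, seed = 2)
  colnames(x) <- c("a", "b", "c")
  x[, "b"] <- NA
  expect_error(impute_missing(x), "b")
})

test_that("EM imputation tracks a perfectly correlated partner feature", {
  set.seed(3)
  f1 <- rnorm(80)
  x <- cbind(f1 = f1, f2 = f1, f3 = rnorm(80))
  miss <- sample(80, 20)
  x[miss, "f2"] <- NA
  out <- impute_missing(x)
  expect_lt(max(abs(out[miss, "f2"] - f1[miss])), 0.15)
})

test_that("MCAR imputation error is close to the known-covariance oracle", {
  p <- 5; n <- 300
  x_true <- sim_mvn(n, p, rho = 0.6, seed = 4)
  colnames(x_true) <- paste0("f", 1:p)
  x <- x_true
  set.seed(5)
  miss <- matrix(runif(n * p) < 0.10, n, p)
  miss[rowSums(miss) == p, ] <- FALSE  # keep at least one observed per row
  x[miss] <- NA
  out <- impute_missing(x)
  rmse <- sqrt(mean((out[miss] - x_true[miss])^2))
  # oracle: conditional mean under the true covariance
  sigma <- 0.6^abs(outer(1:p, 1:p, "-"))
  oracle <- x
  for (i in which(rowSums(miss) > 0)) {
    mi <- which(miss[i, ]); oi <- setdiff(1:p, mi)
    oracle[i, mi] <- sigma[mi, oi] %*% solve(sigma[oi, oi]) %*% x_true[i, oi]
  }
  rmse_oracle <- sqrt(mean((oracle[miss] - x_true[miss])^2))
  expect_lt(rmse, 1.3 * rmse_oracle)
})

test_that("multiple imputation returns distinct completed tables", {
  x <- sim_mvn(60, 3, seed = 6)
  colnames(x) <- paste0("f", 1:3)
  x[sample(60, 10), 2] <- NA
  out <- impute_missing(x, n_imputations = 3, seed = 7)
  expect_length(out, 3)
  expect_false(identical(out[[1]], out[[2]]))
  expect_identical(attr(out, "n_imputed_cells"), 10L)
  # observed cells never change
  for (m in 1:3) expect_equal(out[[m]][!is.na(x)], x[!is.na(x)])
})

test_that("70/30 split is stratified, deterministic and exhaustive", {
  lab <- rep(c("PD", "AP"), c(46, 25))
  sp <- split_cohort(lab, 0.7, seed = 3)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_setequal(c(sp$train, sp$test), seq_along(lab))
  expect_equal(sum(lab[sp$train] == "PD"), 32)  # round(0.7 * 46)
  expect_equal(sum(lab[sp$train] == "AP"), 18)  # round(0.7 * 25)
  expect_identical(split_cohort(lab, 0.7, seed = 3), sp)
  expect_false(identical(split_cohort(lab, 0.7, seed = 4)$train, sp$train))
  lab100 <- rep(c("a", "b"), each = 50)
  sp100 <- split_cohort(lab100, 0.7, seed = 1)
  expect_length(sp100$train, 70)
  expect_length(sp100$test, 30)
  expect_error(split_cohort(c("a", "b", "b"), 0.7), "at least 2")
})

test_that("a single perfectly discriminating feature gives AUC 1", {
  lab <- rep(c("PD", "AP"), each = 20)
  x <- data.frame(f = ifelse(lab == "AP", rnorm(40, 10), rnorm(40, 0)))
  r <- fit_and_evaluate(x, lab, seed = 5, n_trees = 100)
  expect_equal(r$held_out_auc, 1.0)
})

test_that("no leakage: perturbing test labels never changes predictions", {
  cfg <- simulation_config(n_per_group = c(PD = 25, MSA = 15), n_peptides = 6,
                           seed = 23)
  ft <- build_feature_table(generate_cohort(cfg))
  xm <- as.matrix(ft$features)
  set.seed(8)
  xm[sample(length(xm), 30)] <- NA  # some missing cells
  x <- as.data.frame(xm)
  lab1 <- ft$labels
  sp <- split_cohort(lab1, 0.7, seed = 9)
  r1 <- fit_and_evaluate(x, lab1, seed = 9, n_trees = 100, split = sp)
  lab2 <- lab1
  lab2[sp$test] <- rev(lab2[sp$test])  # perturb held-out labels only
  r2 <- fit_and_evaluate(x, lab2, seed = 9, n_trees = 100, split = sp)
  expect_identical(r1$train, r2$train)
  expect_identical(r1$importance, r2$importance)  # fitted model unchanged
})

test_that("adding a pure-noise feature barely moves the planted-effect AUC", {
  aucs <- sapply(1:8, function(s) {
    eff <- lapply(sprintf("P%02d", 1:4), planted_effect, group = "AP",
                  fold_change = 1.8)
    cfg <- simulation_config(n_per_group = c(PD = 40, MSA = 15, PSP = 8),
                             n_peptides = 8, planted_effects = eff,
                             marker_shift = 1.5, seed = s)
    ft <- build_feature_table(generate_cohort(cfg))
    base <- fit_and_evaluate(ft$features, ft$labels, seed = s, n_trees = 200)
    set.seed(s)
    withnoise <- cbind(ft$features, pure_noise = rnorm(nrow(ft$features)))
    noisy <- fit_and_evaluate(withnoise, ft$labels, seed = s, n_trees = 200)
    c(base$held_out_auc, noisy$held_out_auc)
  })
  expect_lt(abs(mean(aucs[1, ]) - mean(aucs[2, ])), 0.05)
})

test_that("feature retention keeps a subset and reports importances", {
  lab <- rep(c("PD", "AP"), each = 25)
  set.seed(10)
  x <- data.frame(good = ifelse(lab == "AP", rnorm(50, 2), rnorm(50)),
                  junk1 = rnorm(50), junk2 = rnorm(50), junk3 = rnorm(50))
  r <- fit_and_evaluate(x, lab, seed = 11, n_trees = 200, select_features = TRUE,
                        importance_quantile = 0.75)
  expect_lt(length(r$retained), 4)
  expect_true("good" %in% r$retained)
})

test_that("the four-dataset suite runs, errors gracefully and is reproducible", {
  eff <- lapply(sprintf("P%02d", 1:3), planted_effect, group = "AP",
                fold_change = 1.8)
  cfg <- simulation_config(n_per_group = c(PD = 30, MSA = 12, PSP = 6),
                           n_peptides = 6, planted_effects = eff,
                           marker_shift = 1.2, seed = 31)
  ft <- build_feature_table(generate_cohort(cfg))
  suite <- run_model_suite(ft$features, ft$labels, ft$families, datasets = 1:4,
                           seed = 2, n_trees = 100)
  expect_equal(nrow(suite$comparison), 4)
  expect_true(all(suite$comparison$error == ""))
  expect_true(all(suite$comparison$held_out_auc >= 0 &
                    suite$comparison$held_out_auc <= 1))
  # reproducible per (seed, spec)
  suite2 <- run_model_suite(ft$features, ft$labels, ft$families, datasets = 1:4,
                            seed = 2, n_trees = 100)
  expect_equal(suite$comparison, suite2$comparison)
  # missing family: per-spec error, suite continues
  fam2 <- ft$families; fam2$markers <- c("NOT_A_COLUMN")
  s3 <- run_model_suite(ft$features, ft$labels, fam2, datasets = c(1, 2), seed = 2,
                        n_trees = 50)
  expect_equal(s3$comparison$error[s3$comparison$dataset_id == 2] != "", TRUE)
  expect_equal(s3$comparison$error[s3$comparison$dataset_id == 1], "")
  expect_warning(run_model_suite(ft$features, ft$labels, ft$families,
                                 datasets = integer(0)), "empty")
})
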