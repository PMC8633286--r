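# Statistical battery: Mann-Whitney, rank ANCOVA, Kruskal-Wallis/Dunn,
# Spearman, chi-squared, ROC/AUC, Bonferroni.

test_that("Mann-Whitney exact p matches the enumeration oracle", {
  mw <- mann_whitney(c(1, 2, 3, 4), c(10, 11, 12, 13))
  expect_equal(mw$statistic, 0)
  expect_equal(mw$p_value, 2 / 70, tolerance = 1e-12)
  # identical multisets: p = 1 at the mean of U
  expect_equal(mann_whitney(c(1, 2, 3), c(3, 2, 1))$p_value, 1)
  # random tie-free cases vs enumeration
  set.seed(4)
  for (i in 1:5) {
    a <- sample(100, 6); b <- sample(200, 5) + 0.5
    expect_equal(mann_whitney(a, b, mode = "exact")$p_value,
                 oracle_mw_exact(a, b), tolerance = 1e-9)
  }
  expect_error(mann_whitney(numeric(0), 1:3), "non-empty")
})

test_that("tied data p matches a permutation oracle within 0.02", {
  set.seed(11)
  a <- sample(1:5, 12, replace = TRUE)
  b <- sample(2:6, 12, replace = TRUE)
  p_pkg <- mann_whitney(a, b, mode = "normal_approx")$p_value
  p_perm <- oracle_mw_permutation(a, b, n_perm = 10000, seed = 2)
  expect_lt(abs(p_pkg - p_perm), 0.02)
  # small tied samples: exact enumeration path
  p_exact <- mann_whitney(c(1, 1, 2), c(2, 3, 3), mode = "exact")$p_value
  expect_equal(p_exact, oracle_mw_exact(c(1, 1, 2), c(2, 3, 3)), tolerance = 1e-12)
})

test_that("Kruskal-Wallis with Dunn reproduces the hand-computed example", {
  kd <- kruskal_dunn(c(1, 2, 3, 4, 5, 6, 7, 8, 9),
                     rep(c("a", "b", "c"), each = 3))
  expect_equal(kd$statistic, 7.2)
  expect_equal(kd$df, 2)
  expect_equal(kd$p_omnibus, stats::pchisq(7.2, 2, lower.tail = FALSE))
  expect_equal(nrow(kd$pairwise), 3)
  expect_true(all(kd$pairwise$p_adjusted >= kd$pairwise$p_raw))
  # identical groups: H = 0, p = 1
  kd0 <- kruskal_dunn(rep(c(1, 2, 3), 3), rep(c("a", "b", "c"), each = 3))
  expect_equal(kd0$statistic, 0)
  expect_equal(kd0$p_omnibus, 1)
  # the extreme pair carries the smallest Dunn p on a planted one-group shift
  set.seed(3)
  v <- c(rnorm(15), rnorm(15), rnorm(15, 3))
  kd2 <- kruskal_dunn(v, rep(c("a", "b", "c"), each = 15))
  pw <- kd2$pairwise
  expect_true(all(pw$p_adjusted[pw$group_1 == "a" & pw$group_2 == "b"] >
                    min(pw$p_adjusted)))
  expect_error(kruskal_dunn(1:3, factor(c("a", "a", "b"), levels = c("a", "b", "c"))),
               "group")
})

test_that("rank ANCOVA detects a group shift and respects the covariate", {
  # strong group shift, covariate uncorrelated: p < 0.01 in nearly all seeds
  ps <- sapply(1:20, function(s) {
    set.seed(s)
    g <- rep(c("a", "b", "c"), each = 30)
    x <- rnorm(90, 60, 10)
    y <- rnorm(90) + (g == "c") * 1
    rank_ancova(y, g, x)$p_omnibus
  })
  expect_gte(sum(ps < 0.01), 18)
  # values determined by the covariate, groups differing only in covariate:
  # the adjusted test rejects near alpha while Kruskal-Wallis rejects wildly
  rej <- sapply(1:200, function(s) {
    set.seed(1000 + s)
    g <- rep(c("a", "b", "c"), each = 20)
    x <- rnorm(60, rep(c(50, 60, 70), each = 20), 6)
    y <- x
    c(rank_ancova(y, g, x, posthoc = FALSE)$p_omnibus < 0.05,
      stats::kruskal.test(y, factor(g))$p.value < 0.05)
  })
  expect_lt(mean(rej[1, ]), 0.12)
  expect_gt(mean(rej[2, ]), 0.5)
  # structure: pairwise Bonferroni with k = 3 groups gives 3 comparisons
  set.seed(5)
  ra <- rank_ancova(rnorm(30), rep(c("a", "b", "c"), 10), rnorm(30))
  expect_equal(nrow(ra$pairwise), 3)
  expect_true(all(ra$pairwise$p_adjusted >= ra$pairwise$p_raw))
  expect_true(all(ra$pairwise$p_adjusted <= 1))
  # degenerate constant response
  rd <- rank_ancova(rep(1, 30), rep(c("a", "b", "c"), 10), rnorm(30))
  expect_true(rd$degenerate)
  expect_equal(rd$p_omnibus, 1)
  expect_error(rank_ancova(rnorm(5), c("a", "a", "a", "b", "b"), rnorm(5)), "n >= 3")
})

test_that("Spearman correlation is monotone invariant and flags constants", {
  x <- c(3, 1, 4, 1.5, 9, 2.6, 5.3)
  expect_equal(spearman_cor(x, x^3)$rho, 1.0)
  expect_equal(spearman_cor(x, -x)$rho, -1.0)
  set.seed(6)
  y <- rnorm(50)
  z <- rnorm(50)
  expect_equal(spearman_cor(y, z)$rho, spearman_cor(exp(y), z)$rho)
  expect_true(spearman_cor(rep(1, 10), rnorm(10))$degenerate)
  expect_error(spearman_cor(1:2, 1:2), "3 complete")
})

test_that("chi-squared reproduces the cohort sex-table p-values", {
  validation <- matrix(c(17, 22, 30, 16, 12, 5, 4, 4), nrow = 2)
  res_v <- chi_squared(validation)
  expect_equal(res_v$df, 3)
  expect_equal(round(res_v$p_value, 2), 0.13)
  discovery <- matrix(c(6, 4, 7, 3, 3, 2), nrow = 2)
  res_d <- chi_squared(discovery)
  expect_equal(res_d$df, 2)
  expect_equal(round(res_d$p_value, 2), 0.88)
  # perfectly proportional table: statistic 0, p 1
  prop <- matrix(c(10, 20, 5, 10), nrow = 2)
  expect_equal(chi_squared(prop)$statistic, 0)
  expect_equal(chi_squared(prop)$p_value, 1)
  expect_error(chi_squared(matrix(c(0, 0, 1, 2), nrow = 2)), "marginal")
})

test_that("AUC equals U/(n1 n2) and label reversal complements it", {
  expect_equal(roc_auc(c(1, 2, 3, 10, 11), c("n", "n", "n", "p", "p"), "p")$auc, 1.0)
  set.seed(7)
  for (i in 1:100) {
    n1 <- sample(3:12, 1); n2 <- sample(3:12, 1)
    sc <- sample(1000, n1 + n2)  # tie-free
    lab <- rep(c("pos", "neg"), c(n1, n2))
    auc <- roc_auc(sc, lab, "pos")$auc
    u <- mann_whitney(sc[lab == "pos"], sc[lab == "neg"])$statistic
    expect_identical(auc, u / (n1 * n2))
    expect_equal(roc_auc(sc, lab, "neg")$auc, 1 - auc)
  }
  # ties contribute one half
  expect_equal(roc_auc(c(1, 1), c("p", "n"), "p")$auc, 0.5)
  expect_error(roc_auc(1:3, c("p", "p", "p"), "p"), "both classes")
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(12)
  sc <- c(rnorm(30), rnorm(25, 0.8))
  lab <- rep(c("PD", "AP"), c(30, 25))
  ours <- roc_auc(sc, lab, "AP")$auc
  ref <- as.numeric(pROC::auc(pROC::roc(lab, sc, levels = c("PD", "AP"),
                                        direction = "<", quiet = TRUE)))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("Bonferroni adjustment is min(1, m p) and never below raw", {
  expect_equal(bonferroni_adjust(c(0.01, 0.2), m = 3), c(0.03, 0.6))
  expect_equal(bonferroni_adjust(1), 1)
  set.seed(13)
  p <- runif(50)
  expect_true(all(bonferroni_adjust(p) >= p))
  expect_true(all(bonferroni_adjust(p, m = 7) <= 1))
  expect_error(bonferroni_adjust(0.5, m = 0), "m must be")
  expect_error(bonferroni_adjust(c(0.5, 0)), "p-values")
})

test_that("tests are invariant under sample reordering", {
  set.seed(14)
  y <- rnorm(45); g <- rep(c("a", "b", "c"), 15); x <- rnorm(45)
  perm <- sample(45)
  expect_equal(rank_ancova(y, g, x)$p_omnibus,
               rank_ancova(y[perm], g[perm], x[perm])$p_omnibus)
  expect_equal(kruskal_dunn(y, g)$p_omnibus,
               kruskal_dunn(y[perm], g[perm])$p_omnibus)
  lab <- rep(c("p", "n"), c(20, 25))
  expect_equal(roc_auc(y, lab, "p")$auc, roc_auc(y[perm], lab[perm], "p")$auc)
})

test_that("per-peptide group table mirrors the validation-stage layout", {
  cfg <- simulation_config(n_per_group = c(control = 12, PD = 15, MSA = 8, PSP = 5),
                           n_peptides = 4,
                           planted_effects = list(planted_effect("P01", "AP", 2)),
                           seed = 19)
  co <- generate_cohort(cfg)
  q <- srm_quantify(co$srm_report, co$metadata)$quant
  tab <- peptide_group_stats(q, co$metadata)
  expect_equal(nrow(tab), 4)
  expect_true(all(c("mean_PD", "sd_MSA", "p_ancova", "p_pd_vs_ap",
                    "p_pd_vs_msa", "auc_pd_vs_ap") %in% names(tab)))
  r1 <- tab[tab$peptide_id == "P01", ]
  expect_lt(r1$mean_MSA, r1$mean_PD)  # planted AP-down effect visible
  expect_gt(r1$auc_pd_vs_ap, 0.5)
})
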