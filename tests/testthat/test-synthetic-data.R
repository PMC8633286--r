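# Synthetic cohort generator: configuration validation, determinism,
# planted-effect and age-correlation recovery, left-censoring behaviour.

test_that("invalid configurations are rejected with the offending field named", {
  expect_error(simulation_config(n_per_group = c(PD = 1, MSA = 10)), "n_per_group")
  expect_error(simulation_config(n_per_group = c(PD = 10, XX = 10)), "n_per_group")
  expect_error(planted_effect("P01", "PD", 0.5), "fold_change")
  expect_error(simulation_config(missing_censor_quantile = 1), "missing_censor_quantile")
  expect_error(simulation_config(age_rho = c(P99 = 0.5)), "age_rho")
  expect_error(simulation_config(
    planted_effects = list(planted_effect("NOPE", "PD", 2))), "NOPE")
  expect_error(simulation_config(sigma_log = -1), "sigma_log")
})

test_that("a fixed seed gives a bit-identical cohort", {
  cfg <- simulation_config(n_per_group = c(control = 5, PD = 6, MSA = 5),
                           n_peptides = 6, missing_censor_quantile = 0.1,
                           seed = 11)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(serialize(c1, NULL), serialize(c2, NULL))
  c3 <- generate_cohort(simulation_config(n_per_group = c(control = 5, PD = 6, MSA = 5),
                                          n_peptides = 6,
                                          missing_censor_quantile = 0.1, seed = 12))
  expect_false(identical(c1$discovery_matrix, c3$discovery_matrix))
})

test_that("cohort structure is internally consistent", {
  cfg <- simulation_config(n_per_group = c(control = 4, PD = 5, MSA = 4),
                           n_peptides = 5, seed = 7)
  co <- generate_cohort(cfg)
  expect_setequal(colnames(co$discovery_matrix), co$metadata$sample_id)
  expect_identical(unname(co$group_of[co$metadata$sample_id]), co$metadata$group)
  expect_length(co$truth$planted_effects, 0)
  expect_true(all(co$metadata$age > 0))
  expect_true(all(co$metadata$total_protein > 0))
  # null model: group medians differ only by sampling noise
  pd <- co$discovery_matrix[1, co$group_of == "PD"]
  msa <- co$discovery_matrix[1, co$group_of == "MSA"]
  expect_gt(mann_whitney(pd, msa)$p_value, 0.001)
})

test_that("a planted fold change of 2 is recovered in the group-mean ratio", {
  # Monte-Carlo mean over 20 seeds at the default (heavily skewed) intensity
  # model, n = 50/group
  ratios <- sapply(1:20, function(s) {
    cfg <- simulation_config(n_per_group = c(PD = 50, MSA = 50), n_peptides = 3,
                             planted_effects = list(planted_effect("P01", "MSA", 2,
                                                                   "down")),
                             seed = s)
    co <- generate_cohort(cfg)
    mean(co$discovery_matrix["P01", co$group_of == "PD"]) /
      mean(co$discovery_matrix["P01", co$group_of == "MSA"])
  })
  expect_gt(mean(ratios), 1.6)
  expect_lt(mean(ratios), 2.5)
})

test_that("planted folds are recoverable per seed under moderate biological noise", {
  # recoverability band [0.75 f, 1.3 f] in >= 18/20 seeds at n = 50/group,
  # sigma_log = 0.5 (moderate dispersion, CV ~ 0.5)
  f <- 2
  hits <- sapply(1:20, function(s) {
    cfg <- simulation_config(n_per_group = c(PD = 50, MSA = 50), n_peptides = 3,
                             planted_effects = list(planted_effect("P01", "MSA", f)),
                             sigma_log = 0.5, seed = s)
    co <- generate_cohort(cfg)
    r <- mean(co$discovery_matrix["P01", co$group_of == "PD"]) /
      mean(co$discovery_matrix["P01", co$group_of == "MSA"])
    r >= 0.75 * f && r <= 1.3 * f
  })
  expect_gte(sum(hits), 18)
})

test_that("target age correlation is induced to within the documented tolerance", {
  rhos <- sapply(1:20, function(s) {
    cfg <- simulation_config(n_per_group = c(control = 100, PD = 100),
                             n_peptides = 3, age_rho = c(P02 = 0.5), seed = s)
    co <- generate_cohort(cfg)
    spearman_cor(co$discovery_matrix["P02", co$metadata$sample_id],
                 co$metadata$age)$rho
  })
  expect_gt(mean(rhos), 0.35)
  expect_lt(mean(rhos), 0.65)
  # a zero-rho peptide stays uncorrelated on average
  rho0 <- sapply(1:10, function(s) {
    cfg <- simulation_config(n_per_group = c(control = 100, PD = 100),
                             n_peptides = 3, seed = s)
    co <- generate_cohort(cfg)
    spearman_cor(co$discovery_matrix["P01", co$metadata$sample_id],
                 co$metadata$age)$rho
  })
  expect_lt(abs(mean(rho0)), 0.15)
})

test_that("missingness is left-censored", {
  cfg <- simulation_config(n_per_group = c(control = 30, PD = 30), n_peptides = 5,
                           missing_censor_quantile = 0.3, seed = 9)
  co <- generate_cohort(cfg)
  expect_true(anyNA(co$discovery_matrix))
  for (p in rownames(co$discovery_matrix)) {
    obs <- co$discovery_matrix[p, ]
    pre <- co$truth$precensor_matrix[p, ]
    # observed mean strictly exceeds the pre-censoring mean, and every
    # censored value sits below every observed one
    expect_gt(mean(obs, na.rm = TRUE), mean(pre))
    expect_lt(max(pre[is.na(obs)]), min(obs, na.rm = TRUE))
  }
})

test_that("calibration series generator honours design and noise", {
  s <- generate_calibration_series(levels = c(0, 1, 2), noise_cv = 0, seed = 1)
  expect_equal(s$area, 1000 * s$concentration)
  expect_equal(fit_linearity(s)$r_squared, 1.0)

  s8 <- generate_calibration_series(n_replicates = 3, noise_cv = 5, seed = 2)
  expect_equal(nrow(s8), 24)
  # per-level replicate CV stays well under 15% across 20 seeds
  cvs <- unlist(lapply(1:20, function(sd) {
    s <- generate_calibration_series(noise_cv = 5, seed = sd)
    s <- s[s$concentration > 0, ]
    tapply(s$area, s$concentration, compute_cv)
  }))
  expect_lt(mean(cvs), 15)
  expect_lt(stats::quantile(cvs, 0.95), 15)

  expect_error(generate_calibration_series(levels = 5), "3 distinct")
  expect_error(generate_calibration_series(levels = c(-1, 0, 1)), "non-negative")
})

test_that("normalized SRM ratios show validation-stage dispersion (SD/mean ~ 0.3-0.5)", {
  # raw-ratio CV compounded with total-protein variability must land in the
  # within-group spread characteristic of protein-normalized ratio tables
  cvs <- unlist(lapply(1:5, function(s) {
    cfg <- simulation_config(n_per_group = c(PD = 46, MSA = 17), n_peptides = 5,
                             seed = s)
    co <- generate_cohort(cfg)
    q <- srm_quantify(co$srm_report, co$metadata)$quant
    q <- q[!q$is_qc_pool, ]
    g <- co$group_of[q$sample_id]
    sapply(split(q$normalized_ratio[g == "PD"], q$peptide_id[g == "PD"]),
           function(v) stats::sd(v) / mean(v))
  }))
  expect_gt(mean(cvs), 0.3)
  expect_lt(mean(cvs), 0.5)
})

test_that("replicate set generator matches its target CV", {
  expect_equal(generate_replicate_set(2.5, 5, 0), rep(2.5, 5))
  v <- generate_replicate_set(1, 1000, 10, seed = 4)
  expect_gt(compute_cv(v), 8.5)
  expect_lt(compute_cv(v), 11.5)
  expect_error(generate_replicate_set(1, 1, 10), "n must be >= 2")
})
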