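# Synthetic cohort generation --------------------------------------------
#
# Emulates the statistical structure of a two-stage CSF tryptic-peptide
# biomarker study: log-normal discovery intensities with planted group fold
# changes, a Gaussian-copula age effect, left-censored missingness, an SRM
# transition-level report with heavy-label spike-ins and per-batch pooled QC
# samples, and clinical/biochemical sample metadata.

.valid_groups <- c("control", "PD", "MSA", "PSP")

#' Describe a planted group effect
#'
#' A planted effect multiplies (direction `"up"`) or divides (`"down"`) the
#' expected level of one peptide in one diagnosis group by `fold_change`.
#' The group `"AP"` is shorthand for both atypical-parkinsonism groups
#' (MSA and PSP).
#'
#' @param peptide_id peptide identifier (must exist in the generated panel)
#' @param group one of `"control"`, `"PD"`, `"MSA"`, `"PSP"`, `"AP"`
#' @param fold_change multiplicative effect size, `>= 1`
#' @param direction `"up"` or `"down"`
#' @return a `planted_effect` list
#' @export
planted_effect <- function(peptide_id, group, fold_change, direction = c("down", "up")) {
  direction <- match.arg(direction)
  if (!is.numeric(fold_change) || length(fold_change) != 1L || fold_change < 1)
    stop("planted_effect: fold_change must be a single number >= 1")
  if (!group %in% c(.valid_groups, "AP"))
    stop("planted_effect: unknown group '", group, "'")
  structure(list(peptide_id = as.character(peptide_id), group = group,
                 fold_change = fold_change, direction = direction),
            class = "planted_effect")
}

#' Simulation configuration for a synthetic CSF cohort
#'
#' Defaults reproduce the validation-cohort design: group sizes 39/46/17/8
#' (control/PD/MSA/PSP), total CSF protein means 426/533/511/724 mg/L with
#' the PSP group elevated, and heavily right-skewed discovery intensities
#' (log-normal, `sigma_log = 0.8`, coefficient of variation near 1). The
#' SRM endogenous/heavy ratios carry their own biological dispersion
#' (`srm_cv_biological`, default 30%), chosen so that the
#' protein-normalized ratios — raw-ratio dispersion compounded with
#' total-protein variability — show within-group SD/mean near 0.4, the
#' spread typical of validation-stage ratio data.
#'
#' @param n_per_group named integer vector of samples per diagnosis group;
#'   names from `control`, `PD`, `MSA`, `PSP`; every generated group needs
#'   at least 2 samples
#' @param n_peptides number of peptides in the panel
#' @param peptide_ids optional explicit peptide identifiers
#' @param age_mean,age_sd cohort age distribution in years
#' @param planted_effects list of [planted_effect()] records
#' @param age_rho named vector of target Spearman correlations between
#'   peptide level and age (peptides not named get 0); attainable to about
#'   +/- 0.15 at moderate sample size
#' @param sigma_log log-scale SD of discovery intensities
#' @param missing_censor_quantile left-censoring fraction in `[0, 1)`:
#'   values below this pooled per-peptide quantile become missing
#' @param cv_technical technical replicate noise, percent
#' @param total_protein_mean,total_protein_sd per-group total CSF protein,
#'   mg/L
#' @param n_batches number of digestion batches
#' @param srm_cv_biological biological CV (%) of SRM endogenous/heavy ratios
#' @param batch_effect_cv between-batch multiplicative drift CV (%) applied
#'   to SRM areas; 0 disables batch effects
#' @param marker_shift standardized log-scale shift planted in CSF NfL for
#'   the AP groups (0 = null cohort)
#' @param seed integer seed; a fixed seed gives a bit-identical cohort
#' @return a validated `simulation_config` list
#' @export
simulation_config <- function(n_per_group = c(control = 39, PD = 46, MSA = 17, PSP = 8),
                              n_peptides = 32,
                              peptide_ids = NULL,
                              age_mean = 60, age_sd = 10,
                              planted_effects = list(),
                              age_rho = NULL,
                              sigma_log = 0.8,
                              missing_censor_quantile = 0,
                              cv_technical = 5,
                              total_protein_mean = c(control = 426, PD = 533, MSA = 511, PSP = 724),
                              total_protein_sd = c(control = 211, PD = 165, MSA = 158, PSP = 366),
                              n_batches = 4,
                              srm_cv_biological = 30,
                              batch_effect_cv = 0,
                              marker_shift = 0,
                              seed = 1L) {
  if (is.null(names(n_per_group)) || !all(names(n_per_group) %in% .valid_groups))
    stop("simulation_config: n_per_group must be named with groups among ",
         paste(.valid_groups, collapse = ", "))
  if (any(n_per_group < 2))
    stop("simulation_config: n_per_group requires at least 2 samples per generated group")
  if (n_peptides < 1) stop("simulation_config: n_peptides must be >= 1")
  if (is.null(peptide_ids))
    peptide_ids <- sprintf("P%0*d", max(2L, nchar(as.character(n_peptides))),
                           seq_len(n_peptides))
  if (anyDuplicated(peptide_ids)) stop("simulation_config: peptide_ids must be unique")
  if (age_sd <= 0 || age_mean <= 0) stop("simulation_config: age_mean/age_sd must be positive")
  if (!is.list(planted_effects) ||
      !all(vapply(planted_effects, inherits, logical(1), "planted_effect")))
    stop("simulation_config: planted_effects must be a list of planted_effect() records")
  for (pe in planted_effects)
    if (!pe$peptide_id %in% peptide_ids)
      stop("simulation_config: planted_effects names unknown peptide '", pe$peptide_id, "'")
  rho <- stats::setNames(rep(0, length(peptide_ids)), peptide_ids)
  if (!is.null(age_rho)) {
    if (is.null(names(age_rho)) || !all(names(age_rho) %in% peptide_ids))
      stop("simulation_config: age_rho must be named by peptide_ids")
    if (any(abs(age_rho) >= 1)) stop("simulation_config: age_rho must lie in (-1, 1)")
    rho[names(age_rho)] <- age_rho
  }
  if (sigma_log <= 0) stop("simulation_config: sigma_log must be positive")
  if (missing_censor_quantile < 0 || missing_censor_quantile >= 1)
    stop("simulation_config: missing_censor_quantile must lie in [0, 1)")
  if (cv_technical < 0) stop("simulation_config: cv_technical must be >= 0")
  grp <- names(n_per_group)
  if (!all(grp %in% names(total_protein_mean)) || !all(grp %in% names(total_protein_sd)))
    stop("simulation_config: total_protein_mean/sd must cover every generated group")
  if (any(total_protein_mean[grp] <= 0)) stop("simulation_config: total_protein_mean must be positive")
  if (n_batches < 1) stop("simulation_config: n_batches must be >= 1")
  if (srm_cv_biological < 0) stop("simulation_config: srm_cv_biological must be >= 0")
  if (batch_effect_cv < 0) stop("simulation_config: batch_effect_cv must be >= 0")
  seed <- as.integer(seed)
  if (is.na(seed)) stop("simulation_config: seed must be an integer")
  structure(list(n_per_group = n_per_group, n_peptides = length(peptide_ids),
                 peptide_ids = peptide_ids, age_mean = age_mean, age_sd = age_sd,
                 planted_effects = planted_effects, age_rho = rho,
                 sigma_log = sigma_log,
                 missing_censor_quantile = missing_censor_quantile,
                 cv_technical = cv_technical,
                 total_protein_mean = total_protein_mean,
                 total_protein_sd = total_protein_sd,
                 n_batches = n_batches, srm_cv_biological = srm_cv_biological,
                 batch_effect_cv = batch_effect_cv, marker_shift = marker_shift,
                 seed = seed),
            class = "simulation_config")
}

# one RNG stream per logical block, derived from the main seed, so adding
# peptides or samples to one block never perturbs draws in another
.block_seed <- function(seed, block) {
  as.integer((as.numeric(seed) %% 1000003) * 131 + block) %% 2147483647L
}

.cv_to_sdlog <- function(cv_percent) sqrt(log(1 + (cv_percent / 100)^2))

# mean-one multiplicative log-normal noise at a given CV%
.mult_noise <- function(n, cv_percent) {
  if (cv_percent <= 0) return(rep(1, n))
  s <- .cv_to_sdlog(cv_percent)
  exp(stats::rnorm(n, -s^2 / 2, s))
}

# expand "AP" planted-effect records into MSA + PSP
.expand_effects <- function(effects) {
  out <- list()
  for (pe in effects) {
    gs <- if (pe$group == "AP") c("MSA", "PSP") else pe$group
    for (g in gs) out[[length(out) + 1L]] <-
        list(peptide_id = pe$peptide_id, group = g,
             fold_change = pe$fold_change, direction = pe$direction)
  }
  out
}

# random tryptic-like peptide sequence: body from the 20-letter alphabet,
# C-terminal K or R
.random_sequence <- function(len) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  paste0(paste(sample(aa, len - 1L, replace = TRUE), collapse = ""),
         sample(c("K", "R"), 1L))
}

#' Generate a synthetic CSF biomarker cohort
#'
#' Draws sample metadata (age, sex, total protein, digestion batch, clinical
#' scores, biochemical markers), a discovery-stage peptide intensity matrix,
#' peptide annotations, and an SRM transition-level report, together with a
#' truth record of what was planted.
#'
#' Intensities are log-normal per peptide. The age association is induced by
#' a Gaussian-copula latent factor: for target Spearman correlation
#' `rho_s`, the latent Pearson correlation is `2*sin(pi*rho_s/6)`, exact for
#' a bivariate normal copula. Planted fold changes multiply or divide the
#' affected group. Left-censoring replaces values below the per-peptide
#' pooled quantile with `NA` (an explicit missing marker, not zero).
#'
#' @param config a [simulation_config()]
#' @return a `synthetic_cohort` list with elements `metadata` (data frame),
#'   `discovery_matrix` (peptides x samples, `NA` = below detection limit),
#'   `group_of` (named sample-to-group vector), `annotations`,
#'   `srm_report`, and `truth`
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "simulation_config"))
    stop("generate_cohort: config must come from simulation_config()")
  groups <- rep(names(config$n_per_group), config$n_per_group)
  n <- length(groups)
  sample_ids <- sprintf("S%03d", seq_len(n))
  peps <- config$peptide_ids
  p <- length(peps)

  # -- ages, sex, protein, batches ---------------------------------------
  set.seed(.block_seed(config$seed, 1L))
  age <- pmax(30, stats::rnorm(n, config$age_mean, config$age_sd))
  sex <- sample(c("M", "F"), n, replace = TRUE)
  # log-normal with the stated group mean/SD: a concentration is positive
  # and right-skewed, and this avoids unstable 1/protein tails
  tp_mean <- config$total_protein_mean[groups]
  tp_sd <- config$total_protein_sd[groups]
  tp_sdlog <- sqrt(log(1 + (tp_sd / tp_mean)^2))
  total_protein <- stats::rlnorm(n, log(tp_mean) - tp_sdlog^2 / 2, tp_sdlog)
  batch_id <- sample(rep_len(seq_len(config$n_batches), n))

  # -- discovery intensities --------------------------------------------
  set.seed(.block_seed(config$seed, 2L))
  mu <- stats::runif(p, log(1e5), log(1e7))
  z_age <- (age - config$age_mean) / config$age_sd
  r_lat <- 2 * sin(pi * config$age_rho[peps] / 6)  # copula calibration
  eps <- matrix(stats::rnorm(p * n), nrow = p)
  z <- r_lat * matrix(z_age, nrow = p, ncol = n, byrow = TRUE) +
    sqrt(1 - r_lat^2) * eps
  mult <- matrix(1, nrow = p, ncol = n, dimnames = list(peps, sample_ids))
  for (pe in .expand_effects(config$planted_effects)) {
    f <- if (pe$direction == "up") pe$fold_change else 1 / pe$fold_change
    mult[pe$peptide_id, groups == pe$group] <-
      mult[pe$peptide_id, groups == pe$group] * f
  }
  tech <- matrix(.mult_noise(p * n, config$cv_technical), nrow = p)
  values <- exp(mu + config$sigma_log * z) * mult * tech
  dimnames(values) <- list(peps, sample_ids)

  # -- left-censoring ----------------------------------------------------
  precensor <- values
  censor_threshold <- stats::setNames(rep(-Inf, p), peps)
  if (config$missing_censor_quantile > 0) {
    censor_threshold <- apply(values, 1, stats::quantile,
                              probs = config$missing_censor_quantile, names = FALSE)
    values[values < censor_threshold[row(values)]] <- NA_real_
  }

  # -- peptide annotations ----------------------------------------------
  set.seed(.block_seed(config$seed, 3L))
  annotations <- data.frame(
    peptide_id = peps,
    sequence = vapply(sample(6:25, p, replace = TRUE), .random_sequence, character(1)),
    protein_name = sprintf("Protein_%s", peps),
    is_unique = stats::runif(p) < 0.8,
    in_knowledge_base = stats::runif(p) < 0.9,
    stringsAsFactors = FALSE)

  # -- SRM transition report --------------------------------------------
  set.seed(.block_seed(config$seed, 4L))
  base_ratio <- exp(stats::runif(p, log(0.03), log(3)))
  names(base_ratio) <- peps
  s_bio <- .cv_to_sdlog(config$srm_cv_biological)
  ratio_true <- base_ratio * mult *
    matrix(exp(stats::rnorm(p * n, -s_bio^2 / 2, s_bio)), nrow = p)
  batch_factor <- if (config$batch_effect_cv > 0)
    .mult_noise(config$n_batches, config$batch_effect_cv) else rep(1, config$n_batches)
  trans_w <- matrix(stats::runif(p * 3, 0.5, 1.5), nrow = p)
  trans_w <- trans_w / rowSums(trans_w)
  heavy_base <- 1e5

  qc_per_batch <- 2L
  qc_ids <- as.vector(outer(seq_len(qc_per_batch), seq_len(config$n_batches),
                            function(i, b) sprintf("QC_B%d_%d", b, i)))
  qc_batch <- rep(seq_len(config$n_batches), each = qc_per_batch)

  all_ids <- c(sample_ids, qc_ids)
  all_batch <- c(batch_id, qc_batch)
  all_qc <- c(rep(FALSE, n), rep(TRUE, length(qc_ids)))
  n_all <- length(all_ids)
  ratio_all <- cbind(ratio_true,
                     matrix(base_ratio, nrow = p, ncol = length(qc_ids)))
  rows <- p * n_all * 3L
  srm <- data.frame(
    sample_id = rep(all_ids, each = p * 3L),
    peptide_id = rep(rep(peps, each = 3L), times = n_all),
    transition_id = rep(sprintf("y%d", 3:5), times = p * n_all),
    batch_id = rep(all_batch, each = p * 3L),
    is_qc_pool = rep(all_qc, each = p * 3L),
    stringsAsFactors = FALSE)
  w_vec <- rep(as.vector(t(trans_w)), times = n_all)
  ratio_vec <- rep(as.vector(ratio_all), each = 3L)
  bf_vec <- batch_factor[srm$batch_id]
  heavy_area <- heavy_base * w_vec * .mult_noise(rows, config$cv_technical)
  endo_area <- heavy_base * w_vec * ratio_vec * bf_vec *
    .mult_noise(rows, config$cv_technical)
  srm <- rbind(
    cbind(srm, data.frame(label = "endogenous", area = endo_area,
                          stringsAsFactors = FALSE)),
    cbind(srm, data.frame(label = "heavy", area = heavy_area,
                          stringsAsFactors = FALSE)))
  srm <- srm[order(srm$sample_id, srm$peptide_id, srm$transition_id, srm$label), ]
  rownames(srm) <- NULL

  # -- clinical scores and biochemical markers ---------------------------
  set.seed(.block_seed(config$seed, 5L))
  clin <- .clinical_params()
  draw_clin <- function(par) {
    v <- rep(NA_real_, n)
    for (g in setdiff(unique(groups), "control")) {
      i <- groups == g
      v[i] <- pmax(par$min, pmin(par$max, stats::rnorm(sum(i), par[[g]][1], par[[g]][2])))
    }
    v
  }
  updrs <- draw_clin(clin$updrs); icars <- draw_clin(clin$icars)
  mmse <- draw_clin(clin$mmse); hy <- draw_clin(clin$hy)
  disease_duration <- ifelse(groups == "control", NA_real_,
                             pmax(3, stats::rnorm(n, 35, 25)))
  ap <- groups %in% c("MSA", "PSP")
  nfl <- exp(stats::rnorm(n, log(800), 0.5) + ifelse(ap, config$marker_shift * 0.5, 0))
  alpha_syn <- exp(stats::rnorm(n, log(1500), 0.4))
  t_tau <- exp(stats::rnorm(n, log(200), 0.4))
  p_tau <- exp(stats::rnorm(n, log(40), 0.35))
  abeta42 <- exp(stats::rnorm(n, log(800), 0.3))
  rt_quic <- as.integer(stats::runif(n) <
                          c(control = 0.05, PD = 0.9, MSA = 0.75, PSP = 0.1)[groups])

  metadata <- data.frame(
    sample_id = sample_ids, group = groups, age = age, sex = sex,
    disease_duration = disease_duration, total_protein = total_protein,
    batch_id = batch_id, UPDRS = updrs, ICARS = icars, MMSE = mmse,
    hoehn_yahr = hy, NfL = nfl, alpha_syn = alpha_syn, t_tau = t_tau,
    p_tau = p_tau, abeta42 = abeta42, rt_quic = rt_quic,
    stringsAsFactors = FALSE)

  truth <- list(planted_effects = config$planted_effects,
                age_rho = config$age_rho,
                precensor_matrix = precensor,
                censor_threshold = censor_threshold,
                srm_base_ratio = base_ratio,
                marker_shift = config$marker_shift)

  structure(list(metadata = metadata, discovery_matrix = values,
                 group_of = stats::setNames(groups, sample_ids),
                 annotations = annotations, srm_report = srm, truth = truth,
                 config = config),
            class = "synthetic_cohort")
}

# group-wise clinical score parameters (mean, sd) with plausible ranges
.clinical_params <- function() {
  list(updrs = list(PD = c(27.3, 12.7), MSA = c(30.2, 11.2), PSP = c(35.3, 14.6),
                    min = 0, max = 108),
       icars = list(PD = c(2.8, 3.2), MSA = c(9.5, 11.1), PSP = c(10.7, 7.4),
                    min = 0, max = 100),
       mmse = list(PD = c(28.3, 2.1), MSA = c(27.9, 2.5), PSP = c(26.0, 3.0),
                   min = 0, max = 30),
       hy = list(PD = c(2.0, 0.7), MSA = c(2.5, 0.8), PSP = c(2.7, 0.8),
                 min = 1, max = 5))
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("synthetic_cohort:", nrow(x$metadata), "samples (",
      paste(sprintf("%s=%d", names(table(x$group_of)), table(x$group_of)),
            collapse = ", "), "),",
      nrow(x$discovery_matrix), "peptides,",
      length(x$truth$planted_effects), "planted effects\n")
  invisible(x)
}

#' Generate a calibration dilution series
#'
#' Simulates peak areas for a heavy-peptide dilution series (default the
#' 8-level series 0-40 fmol in three replicates) with multiplicative noise
#' of the stated CV, for exercising the linearity criterion.
#'
#' @param levels concentrations in fmol; at least 3 distinct non-negative
#'   levels are required (fewer cannot support a linearity fit)
#' @param n_replicates replicate injections per level
#' @param noise_cv multiplicative noise CV, percent
#' @param seed integer seed
#' @param slope area per fmol
#' @param peptide_id identifier attached to the series
#' @return data frame with columns `peptide_id`, `concentration`,
#'   `replicate`, `area`
#' @export
generate_calibration_series <- function(levels = c(0, 0.625, 1.25, 2.5, 5, 10, 20, 40),
                                        n_replicates = 3, noise_cv = 5, seed = 1L,
                                        slope = 1000, peptide_id = "PEP") {
  if (any(levels < 0)) stop("generate_calibration_series: levels must be non-negative")
  if (length(unique(levels)) < 3)
    stop("generate_calibration_series: need at least 3 distinct levels to fit linearity")
  if (n_replicates < 1) stop("generate_calibration_series: n_replicates must be >= 1")
  if (noise_cv < 0) stop("generate_calibration_series: noise_cv must be >= 0")
  set.seed(as.integer(seed))
  conc <- rep(levels, each = n_replicates)
  data.frame(peptide_id = peptide_id, concentration = conc,
             replicate = rep(seq_len(n_replicates), times = length(levels)),
             area = slope * conc * .mult_noise(length(conc), noise_cv),
             stringsAsFactors = FALSE)
}

#' Generate a technical replicate set
#'
#' Simulates repeated measurements of one quantity (e.g. five same-day
#' injections of a pooled digest) with a target coefficient of variation.
#'
#' @param true_value underlying value
#' @param n number of replicates, `>= 2`
#' @param cv_target expected CV, percent
#' @param seed integer seed
#' @return numeric vector of length `n`
#' @export
generate_replicate_set <- function(true_value, n, cv_target, seed = 1L) {
  if (n < 2) stop("generate_replicate_set: n must be >= 2")
  if (cv_target < 0) stop("generate_replicate_set: cv_target must be >= 0")
  set.seed(as.integer(seed))
  true_value * .mult_noise(n, cv_target)
}
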