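# Pipeline orchestration ---------------------------------------------------
#
# Chains simulate -> discover -> srm-qc -> srm-quant -> stats -> model over
# a run directory, writing each stage's tables plus a machine-readable
# manifest (seed, thresholds, input digests) that fully determines the run.

#' Pipeline configuration
#'
#' Documented defaults: p cutoff 0.05, fold-ratio cutoff 1.5, detection
#' fraction 0.75, maximum peptide length 20, linearity R^2 minimum 0.7,
#' CV maximum 20%, training fraction 0.7.
#'
#' @param p_cutoff,ratio_cutoff,detection_fraction,max_length discovery
#'   selection thresholds
#' @param r2_min,cv_max assay-validation thresholds
#' @param protein_scale normalization divisor (mg/L per unit)
#' @param batch_correct apply pooled-QC batch correction
#' @param split_fraction,n_trees,datasets model-suite settings
#' @param seed integer seed for the whole run
#' @param simulation a [simulation_config()] (used by the simulate stage)
#' @return a `pipeline_config` list
#' @export
pipeline_config <- function(p_cutoff = 0.05, ratio_cutoff = 1.5,
                            detection_fraction = 0.75, max_length = 20,
                            r2_min = 0.7, cv_max = 20, protein_scale = 1000,
                            batch_correct = FALSE, split_fraction = 0.7,
                            n_trees = 500, datasets = 1:4, seed = 1L,
                            simulation = NULL) {
  if (p_cutoff <= 0 || p_cutoff > 1) stop("pipeline_config: p_cutoff in (0, 1] required")
  if (ratio_cutoff < 1) stop("pipeline_config: ratio_cutoff must be >= 1")
  if (detection_fraction <= 0 || detection_fraction > 1)
    stop("pipeline_config: detection_fraction in (0, 1] required")
  if (max_length < 1) stop("pipeline_config: max_length must be >= 1")
  if (r2_min < 0 || r2_min > 1) stop("pipeline_config: r2_min in [0, 1] required")
  if (cv_max <= 0) stop("pipeline_config: cv_max must be positive")
  if (split_fraction <= 0 || split_fraction >= 1)
    stop("pipeline_config: split_fraction in (0, 1) required")
  if (is.null(simulation)) simulation <- simulation_config(seed = seed)
  structure(list(p_cutoff = p_cutoff, ratio_cutoff = ratio_cutoff,
                 detection_fraction = detection_fraction, max_length = max_length,
                 r2_min = r2_min, cv_max = cv_max, protein_scale = protein_scale,
                 batch_correct = batch_correct, split_fraction = split_fraction,
                 n_trees = n_trees, datasets = datasets, seed = as.integer(seed),
                 simulation = simulation),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Scalar threshold fields override [pipeline_config()] defaults; the
#' round trip through [write_pipeline_config()] is lossless for them.
#'
#' @param path YAML file
#' @return a `pipeline_config`
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- c("p_cutoff", "ratio_cutoff", "detection_fraction", "max_length",
             "r2_min", "cv_max", "protein_scale", "batch_correct",
             "split_fraction", "n_trees", "datasets", "seed")
  do.call(pipeline_config, y[intersect(names(y), known)])
}

#' Write a pipeline configuration to YAML
#' @param config a `pipeline_config`
#' @param path output path
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(config[setdiff(names(config), "simulation")], path)
  invisible(path)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full pipeline on a simulated cohort
#'
#' Stage order mirrors the study workflow: simulate the cohort, run the
#' discovery screen and candidate selection, validate the SRM assay
#' (calibration linearity plus CV criteria on simulated QC sets), quantify
#' the SRM report, compute the per-peptide statistics table, and fit the
#' model suite. Each stage writes its outputs under `outdir`; a manifest
#' JSON records the seed, thresholds and md5 digests of every artifact, so
#' equal manifests imply byte-identical tables.
#'
#' @param config a [pipeline_config()]
#' @param outdir run directory (created if needed)
#' @return invisibly, the manifest list
#' @export
run_pipeline <- function(config, outdir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package_version = as.character(utils::packageVersion("srmpipe")),
                   seed = config$seed,
                   thresholds = config[c("p_cutoff", "ratio_cutoff",
                                         "detection_fraction", "max_length",
                                         "r2_min", "cv_max", "protein_scale",
                                         "split_fraction")],
                   stages = character(0), outputs = list())
  add_output <- function(manifest, path) {
    manifest$outputs[[basename(path)]] <- unname(tools::md5sum(path))
    manifest
  }

  # 1 simulate
  cohort <- .stage("simulate", generate_cohort(config$simulation))
  paths <- .stage("simulate", write_cohort(cohort, file.path(outdir, "inputs")))
  for (p in paths) manifest <- add_output(manifest, p)
  manifest$stages <- c(manifest$stages, "simulate")

  # 2 discover
  diff <- .stage("discover", differential_test(cohort$discovery_matrix,
                                               cohort$group_of))
  cand <- .stage("discover", select_candidates(
    diff, cohort$annotations, cohort$discovery_matrix, cohort$group_of,
    p_cutoff = config$p_cutoff, ratio_cutoff = config$ratio_cutoff,
    detection_fraction = config$detection_fraction,
    max_length = config$max_length))
  p1 <- write_result_table(diff, file.path(outdir, "differential.tsv"))
  p2 <- write_result_table(cand, file.path(outdir, "candidates.tsv"))
  manifest <- add_output(add_output(manifest, p1), p2)
  manifest$stages <- c(manifest$stages, "discover")
  message("discover: ", nrow(diff), " peptides screened, ",
          sum(cand$selected, na.rm = TRUE), " selected")

  # 3 srm-qc (assay validation on simulated QC sets)
  val <- .stage("srm-qc", {
    peps <- utils::head(rownames(cohort$discovery_matrix), 4)
    cal <- do.call(rbind, lapply(seq_along(peps), function(i)
      generate_calibration_series(seed = config$seed + i, noise_cv = 5,
                                  peptide_id = peps[i])))
    reps <- do.call(rbind, lapply(seq_along(peps), function(i) {
      do.call(rbind, lapply(c("INTRA_ASSAY", "INTER_ASSAY", "PREP",
                              "AUTOSAMPLER", "FREEZE_THAW_DIGESTED",
                              "FREEZE_THAW_PREDIGEST"), function(cr) {
        n <- .criterion_designs[[cr]]$n
        if (cr == "FREEZE_THAW_DIGESTED") n <- 5L
        if (cr == "FREEZE_THAW_PREDIGEST") n <- 3L
        data.frame(criterion_id = cr, peptide_id = peps[i],
                   axis_index = seq_len(n),
                   value = generate_replicate_set(1, n, cv_target = 8,
                                                  seed = config$seed + 97L + i),
                   stringsAsFactors = FALSE)
      }))
    }))
    validate_assay(list(calibration = cal, replicates = reps),
                   r2_min = config$r2_min, cv_max = config$cv_max)
  })
  p3 <- write_result_table(val$criteria, file.path(outdir, "assay_validation.tsv"))
  jsonlite::write_json(val$peptides, file.path(outdir, "assay_validation.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest <- add_output(add_output(manifest, p3),
                         file.path(outdir, "assay_validation.json"))
  manifest$stages <- c(manifest$stages, "srm-qc")

  # 4 srm-quant
  sq <- .stage("srm-quant", srm_quantify(cohort$srm_report, cohort$metadata,
                                         protein_scale = config$protein_scale,
                                         batch_correct = config$batch_correct))
  p4 <- write_result_table(sq$quant, file.path(outdir, "srm_quant.tsv"))
  jsonlite::write_json(sq$qc$summary, file.path(outdir, "batch_qc.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest <- add_output(add_output(manifest, p4), file.path(outdir, "batch_qc.json"))
  manifest$stages <- c(manifest$stages, "srm-quant")

  # 5 stats
  stats_tab <- .stage("stats", peptide_group_stats(sq$quant, cohort$metadata))
  p5 <- write_result_table(stats_tab, file.path(outdir, "group_statistics.tsv"))
  manifest <- add_output(manifest, p5)
  manifest$stages <- c(manifest$stages, "stats")

  # 6 model
  suite <- .stage("model", {
    ft <- build_feature_table(cohort)
    run_model_suite(ft$features, ft$labels, ft$families,
                    datasets = config$datasets, seed = config$seed,
                    n_trees = config$n_trees,
                    split_fraction = config$split_fraction)
  })
  p6 <- write_result_table(suite$comparison, file.path(outdir, "model_comparison.tsv"))
  manifest <- add_output(manifest, p6)
  manifest$stages <- c(manifest$stages, "model")

  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
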