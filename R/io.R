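# Tabular IO ---------------------------------------------------------------
#
# Readers/writers for the pipeline's standard formats: intensity-matrix TSV,
# sample-metadata CSV, Skyline-style transition-report CSV (with column
# aliases) and annotation CSV. Missing markers "", "NA", "NaN" are read as
# NA and written as "NA"; TSV for matrices/results, CSV for metadata and
# transition reports; UTF-8, decimal point ".".

.na_markers <- c("", "NA", "NaN")

# Skyline export dialect -> canonical column names
.transition_aliases <- c(
  PeptideSequence = "peptide_id", PeptideModifiedSequence = "peptide_id",
  ReplicateName = "sample_id", FragmentIon = "transition_id",
  IsotopeLabelType = "label", Area = "area", RetentionTime = "retention_time",
  peptide = "peptide_id", sample = "sample_id", transition = "transition_id",
  rt = "retention_time", batch = "batch_id", qc_pool = "is_qc_pool")

.group_aliases <- c(HC = "control", CTRL = "control", Control = "control",
                    CON = "control")

.apply_aliases <- function(nms, aliases) {
  hit <- nms %in% names(aliases)
  nms[hit] <- aliases[nms[hit]]
  nms
}

#' Read a peptide intensity matrix (TSV)
#'
#' First column = peptide id, remaining columns = samples; `""`, `"NA"`
#' and `"NaN"` cells are missing. Negative intensities are rejected with
#' the offending coordinates.
#'
#' @param path TSV file
#' @return numeric matrix, peptides x samples
#' @export
read_intensity_matrix <- function(path) {
  if (!file.exists(path)) stop("read_intensity_matrix: no such file: ", path)
  d <- utils::read.delim(path, check.names = FALSE, na.strings = .na_markers,
                         stringsAsFactors = FALSE)
  if (ncol(d) < 2) stop("read_intensity_matrix: need peptide column plus samples")
  if (anyDuplicated(d[[1]]))
    stop("read_intensity_matrix: duplicate peptide id(s): ",
         paste(unique(d[[1]][duplicated(d[[1]])]), collapse = ", "))
  m <- as.matrix(d[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("read_intensity_matrix: non-numeric intensity cells")
  rownames(m) <- d[[1]]
  neg <- which(m < 0, arr.ind = TRUE)
  if (nrow(neg))
    stop("read_intensity_matrix: negative intensity at peptide ",
         rownames(m)[neg[1, 1]], ", sample ", colnames(m)[neg[1, 2]])
  m
}

#' Write a peptide intensity matrix (TSV)
#' @param m peptides x samples matrix
#' @param path output path
#' @export
write_intensity_matrix <- function(m, path) {
  d <- data.frame(peptide_id = rownames(m), m, check.names = FALSE,
                  stringsAsFactors = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Read sample metadata (CSV)
#'
#' Validates unique sample ids, positive ages, positive total protein when
#' present, and the group vocabulary (`control`, `PD`, `MSA`, `PSP`;
#' configurable aliases such as `HC` are mapped).
#'
#' @param path CSV file
#' @param group_aliases named map of accepted alternative group labels
#' @return data frame
#' @export
read_sample_metadata <- function(path, group_aliases = .group_aliases) {
  if (!file.exists(path)) stop("read_sample_metadata: no such file: ", path)
  d <- utils::read.csv(path, na.strings = .na_markers, stringsAsFactors = FALSE)
  need <- c("sample_id", "group", "age")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("read_sample_metadata: missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(d$sample_id))
    stop("read_sample_metadata: duplicate sample_id at row ",
         which(duplicated(d$sample_id))[1])
  hit <- d$group %in% names(group_aliases)
  d$group[hit] <- group_aliases[d$group[hit]]
  bad <- !d$group %in% .valid_groups
  if (any(bad))
    stop("read_sample_metadata: unknown group '", d$group[which(bad)[1]],
         "' at row ", which(bad)[1])
  bad_age <- !is.na(d$age) & d$age <= 0
  if (any(bad_age))
    stop("read_sample_metadata: non-positive age at row ", which(bad_age)[1],
         " (sample ", d$sample_id[which(bad_age)[1]], ")")
  if ("total_protein" %in% names(d)) {
    bad_tp <- !is.na(d$total_protein) & d$total_protein <= 0
    if (any(bad_tp))
      stop("read_sample_metadata: non-positive total_protein at row ",
           which(bad_tp)[1])
  }
  d
}

#' Write sample metadata (CSV)
#' @param metadata data frame
#' @param path output path
#' @export
write_sample_metadata <- function(metadata, path) {
  utils::write.csv(metadata, path, row.names = FALSE, na = "NA", quote = FALSE)
  invisible(path)
}

#' Read a transition-level SRM report (CSV)
#'
#' Accepts both the pipeline's canonical header (`sample_id`, `peptide_id`,
#' `transition_id`, `label`, `area`, `batch_id`, `is_qc_pool`) and common
#' Skyline export aliases (`ReplicateName`, `PeptideSequence`,
#' `FragmentIon`, `IsotopeLabelType`, `Area`). Label `light` is read as
#' endogenous.
#'
#' @param path CSV file
#' @return data frame with canonical columns
#' @export
read_transition_report <- function(path) {
  if (!file.exists(path)) stop("read_transition_report: no such file: ", path)
  d <- utils::read.csv(path, na.strings = .na_markers, stringsAsFactors = FALSE)
  names(d) <- .apply_aliases(names(d), .transition_aliases)
  need <- c("sample_id", "peptide_id", "transition_id", "label", "area")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("read_transition_report: missing column(s): ",
         paste(miss, collapse = ", "))
  d$label <- .normalize_label(d$label)
  if (any(!is.na(d$area) & d$area < 0))
    stop("read_transition_report: negative area at row ",
         which(!is.na(d$area) & d$area < 0)[1])
  if ("is_qc_pool" %in% names(d)) {
    d$is_qc_pool <- d$is_qc_pool %in% c(TRUE, "TRUE", "true", 1, "1")
  }
  d
}

#' Write a transition-level SRM report (CSV)
#' @param report data frame
#' @param path output path
#' @export
write_transition_report <- function(report, path) {
  utils::write.csv(report, path, row.names = FALSE, na = "NA", quote = FALSE)
  invisible(path)
}

#' Read peptide annotations (CSV)
#'
#' Columns: `peptide` (or `peptide_id`), `sequence`, `protein`
#' (or `protein_name`), `unique` (or `is_unique`, 0/1), `knowledge_base`
#' (or `in_knowledge_base`, 0/1).
#'
#' @param path CSV file
#' @return data frame with canonical columns
#' @export
read_peptide_annotations <- function(path) {
  if (!file.exists(path)) stop("read_peptide_annotations: no such file: ", path)
  d <- utils::read.csv(path, na.strings = .na_markers, stringsAsFactors = FALSE)
  ali <- c(peptide = "peptide_id", protein = "protein_name",
           unique = "is_unique", knowledge_base = "in_knowledge_base")
  names(d) <- .apply_aliases(names(d), ali)
  need <- c("peptide_id", "sequence", "is_unique", "in_knowledge_base")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("read_peptide_annotations: missing column(s): ",
         paste(miss, collapse = ", "))
  d$is_unique <- as.logical(d$is_unique)
  d$in_knowledge_base <- as.logical(d$in_knowledge_base)
  d
}

#' Write a generic result table (TSV)
#' @param d data frame
#' @param path output path
#' @export
write_result_table <- function(d, path) {
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Read a result table written by [write_result_table()]
#' @param path TSV file
#' @return data frame
#' @export
read_result_table <- function(path) {
  utils::read.delim(path, na.strings = .na_markers, stringsAsFactors = FALSE,
                    check.names = FALSE)
}

#' Write a synthetic cohort to a directory
#'
#' Emits the three standard pipeline inputs (intensity-matrix TSV,
#' metadata CSV, transition-report CSV), the annotation CSV and a truth
#' JSON recording the planted effects.
#'
#' @param cohort a [generate_cohort()] result
#' @param outdir directory (created if needed)
#' @return invisibly, the named vector of written paths
#' @export
write_cohort <- function(cohort, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(matrix = file.path(outdir, "discovery_matrix.tsv"),
             metadata = file.path(outdir, "metadata.csv"),
             srm = file.path(outdir, "srm_report.csv"),
             annotations = file.path(outdir, "annotations.csv"),
             truth = file.path(outdir, "truth.json"))
  write_intensity_matrix(cohort$discovery_matrix, paths["matrix"])
  write_sample_metadata(cohort$metadata, paths["metadata"])
  write_transition_report(cohort$srm_report, paths["srm"])
  utils::write.csv(cohort$annotations, paths["annotations"], row.names = FALSE,
                   na = "NA", quote = FALSE)
  truth <- list(planted_effects = lapply(cohort$truth$planted_effects,
                                         function(pe) pe[c("peptide_id", "group",
                                                           "fold_change", "direction")]),
                age_rho = as.list(cohort$truth$age_rho),
                marker_shift = cohort$truth$marker_shift,
                seed = cohort$config$seed)
  jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
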