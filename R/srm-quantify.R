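# SRM relative quantification ---------------------------------------------
#
# Transition-level peak areas -> per-sample peptide relative quantities:
# sum transitions per (sample, peptide, label), form the endogenous/heavy
# ratio, normalize by total CSF protein, and monitor (or optionally
# correct) digestion-batch drift with pooled QC samples.

# Skyline-dialect label normalization: endogenous == "light"
.normalize_label <- function(label) {
  l <- tolower(as.character(label))
  out <- ifelse(l %in% c("endogenous", "light", "endo"), "endogenous",
                ifelse(l %in% c("heavy"), "heavy", NA_character_))
  if (anyNA(out))
    stop("unknown isotope label(s): ", paste(unique(label[is.na(out)]), collapse = ", "))
  out
}

#' Aggregate transition areas to peptide level
#'
#' Sums peak areas over the available transitions per (sample, peptide,
#' label). Peptides quantified from fewer than `min_transitions` transitions
#' are flagged `low_evidence` (flagged, never dropped). A mean-based
#' aggregation mode is available.
#'
#' @param report transition-level data frame with columns `sample_id`,
#'   `peptide_id`, `transition_id`, `label` (`endogenous`/`light` or
#'   `heavy`), `area` and optionally `batch_id`, `is_qc_pool`
#' @param min_transitions evidence threshold (default 2, the assay design
#'   minimum)
#' @param method `"sum"` (standard SRM practice) or `"mean"`
#' @return data frame with one row per (sample, peptide, label): `area`,
#'   `n_transitions`, `low_evidence`, carrying `batch_id`/`is_qc_pool`
#'   through when present
#' @export
aggregate_transitions <- function(report, min_transitions = 2, method = c("sum", "mean")) {
  method <- match.arg(method)
  need <- c("sample_id", "peptide_id", "transition_id", "label", "area")
  if (!all(need %in% names(report)))
    stop("aggregate_transitions: report must have columns ",
         paste(need, collapse = ", "))
  if (any(report$area < 0, na.rm = TRUE))
    stop("aggregate_transitions: negative peak areas are invalid")
  lab <- .normalize_label(report$label)
  key <- paste(report$sample_id, report$peptide_id, lab, sep = "\r")
  if (anyDuplicated(paste(key, report$transition_id, sep = "\r")))
    stop("aggregate_transitions: duplicate (sample, peptide, transition, label) rows")
  fun <- if (method == "sum") sum else mean
  area <- tapply(report$area, key, fun)
  n_trans <- tapply(report$area, key, length)
  first <- !duplicated(key)
  idx <- match(names(area), key[first])
  out <- data.frame(sample_id = report$sample_id[first][idx],
                    peptide_id = report$peptide_id[first][idx],
                    label = lab[first][idx],
                    area = as.numeric(area),
                    n_transitions = as.integer(n_trans),
                    stringsAsFactors = FALSE)
  out$low_evidence <- out$n_transitions < min_transitions
  for (extra in c("batch_id", "is_qc_pool"))
    if (extra %in% names(report)) out[[extra]] <- report[[extra]][first][idx]
  rownames(out) <- NULL
  out[order(out$sample_id, out$peptide_id, out$label), ]
}

#' Endogenous/heavy peak-area ratio
#'
#' Relative quantification of one peptide in one sample: the summed
#' endogenous area divided by the summed heavy-standard area. A heavy area
#' of zero means the internal standard was not detected, so no ratio can be
#' formed: the result is `NA` with reason `HEAVY_UNDETECTED` (mirroring the
#' exclusion of peptides whose heavy standards cannot be robustly
#' detected).
#'
#' @param endo_area,heavy_area non-negative summed areas (vectorized)
#' @return numeric ratio(s); `NA` where the heavy standard is undetected,
#'   with a `reason` attribute vector
#' @export
compute_ratio <- function(endo_area, heavy_area) {
  if (any(endo_area < 0, na.rm = TRUE) || any(heavy_area < 0, na.rm = TRUE))
    stop("compute_ratio: areas must be non-negative")
  undet <- is.na(heavy_area) | heavy_area == 0
  ratio <- ifelse(undet, NA_real_, endo_area / heavy_area)
  attr(ratio, "reason") <- ifelse(undet, "HEAVY_UNDETECTED", NA_character_)
  ratio
}

#' Normalize a peptide ratio by total CSF protein
#'
#' Divides the endogenous/heavy ratio by the sample's total CSF protein
#' concentration expressed in g/L (`mg/L / protein_scale`). The scale
#' constant is configurable; the default of 1000 keeps normalized ratios
#' on the order of the raw ratios for typical CSF protein (~0.4-0.7 g/L).
#'
#' @param ratio endogenous/heavy ratio(s)
#' @param total_protein_mg_L positive total protein, mg/L
#' @param protein_scale divisor converting mg/L to the normalization unit
#' @return normalized ratio(s)
#' @export
normalize_ratio <- function(ratio, total_protein_mg_L, protein_scale = 1000) {
  if (any(!is.finite(total_protein_mg_L)) || any(total_protein_mg_L <= 0))
    stop("normalize_ratio: total_protein_mg_L must be positive")
  if (protein_scale <= 0) stop("normalize_ratio: protein_scale must be positive")
  ratio / (total_protein_mg_L / protein_scale)
}

#' Pooled-QC batch monitoring and optional correction
#'
#' The assay design places pooled CSF QC samples in every digestion batch.
#' `monitor` mode reports, per peptide, the QC-pool mean ratio of each
#' batch and the CV of those batch means, leaving the data untouched.
#' `correct` mode additionally multiplies every ratio in a batch by
#' (grand QC mean / batch QC mean), equalizing QC means across batches;
#' the correction is idempotent.
#'
#' @param ratios data frame with `sample_id`, `peptide_id`, `ratio`,
#'   `batch_id`, `is_qc_pool`
#' @param mode `"monitor"` (default; the correction formula is a package
#'   choice, so it is opt-in) or `"correct"`
#' @return list with `ratios` (input plus `corrected_ratio`), `summary`
#'   (per peptide x batch QC mean and correction factor) and `cv` (per
#'   peptide across-batch QC CV, %)
#' @export
batch_qc_correct <- function(ratios, mode = c("monitor", "correct")) {
  mode <- match.arg(mode)
  need <- c("sample_id", "peptide_id", "ratio", "batch_id", "is_qc_pool")
  if (!all(need %in% names(ratios)))
    stop("batch_qc_correct: ratios must have columns ", paste(need, collapse = ", "))
  peps <- unique(ratios$peptide_id)
  batches <- unique(ratios$batch_id)
  qc <- ratios[ratios$is_qc_pool & !is.na(ratios$ratio), ]
  summ <- expand.grid(peptide_id = peps, batch_id = batches,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  summ$qc_mean <- mapply(function(p, b) {
    v <- qc$ratio[qc$peptide_id == p & qc$batch_id == b]
    if (length(v)) mean(v) else NA_real_
  }, summ$peptide_id, summ$batch_id)
  if (mode == "correct") {
    missing_qc <- unique(summ$batch_id[is.na(summ$qc_mean) | summ$qc_mean <= 0])
    if (length(missing_qc))
      stop("batch_qc_correct: batches without usable QC pools in correct mode: ",
           paste(missing_qc, collapse = ", "))
  }
  grand <- tapply(summ$qc_mean, summ$peptide_id, mean, na.rm = TRUE)
  summ$correction_factor <- as.numeric(grand[summ$peptide_id]) / summ$qc_mean
  cv <- vapply(split(summ$qc_mean, summ$peptide_id), function(v) {
    v <- v[!is.na(v)]
    if (length(v) < 2 || mean(v) == 0) NA_real_ else 100 * stats::sd(v) / mean(v)
  }, numeric(1))
  out <- ratios
  if (mode == "correct") {
    f <- summ$correction_factor[match(paste(ratios$peptide_id, ratios$batch_id),
                                      paste(summ$peptide_id, summ$batch_id))]
    out$corrected_ratio <- ratios$ratio * f
  } else {
    out$corrected_ratio <- ratios$ratio
  }
  list(ratios = out, summary = summ,
       cv = data.frame(peptide_id = names(cv), cv_across_batches = as.numeric(cv),
                       row.names = NULL, stringsAsFactors = FALSE),
       mode = mode)
}

#' Full SRM quantification of a transition report
#'
#' Chains transition aggregation, ratio formation, total-protein
#' normalization and pooled-QC batch monitoring (correction optional).
#' QC-pool samples get ratios but no protein normalization (they carry no
#' clinical metadata).
#'
#' @param report transition-level data frame (see [aggregate_transitions()])
#' @param metadata sample metadata with `sample_id` and `total_protein`
#'   (mg/L)
#' @param min_transitions evidence threshold for `low_evidence` flags
#' @param protein_scale see [normalize_ratio()]
#' @param batch_correct apply the QC correction (default `FALSE`: monitor
#'   only)
#' @param method transition aggregation method
#' @return list with `quant` (per sample x peptide: `endo_area`,
#'   `heavy_area`, `ratio`, `reason`, `normalized_ratio`,
#'   `corrected_ratio`, flags) and `qc` (batch QC summary)
#' @export
srm_quantify <- function(report, metadata, min_transitions = 2,
                         protein_scale = 1000, batch_correct = FALSE,
                         method = c("sum", "mean")) {
  agg <- aggregate_transitions(report, min_transitions = min_transitions,
                               method = match.arg(method))
  endo <- agg[agg$label == "endogenous", ]
  heavy <- agg[agg$label == "heavy", ]
  key_e <- paste(endo$sample_id, endo$peptide_id)
  key_h <- paste(heavy$sample_id, heavy$peptide_id)
  idx <- match(key_e, key_h)
  quant <- data.frame(sample_id = endo$sample_id, peptide_id = endo$peptide_id,
                      endo_area = endo$area,
                      heavy_area = heavy$area[idx],
                      stringsAsFactors = FALSE)
  quant$heavy_area[is.na(quant$heavy_area)] <- 0
  r <- compute_ratio(quant$endo_area, quant$heavy_area)
  quant$ratio <- as.numeric(r)
  quant$reason <- attr(r, "reason")
  quant$low_evidence <- endo$low_evidence | heavy$low_evidence[idx]
  if ("batch_id" %in% names(endo)) quant$batch_id <- endo$batch_id
  quant$is_qc_pool <- if ("is_qc_pool" %in% names(endo)) endo$is_qc_pool else FALSE
  qc_res <- NULL
  if ("batch_id" %in% names(quant) && any(quant$is_qc_pool)) {
    qc_res <- batch_qc_correct(quant[, c("sample_id", "peptide_id", "ratio",
                                         "batch_id", "is_qc_pool")],
                               mode = if (batch_correct) "correct" else "monitor")
    quant$corrected_ratio <- qc_res$ratios$corrected_ratio
  } else {
    if (batch_correct)
      stop("srm_quantify: batch_correct requires batch_id and QC-pool samples")
    quant$corrected_ratio <- quant$ratio
  }
  tp <- metadata$total_protein[match(quant$sample_id, metadata$sample_id)]
  quant$total_protein <- tp
  ok <- !is.na(tp)
  if (any(!is.na(tp) & tp <= 0))
    stop("srm_quantify: non-positive total_protein in metadata")
  quant$normalized_ratio <- NA_real_
  quant$normalized_ratio[ok] <- normalize_ratio(quant$corrected_ratio[ok], tp[ok],
                                                protein_scale)
  list(quant = quant, qc = qc_res)
}
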