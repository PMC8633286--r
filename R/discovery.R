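# Discovery-stage screen and SRM candidate selection ----------------------
#
# Shotgun-stage detection filter, PD-vs-MSA differential screen and the
# seven-criterion selection of peptides suitable for SRM assay development:
# (1) Mann-Whitney p < 0.05, (2) fold ratio >= 1.5, (3) detection in >= 75%
# of samples in both compared groups, (4) length <= 20 residues,
# (5) protein-unique, (6) present in a knowledge base, (7) free of sequence
# liabilities (Met/Cys oxidation, NG deamidation motif, N-terminal Q/E
# pyroglutamate formation).

.aa_alphabet <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# "intensity above the detection limit": NA is missing and, following the
# MaxQuant convention, a numeric zero is treated as below the limit too
.detected <- function(values, zero_as_missing = TRUE) {
  d <- !is.na(values)
  if (zero_as_missing) d & values > 0 else d
}

#' Detection-fraction filter
#'
#' Keeps peptides observed (non-missing intensity) in at least
#' `min_fraction` of the samples of one listed group (`scope =
#' "one_group"`, the shotgun-stage rule) or of every listed group
#' (`scope = "both_groups"`, selection criterion 3). Fractions are compared
#' with `>=` on exact counts.
#'
#' @param values peptides x samples intensity matrix, `NA` = missing
#' @param group_of named character vector mapping sample id to group
#' @param min_fraction required detection fraction in `(0, 1]`
#' @param scope `"one_group"` or `"both_groups"`
#' @param groups groups the rule applies to (default: all groups present)
#' @param zero_as_missing treat numeric zero as below the detection limit
#' @return character vector of retained peptide ids
#' @export
filter_detection <- function(values, group_of, min_fraction = 0.75,
                             scope = c("one_group", "both_groups"),
                             groups = NULL, zero_as_missing = TRUE) {
  scope <- match.arg(scope)
  stopifnot(is.matrix(values), !is.null(rownames(values)))
  if (min_fraction <= 0 || min_fraction > 1)
    stop("filter_detection: min_fraction must lie in (0, 1]")
  g <- group_of[colnames(values)]
  if (anyNA(g)) stop("filter_detection: every sample needs a group label")
  if (is.null(groups)) groups <- unique(g)
  frac <- sapply(groups, function(grp) {
    cols <- which(g == grp)
    if (length(cols) == 0) stop("filter_detection: group '", grp, "' is empty")
    rowMeans(.detected(values[, cols, drop = FALSE], zero_as_missing))
  })
  frac <- matrix(frac, nrow = nrow(values), dimnames = list(rownames(values), groups))
  keep <- if (scope == "one_group") apply(frac >= min_fraction, 1, any)
          else apply(frac >= min_fraction, 1, all)
  rownames(values)[keep]
}

#' Direction-agnostic fold ratio of two group means
#'
#' `max(a, b) / min(a, b)`, always `>= 1`. The discovery screen reports the
#' magnitude of the group difference regardless of direction, so a peptide
#' elevated in MSA and one elevated in PD are treated symmetrically.
#'
#' @param mean_a,mean_b positive group means (vectorized)
#' @return fold ratio(s) `>= 1`
#' @export
fold_ratio <- function(mean_a, mean_b) {
  if (any(!is.finite(mean_a)) || any(!is.finite(mean_b)) ||
      any(mean_a <= 0) || any(mean_b <= 0))
    stop("fold_ratio: group means must be positive and finite")
  pmax(mean_a, mean_b) / pmin(mean_a, mean_b)
}

#' Per-peptide differential screen between two groups
#'
#' Two-sided Mann-Whitney test (exact for small tie-free samples, normal
#' approximation with tie and continuity correction otherwise) plus group
#' means/SDs of the non-missing values and the direction-agnostic fold
#' ratio. Peptides with fewer than 2 non-missing values in either group are
#' flagged `untestable` and carry no p-value rather than a fabricated one.
#'
#' @param values peptides x samples intensity matrix
#' @param group_of named sample-to-group vector
#' @param group_a,group_b groups to compare (defaults PD vs MSA)
#' @param zero_as_missing treat numeric zero as missing
#' @param report_groups extra groups whose mean/SD are reported (default:
#'   `control` when present)
#' @return data frame with one row per peptide: means, SDs, `p_value`,
#'   `fold_ratio`, `untestable`
#' @export
differential_test <- function(values, group_of, group_a = "PD", group_b = "MSA",
                              zero_as_missing = TRUE, report_groups = NULL) {
  stopifnot(is.matrix(values), !is.null(rownames(values)))
  g <- group_of[colnames(values)]
  if (!all(c(group_a, group_b) %in% g))
    stop("differential_test: groups '", group_a, "'/'", group_b, "' must be present")
  if (is.null(report_groups)) report_groups <- intersect("control", g)
  v <- values
  if (zero_as_missing) v[!is.na(v) & v == 0] <- NA_real_
  grp_stats <- function(grp) {
    sub <- v[, g == grp, drop = FALSE]
    list(mean = rowMeans(sub, na.rm = TRUE),
         sd = apply(sub, 1, stats::sd, na.rm = TRUE),
         n = rowSums(!is.na(sub)))
  }
  sa <- grp_stats(group_a); sb <- grp_stats(group_b)
  out <- data.frame(peptide_id = rownames(v), stringsAsFactors = FALSE)
  for (grp in report_groups) {
    s <- grp_stats(grp)
    out[[paste0("mean_", grp)]] <- s$mean
    out[[paste0("sd_", grp)]] <- s$sd
  }
  out[[paste0("mean_", group_a)]] <- sa$mean
  out[[paste0("sd_", group_a)]] <- sa$sd
  out[[paste0("mean_", group_b)]] <- sb$mean
  out[[paste0("sd_", group_b)]] <- sb$sd
  out$untestable <- sa$n < 2 | sb$n < 2
  out$p_value <- NA_real_
  out$fold_ratio <- ifelse(!out$untestable & sa$mean > 0 & sb$mean > 0,
                           pmax(sa$mean, sb$mean) / pmin(sa$mean, sb$mean),
                           NA_real_)
  for (i in which(!out$untestable)) {
    a <- v[i, g == group_a]; b <- v[i, g == group_b]
    out$p_value[i] <- mann_whitney(a[!is.na(a)], b[!is.na(b)])$p_value
  }
  out
}

#' Sequence-liability check for SRM suitability
#'
#' Flags residues and motifs prone to chemical or post-translational
#' modification that destabilize SRM quantification: methionine (`MET`) and
#' cysteine (`CYS`) oxidation, the Asn-Gly deamidation motif
#' (`DEAMIDATION_MOTIF`), and N-terminal Gln/Glu pyroglutamate cyclization
#' (`NTERM_CYCLIZATION`). An empty result means the sequence is clean.
#'
#' @param sequence uppercase amino-acid string over the standard 20 letters
#' @return character vector of liability codes (possibly empty)
#' @export
sequence_liability_check <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1L || nchar(sequence) == 0)
    stop("sequence_liability_check: sequence must be a non-empty string")
  chars <- strsplit(sequence, "")[[1]]
  bad <- setdiff(chars, .aa_alphabet)
  if (length(bad))
    stop("sequence_liability_check: invalid residue(s): ", paste(bad, collapse = ", "))
  codes <- character(0)
  if ("M" %in% chars) codes <- c(codes, "MET")
  if ("C" %in% chars) codes <- c(codes, "CYS")
  if (grepl("NG", sequence, fixed = TRUE)) codes <- c(codes, "DEAMIDATION_MOTIF")
  if (chars[1] %in% c("Q", "E")) codes <- c(codes, "NTERM_CYCLIZATION")
  codes
}

#' Seven-criterion SRM candidate selection
#'
#' Applies the full candidate rule set to a differential screen: (c1)
#' p-value below `p_cutoff`; (c2) fold ratio at least `ratio_cutoff`; (c3)
#' detection in at least `detection_fraction` of samples in both compared
#' groups; (c4) sequence length at most `max_length`; (c5) unique protein
#' assignment; (c6) knowledge-base presence; (c7) no sequence liabilities.
#' A peptide is selected iff all seven hold. Peptides lacking an annotation
#' get an error entry (`error` column) and the run continues.
#'
#' @param differentials output of [differential_test()]
#' @param annotations data frame with `peptide_id`, `sequence`,
#'   `is_unique`, `in_knowledge_base`
#' @param values the intensity matrix (for the detection criterion)
#' @param group_of named sample-to-group vector
#' @param group_a,group_b the compared groups (both must meet detection)
#' @param p_cutoff,ratio_cutoff,detection_fraction,max_length thresholds
#' @param zero_as_missing treat numeric zero as missing
#' @return data frame with per-criterion booleans `c1_pvalue` ...
#'   `c7_liability`, `liability_reasons`, `selected`, `error`
#' @export
select_candidates <- function(differentials, annotations, values, group_of,
                              group_a = "PD", group_b = "MSA",
                              p_cutoff = 0.05, ratio_cutoff = 1.5,
                              detection_fraction = 0.75, max_length = 20,
                              zero_as_missing = TRUE) {
  stopifnot(is.data.frame(differentials), "peptide_id" %in% names(differentials))
  detected <- filter_detection(values, group_of, min_fraction = detection_fraction,
                               scope = "both_groups", groups = c(group_a, group_b),
                               zero_as_missing = zero_as_missing)
  ann <- annotations[match(differentials$peptide_id, annotations$peptide_id), ]
  n <- nrow(differentials)
  out <- data.frame(peptide_id = differentials$peptide_id,
                    c1_pvalue = NA, c2_ratio = NA, c3_detection = NA,
                    c4_length = NA, c5_unique = NA, c6_knowledge_base = NA,
                    c7_liability = NA, liability_reasons = "",
                    selected = NA, error = NA_character_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    if (is.na(ann$peptide_id[i])) {
      out$error[i] <- "missing annotation"
      next
    }
    chk <- tryCatch(list(ok = TRUE, codes = sequence_liability_check(ann$sequence[i])),
                    error = function(e) list(ok = FALSE, msg = conditionMessage(e)))
    if (!chk$ok) {
      out$error[i] <- chk$msg
      next
    }
    liab <- chk$codes
    out$c1_pvalue[i] <- !is.na(differentials$p_value[i]) &&
      differentials$p_value[i] < p_cutoff
    out$c2_ratio[i] <- !is.na(differentials$fold_ratio[i]) &&
      differentials$fold_ratio[i] >= ratio_cutoff
    out$c3_detection[i] <- out$peptide_id[i] %in% detected
    out$c4_length[i] <- nchar(ann$sequence[i]) <= max_length
    out$c5_unique[i] <- isTRUE(as.logical(ann$is_unique[i]))
    out$c6_knowledge_base[i] <- isTRUE(as.logical(ann$in_knowledge_base[i]))
    out$c7_liability[i] <- length(liab) == 0
    out$liability_reasons[i] <- paste(liab, collapse = ",")
    out$selected[i] <- all(out$c1_pvalue[i], out$c2_ratio[i], out$c3_detection[i],
                           out$c4_length[i], out$c5_unique[i],
                           out$c6_knowledge_base[i], out$c7_liability[i])
  }
  out
}
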