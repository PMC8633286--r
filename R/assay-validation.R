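# SRM assay validation -----------------------------------------------------
#
# Calibration linearity (ordinary least squares of area on concentration,
# exclusion below R^2 = 0.7) and the six CV-based criteria of the
# method-validation framework, each accepted at 20% variation between
# technical replicates. Thresholds are boundary-inclusive (R^2 = 0.7 and
# CV = 20.0% pass); a strict mode is available.

.criterion_designs <- list(
  INTRA_ASSAY = list(n = 5L, exact = TRUE,
                     design = "5 injections of one pooled digest on the same day"),
  INTER_ASSAY = list(n = 10L, exact = TRUE,
                     design = "1 digested sample measured on 10 different days"),
  PREP = list(n = 5L, exact = TRUE,
              design = "5 identical aliquots digested and measured the same day"),
  AUTOSAMPLER = list(n = 7L, exact = TRUE,
                     design = "repeated injection every 4 h for 24 h (7 time points)"),
  FREEZE_THAW_DIGESTED = list(n = 2L, exact = FALSE,
                              design = "up to 5 freeze/thaw cycles of a digested pool"),
  FREEZE_THAW_PREDIGEST = list(n = 2L, exact = FALSE,
                               design = "3 freeze/thaw cycles prior to digestion"))

#' Coefficient of variation (%)
#'
#' `100 * sd / mean` with the sample (n-1) standard deviation; a
#' population-SD mode is available behind `sd_type`.
#'
#' @param values at least 2 numeric values with non-zero mean
#' @param sd_type `"sample"` (default) or `"population"`
#' @return CV in percent
#' @export
compute_cv <- function(values, sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  values <- values[!is.na(values)]
  if (length(values) < 2) stop("compute_cv: need at least 2 values")
  m <- mean(values)
  if (m == 0) stop("compute_cv: mean is zero, CV undefined")
  s <- stats::sd(values)
  if (sd_type == "population") s <- s * sqrt((length(values) - 1) / length(values))
  100 * s / m
}

#' Calibration-curve linearity
#'
#' Ordinary least squares of peak area on spiked concentration over all
#' replicate points (zero-concentration points included; they are part of
#' the dilution series). R^2 is the squared Pearson correlation; the
#' criterion passes at `R^2 >= r2_min` (default 0.7, the exclusion
#' threshold for peptide fragments).
#'
#' @param series data frame with `concentration` and `area` (one row per
#'   replicate point); at least 3 distinct concentrations
#' @param r2_min acceptance threshold
#' @param strict use `>` instead of `>=` at the boundary
#' @return list with `slope`, `intercept`, `r_squared`, `pass`
#' @export
fit_linearity <- function(series, r2_min = 0.7, strict = FALSE) {
  if (!all(c("concentration", "area") %in% names(series)))
    stop("fit_linearity: series needs columns concentration, area")
  ok <- stats::complete.cases(series[, c("concentration", "area")])
  series <- series[ok, ]
  if (length(unique(series$concentration)) < 3)
    stop("fit_linearity: need at least 3 distinct concentrations")
  fit <- stats::lm(area ~ concentration, data = series)
  r2 <- suppressWarnings(stats::cor(series$concentration, series$area))^2
  if (is.na(r2)) r2 <- 0  # flat response: no linear signal
  list(slope = unname(stats::coef(fit)[2]), intercept = unname(stats::coef(fit)[1]),
       r_squared = r2,
       pass = if (strict) r2 > r2_min else r2 >= r2_min)
}

#' Evaluate one CV-based validation criterion
#'
#' Computes the CV across the criterion's replicate axis (same-day
#' injections, measurement days, preparation aliquots, autosampler time
#' points, or freeze/thaw cycles) and accepts at `cv_max` (default 20%,
#' boundary-inclusive).
#'
#' @param values replicate measurements along the criterion's axis
#' @param criterion_id one of `INTRA_ASSAY`, `INTER_ASSAY`, `PREP`,
#'   `AUTOSAMPLER`, `FREEZE_THAW_DIGESTED`, `FREEZE_THAW_PREDIGEST`
#' @param cv_max acceptance threshold, percent
#' @param strict use `<` instead of `<=` at the boundary
#' @param sd_type passed to [compute_cv()]
#' @return data frame row: `criterion_id`, `metric_name`, `value`,
#'   `threshold`, `pass`
#' @export
evaluate_criterion <- function(values, criterion_id, cv_max = 20,
                               strict = FALSE, sd_type = "sample") {
  if (!criterion_id %in% names(.criterion_designs))
    stop("evaluate_criterion: unknown criterion '", criterion_id, "'; expected one of ",
         paste(names(.criterion_designs), collapse = ", "))
  des <- .criterion_designs[[criterion_id]]
  values <- values[!is.na(values)]
  if ((des$exact && length(values) != des$n) ||
      (!des$exact && length(values) < des$n))
    stop("evaluate_criterion: ", criterion_id, " expects ",
         if (des$exact) "" else "at least ", des$n,
         " replicate values (design: ", des$design, "), got ", length(values))
  cv <- compute_cv(values, sd_type = sd_type)
  data.frame(criterion_id = criterion_id, metric_name = "CV%", value = cv,
             threshold = cv_max,
             pass = if (strict) cv < cv_max else cv <= cv_max,
             stringsAsFactors = FALSE)
}

#' Validate the full SRM assay for a set of peptides
#'
#' Applies the linearity criterion to each peptide's calibration series and
#' every supplied CV criterion, then reports per-peptide results and an
#' overall pass (the conjunction of all evaluated criteria). Peptides
#' failing linearity are marked `excluded`, mirroring the R^2 < 0.7
#' fragment exclusion; other peptides are unaffected.
#'
#' @param bundle list with `calibration` (data frame: `peptide_id`,
#'   `concentration`, `replicate`, `area`; optional) and `replicates`
#'   (data frame: `criterion_id`, `peptide_id`, `axis_index`, `value`;
#'   optional); at least one criterion per peptide must be present
#' @param r2_min,cv_max,strict thresholds (see [fit_linearity()],
#'   [evaluate_criterion()])
#' @return list with `criteria` (flat per-peptide criterion table),
#'   `peptides` (per-peptide `overall_pass` and `excluded`)
#' @export
validate_assay <- function(bundle, r2_min = 0.7, cv_max = 20, strict = FALSE) {
  cal <- bundle$calibration
  reps <- bundle$replicates
  if ((is.null(cal) || nrow(cal) == 0) && (is.null(reps) || nrow(reps) == 0))
    stop("validate_assay: empty bundle, nothing to validate")
  rows <- list()
  if (!is.null(cal) && nrow(cal)) {
    for (p in unique(cal$peptide_id)) {
      fit <- fit_linearity(cal[cal$peptide_id == p, ], r2_min = r2_min, strict = strict)
      rows[[length(rows) + 1L]] <-
        data.frame(peptide_id = p, criterion_id = "LINEARITY",
                   metric_name = "R2", value = fit$r_squared, threshold = r2_min,
                   pass = fit$pass, stringsAsFactors = FALSE)
    }
  }
  if (!is.null(reps) && nrow(reps)) {
    keys <- unique(reps[, c("peptide_id", "criterion_id")])
    for (i in seq_len(nrow(keys))) {
      sel <- reps$peptide_id == keys$peptide_id[i] &
        reps$criterion_id == keys$criterion_id[i]
      res <- evaluate_criterion(reps$value[sel], keys$criterion_id[i],
                                cv_max = cv_max, strict = strict)
      rows[[length(rows) + 1L]] <- cbind(peptide_id = keys$peptide_id[i], res)
    }
  }
  criteria <- do.call(rbind, rows)
  rownames(criteria) <- NULL
  per_pep <- vapply(split(criteria, criteria$peptide_id),
                    function(d) all(d$pass), logical(1))
  excluded <- vapply(split(criteria, criteria$peptide_id),
                     function(d) any(d$criterion_id == "LINEARITY" & !d$pass),
                     logical(1))
  list(criteria = criteria,
       peptides = data.frame(peptide_id = names(per_pep),
                             overall_pass = as.logical(per_pep),
                             excluded = as.logical(excluded),
                             row.names = NULL, stringsAsFactors = FALSE))
}
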