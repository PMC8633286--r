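# Random-forest discrimination models --------------------------------------
#
# PD-vs-AP discrimination from combinations of feature families (tryptic
# peptide quantities, biochemical CSF markers, clinical assessments, age):
# expectation-maximization imputation under a multivariate-normal working
# model (with bootstrap multiple imputation), a stratified 70/30 split, a
# random-forest classifier, and held-out AUC. Imputation parameters are
# fitted on the training fold only and applied to the test fold.

# -- EM for multivariate normal with missing values ------------------------

#' Fit an EM imputation model
#'
#' Estimates the mean vector and covariance matrix of a multivariate-normal
#' working model from incompletely observed rows by
#' expectation-maximization, with a small ridge on the covariance diagonal
#' for numerical stability.
#'
#' @param x numeric matrix or data frame (rows = samples)
#' @param max_iter,tol EM iteration controls
#' @param ridge diagonal regularization added to the covariance
#' @return list with `mu`, `sigma`, `iterations`, `converged`
#' @export
fit_imputer <- function(x, max_iter = 100, tol = 1e-5, ridge = 1e-6) {
  x <- as.matrix(x)
  if (!is.numeric(x)) stop("fit_imputer: features must be numeric")
  p <- ncol(x); n <- nrow(x)
  all_missing <- colSums(!is.na(x)) == 0
  if (any(all_missing))
    stop("fit_imputer: feature(s) fully missing: ",
         paste(colnames(x)[all_missing], collapse = ", "))
  mu <- colMeans(x, na.rm = TRUE)
  v <- apply(x, 2, stats::var, na.rm = TRUE)
  v[is.na(v) | v == 0] <- 1
  sigma <- diag(v, p)
  scale_ridge <- ridge * mean(diag(sigma))
  miss <- is.na(x)
  if (!any(miss))
    return(list(mu = mu, sigma = stats::cov(x) + diag(scale_ridge, p),
                iterations = 0L, converged = TRUE))
  pattern <- apply(miss, 1, function(m) paste(which(m), collapse = ","))
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    filled <- x
    cond_acc <- matrix(0, p, p)
    for (pat in unique(pattern)) {
      rows <- which(pattern == pat)
      if (pat == "") next
      mi <- as.integer(strsplit(pat, ",")[[1]])
      oi <- setdiff(seq_len(p), mi)
      if (length(oi) == 0) {
        filled[rows, ] <- matrix(mu, length(rows), p, byrow = TRUE)
        cond_acc[mi, mi] <- cond_acc[mi, mi] + length(rows) * sigma[mi, mi]
        next
      }
      soo_inv <- solve(sigma[oi, oi, drop = FALSE] + diag(scale_ridge, length(oi)))
      beta <- sigma[mi, oi, drop = FALSE] %*% soo_inv
      resid_o <- sweep(x[rows, oi, drop = FALSE], 2, mu[oi])
      filled[rows, mi] <- matrix(mu[mi], length(rows), length(mi), byrow = TRUE) +
        resid_o %*% t(beta)
      cond_cov <- sigma[mi, mi, drop = FALSE] -
        beta %*% sigma[oi, mi, drop = FALSE]
      cond_acc[mi, mi] <- cond_acc[mi, mi] + length(rows) * cond_cov
    }
    mu_new <- colMeans(filled)
    xc <- sweep(filled, 2, mu_new)
    sigma_new <- (crossprod(xc) + cond_acc) / n + diag(scale_ridge, p)
    delta <- max(abs(mu_new - mu), abs(sigma_new - sigma))
    mu <- mu_new; sigma <- sigma_new
    if (delta < tol * (1 + max(abs(mu)))) { converged <- TRUE; break }
  }
  list(mu = mu, sigma = sigma, iterations = it, converged = converged)
}

#' Impute missing values with a fitted EM model
#'
#' Fills each missing cell with its conditional expectation given the
#' observed cells of the row; `noise = TRUE` adds a draw from the
#' conditional covariance (used for multiple imputation).
#'
#' @param model output of [fit_imputer()]
#' @param x matrix/data frame with the same columns the model was fitted on
#' @param noise add conditional-covariance noise
#' @return completed numeric matrix
#' @export
impute_with <- function(model, x, noise = FALSE) {
  x <- as.matrix(x)
  p <- ncol(x)
  miss <- is.na(x)
  if (!any(miss)) return(x)
  mu <- model$mu; sigma <- model$sigma
  for (i in which(rowSums(miss) > 0)) {
    mi <- which(miss[i, ]); oi <- setdiff(seq_len(p), mi)
    if (length(oi) == 0) {
      x[i, ] <- mu
      next
    }
    soo_inv <- solve(sigma[oi, oi, drop = FALSE])
    beta <- sigma[mi, oi, drop = FALSE] %*% soo_inv
    cm <- mu[mi] + as.numeric(beta %*% (x[i, oi] - mu[oi]))
    if (noise) {
      cc <- sigma[mi, mi, drop = FALSE] - beta %*% sigma[oi, mi, drop = FALSE]
      cc <- (cc + t(cc)) / 2
      ev <- eigen(cc, symmetric = TRUE)
      ev$values[ev$values < 0] <- 0
      cm <- cm + as.numeric(ev$vectors %*% (sqrt(ev$values) *
                                              stats::rnorm(length(mi))))
    }
    x[i, mi] <- cm
  }
  x
}

#' EM + bootstrap multiple imputation
#'
#' Single imputation (`n_imputations = 1`) fills conditional means from an
#' EM fit on the full table. Multiple imputation refits the EM model on a
#' bootstrap resample of the rows for each imputation and adds
#' conditional-covariance noise, propagating parameter uncertainty in the
#' style of bootstrap-EM imputation.
#'
#' @param x numeric matrix/data frame; labels must not be included
#' @param n_imputations number of completed tables
#' @param seed integer seed
#' @param ... passed to [fit_imputer()]
#' @return a completed matrix (`n_imputations = 1`) or list of matrices;
#'   attribute `n_imputed_cells` records how many cells were filled
#' @export
impute_missing <- function(x, n_imputations = 1, seed = 1L, ...) {
  x <- as.matrix(x)
  n_filled <- sum(is.na(x))
  if (n_filled == 0) {
    out <- if (n_imputations == 1) x else replicate(n_imputations, x,
                                                    simplify = FALSE)
    attr(out, "n_imputed_cells") <- 0L
    return(out)
  }
  set.seed(as.integer(seed))
  if (n_imputations == 1) {
    out <- impute_with(fit_imputer(x, ...), x, noise = FALSE)
  } else {
    out <- lapply(seq_len(n_imputations), function(m) {
      boot <- x[sample(nrow(x), nrow(x), replace = TRUE), , drop = FALSE]
      model <- tryCatch(fit_imputer(boot, ...),
                        error = function(e) fit_imputer(x, ...))
      impute_with(model, x, noise = TRUE)
    })
  }
  attr(out, "n_imputed_cells") <- n_filled
  out
}

#' Stratified 70/30 cohort split
#'
#' Deterministic per seed; preserves class proportions within rounding.
#' Both folds keep at least one sample of every class.
#'
#' @param labels class labels
#' @param fraction training fraction
#' @param seed integer seed
#' @param stratify split within class (default) or completely at random
#' @return list with integer index vectors `train` and `test`
#' @export
split_cohort <- function(labels, fraction = 0.7, seed = 1L, stratify = TRUE) {
  if (fraction <= 0 || fraction >= 1) stop("split_cohort: fraction must be in (0, 1)")
  labels <- as.character(labels)
  if (any(table(labels) < 2))
    stop("split_cohort: every class needs at least 2 samples")
  set.seed(as.integer(seed))
  train <- integer(0)
  if (stratify) {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      n_tr <- min(max(round(fraction * length(idx)), 1L), length(idx) - 1L)
      train <- c(train, sample(idx, n_tr))
    }
  } else {
    n_tr <- min(max(round(fraction * length(labels)), 1L), length(labels) - 1L)
    train <- sample(seq_along(labels), n_tr)
  }
  train <- sort(train)
  list(train = train, test = setdiff(seq_along(labels), train))
}

#' Fit and evaluate one discrimination model
#'
#' Imputes (training-fold fit only), splits 70/30, fits a random forest on
#' the training fold and reports the AUC of the held-out predicted
#' probabilities. Optional permutation-style feature retention keeps
#' training-fold features with importance above a quantile and refits.
#'
#' @param features samples x features numeric data frame/matrix (may
#'   contain `NA`)
#' @param labels binary class labels aligned with rows
#' @param positive label treated as positive for the AUC (default `"AP"`)
#' @param dataset_id optional identifier carried into the result
#' @param n_trees random-forest size (default 500)
#' @param split_fraction training fraction
#' @param seed integer seed controlling split, imputation and forest
#' @param n_imputations EM+bootstrap imputations; test predictions are
#'   averaged over imputations
#' @param select_features retain only high-importance features and refit
#' @param importance_quantile retention threshold quantile
#' @param split optional precomputed `list(train, test)` index split
#'   (overrides the internal stratified split)
#' @return list of class `srm_model_result`: `held_out_auc`, `importance`,
#'   `retained`, `train`/`test` indices, `n_imputed_cells`
#' @export
fit_and_evaluate <- function(features, labels, positive = "AP", dataset_id = NULL,
                             n_trees = 500, split_fraction = 0.7, seed = 1L,
                             n_imputations = 1, select_features = FALSE,
                             importance_quantile = 0.5, split = NULL) {
  x <- as.data.frame(features)
  if (!all(vapply(x, is.numeric, logical(1))))
    stop("fit_and_evaluate: all features must be numeric")
  labels <- factor(as.character(labels))
  if (nlevels(labels) != 2) stop("fit_and_evaluate: labels must be binary")
  if (!positive %in% levels(labels))
    stop("fit_and_evaluate: positive class '", positive, "' absent")
  fully_missing <- names(x)[colSums(!is.na(x)) == 0]
  if (length(fully_missing))
    stop("fit_and_evaluate: feature(s) fully missing: ",
         paste(fully_missing, collapse = ", "))
  sp <- if (is.null(split)) split_cohort(labels, fraction = split_fraction,
                                         seed = seed) else split
  if (length(unique(labels[sp$test])) < 2)
    stop("fit_and_evaluate: degenerate test fold (one class)")
  xm <- as.matrix(x)
  set.seed(as.integer(seed) + 1L)
  preds <- matrix(0, nrow = length(sp$test), ncol = n_imputations)
  retained <- colnames(xm)
  imp_out <- NULL
  n_imputed <- sum(is.na(xm))
  for (m in seq_len(n_imputations)) {
    train_x <- xm[sp$train, , drop = FALSE]
    if (anyNA(train_x)) {
      boot_idx <- if (n_imputations > 1)
        sample(nrow(train_x), nrow(train_x), replace = TRUE) else seq_len(nrow(train_x))
      model <- tryCatch(fit_imputer(train_x[boot_idx, , drop = FALSE]),
                        error = function(e) fit_imputer(train_x))
      train_imp <- impute_with(model, train_x, noise = n_imputations > 1)
      test_imp <- impute_with(model, xm[sp$test, , drop = FALSE],
                              noise = n_imputations > 1)
    } else {
      train_imp <- train_x
      test_imp <- xm[sp$test, , drop = FALSE]
      if (anyNA(test_imp)) {
        model <- fit_imputer(train_x)
        test_imp <- impute_with(model, test_imp, noise = n_imputations > 1)
      }
    }
    rf <- randomForest::randomForest(x = train_imp, y = droplevels(labels[sp$train]),
                                     ntree = n_trees)
    imp <- randomForest::importance(rf)[, 1]
    if (select_features) {
      keep <- names(imp)[imp >= stats::quantile(imp, importance_quantile)]
      if (length(keep) >= 1) {
        rf <- randomForest::randomForest(x = train_imp[, keep, drop = FALSE],
                                         y = droplevels(labels[sp$train]),
                                         ntree = n_trees)
        test_imp <- test_imp[, keep, drop = FALSE]
        retained <- keep
        imp <- randomForest::importance(rf)[, 1]
      }
    }
    imp_out <- imp
    preds[, m] <- stats::predict(rf, test_imp, type = "prob")[, positive]
  }
  score <- rowMeans(preds)
  auc <- roc_auc(score, labels[sp$test], positive_group = positive)$auc
  structure(list(dataset_id = dataset_id, train = sp$train, test = sp$test,
                 n_imputed_cells = n_imputed, held_out_auc = auc,
                 importance = imp_out, retained = retained,
                 positive = positive, seed = seed),
            class = "srm_model_result")
}

#' @export
print.srm_model_result <- function(x, ...) {
  cat("model", if (!is.null(x$dataset_id)) paste0("dataset ", x$dataset_id) else "",
      ": held-out AUC =", round(x$held_out_auc, 3),
      "(", length(x$train), "train /", length(x$test), "test,",
      x$n_imputed_cells, "imputed cells )\n")
  invisible(x)
}

# feature families of the four model datasets
.dataset_families <- list(`1` = c("peptides"),
                          `2` = c("peptides", "markers", "age"),
                          `3` = c("peptides", "markers", "clinical", "age"),
                          `4` = c("markers", "clinical", "age"))

#' Run the four-dataset model suite
#'
#' Dataset 1: the differential peptides alone. Dataset 2: peptides plus the
#' biochemical markers and age. Dataset 3: peptides, markers, clinical
#' scores and age. Dataset 4: markers and clinical scores (no peptides)
#' plus age. A dataset whose feature family is missing from the table
#' yields an error entry; the suite continues.
#'
#' @param features samples x features table
#' @param labels binary labels
#' @param families named list mapping family name (`peptides`, `markers`,
#'   `clinical`, `age`) to column names of `features`
#' @param datasets which of 1-4 to run
#' @param ... passed to [fit_and_evaluate()]
#' @return list with `results` (per dataset) and `comparison` data frame
#' @export
run_model_suite <- function(features, labels, families, datasets = 1:4, ...) {
  if (length(datasets) == 0) {
    warning("run_model_suite: empty dataset list")
    return(list(results = list(), comparison = data.frame()))
  }
  results <- list()
  for (d in datasets) {
    fam <- .dataset_families[[as.character(d)]]
    if (is.null(fam)) {
      results[[as.character(d)]] <- list(dataset_id = d, error = "unknown dataset id")
      next
    }
    missing_fam <- setdiff(fam, names(families))
    cols <- unlist(families[intersect(fam, names(families))], use.names = FALSE)
    missing_cols <- setdiff(cols, colnames(features))
    if (length(missing_fam) || length(missing_cols)) {
      results[[as.character(d)]] <- list(
        dataset_id = d,
        error = paste("missing feature family/columns:",
                      paste(c(missing_fam, missing_cols), collapse = ", ")))
      next
    }
    results[[as.character(d)]] <-
      fit_and_evaluate(features[, cols, drop = FALSE], labels,
                       dataset_id = d, ...)
  }
  comparison <- do.call(rbind, lapply(results, function(r) {
    data.frame(dataset_id = r$dataset_id,
               held_out_auc = if (is.null(r$error)) r$held_out_auc else NA_real_,
               n_features = if (is.null(r$error)) length(r$retained) else NA_integer_,
               error = if (is.null(r$error)) "" else r$error,
               stringsAsFactors = FALSE)
  }))
  rownames(comparison) <- NULL
  list(results = results, comparison = comparison)
}

#' Build the merged feature table of a synthetic cohort
#'
#' Runs SRM quantification on the cohort's transition report, pivots the
#' normalized ratios to samples x peptides, joins the biochemical markers,
#' clinical scores and age, and attaches the PD-vs-AP label (MSA and PSP
#' pooled as AP; controls dropped).
#'
#' @param cohort a [generate_cohort()] result
#' @param peptides which peptides to include (default: all)
#' @return list with `features` (data frame), `labels` (factor PD/AP) and
#'   `families` (column-name map for [run_model_suite()])
#' @export
build_feature_table <- function(cohort, peptides = NULL) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  sq <- srm_quantify(cohort$srm_report, cohort$metadata)
  q <- sq$quant[!sq$quant$is_qc_pool, ]
  if (is.null(peptides)) peptides <- unique(q$peptide_id)
  wide <- stats::reshape(q[q$peptide_id %in% peptides,
                           c("sample_id", "peptide_id", "normalized_ratio")],
                         idvar = "sample_id", timevar = "peptide_id",
                         direction = "wide")
  names(wide) <- sub("^normalized_ratio\\.", "", names(wide))
  md <- cohort$metadata
  keep <- md$group %in% c("PD", "MSA", "PSP")
  md <- md[keep, ]
  wide <- wide[match(md$sample_id, wide$sample_id), ]
  marker_cols <- c("NfL", "alpha_syn", "t_tau", "p_tau", "abeta42", "rt_quic")
  clinical_cols <- c("UPDRS", "ICARS", "MMSE", "hoehn_yahr")
  features <- cbind(wide[, peptides, drop = FALSE],
                    md[, marker_cols], md[, clinical_cols], age = md$age)
  rownames(features) <- md$sample_id
  labels <- factor(ifelse(md$group == "PD", "PD", "AP"), levels = c("PD", "AP"))
  list(features = features, labels = labels,
       families = list(peptides = peptides, markers = marker_cols,
                       clinical = clinical_cols, age = "age"))
}
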