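# Nonparametric statistical battery ---------------------------------------
#
# Mann-Whitney, Kruskal-Wallis with Dunn post hoc, Quade-style rank
# analysis of covariance with Bonferroni-adjusted pairwise comparisons,
# Spearman correlation, Pearson chi-squared and rank-formula ROC/AUC.
# Standard tests are delegated to base R engines (wilcox.test,
# kruskal.test, cor.test, chisq.test); the rank-ANCOVA and Dunn post hoc
# are implemented here.

#' Two-sided Mann-Whitney U test
#'
#' `auto` mode uses the exact distribution when both samples have at most
#' 10 observations and there are no ties, otherwise the normal
#' approximation with tie and continuity correction. `exact` mode with tied
#' data enumerates the permutation distribution of U (feasible for small
#' samples only).
#'
#' @param a,b numeric samples (each non-empty)
#' @param mode `"auto"`, `"exact"` or `"normal_approx"`
#' @return list with `method`, `statistic` (U for sample `a`), `p_value`,
#'   `n`
#' @export
mann_whitney <- function(a, b, mode = c("auto", "exact", "normal_approx")) {
  mode <- match.arg(mode)
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) == 0 || length(b) == 0)
    stop("mann_whitney: both samples must be non-empty")
  na <- length(a); nb <- length(b)
  r <- rank(c(a, b))
  U <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  ties <- anyDuplicated(c(a, b)) > 0
  if (mode == "auto") mode <- if (na <= 10 && nb <= 10 && !ties)
    "exact" else "normal_approx"
  if (mode == "exact") {
    if (!ties) {
      p <- stats::wilcox.test(a, b, exact = TRUE)$p.value
    } else {
      if (choose(na + nb, na) > 2e5)
        stop("mann_whitney: exact mode with ties infeasible at this sample size")
      p <- .mw_exact_ties(c(a, b), na)
    }
  } else {
    p <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE,
                                             correct = TRUE)$p.value)
  }
  list(method = paste0("Mann-Whitney U (", mode, ")"),
       statistic = U, p_value = min(1, p), n = c(n_a = na, n_b = nb))
}

# exact two-sided p with ties: full enumeration of group assignments,
# two-sided as 2 * min tail probability of U (capped at 1)
.mw_exact_ties <- function(pooled, na) {
  n <- length(pooled)
  r <- rank(pooled)
  combs <- utils::combn(n, na)
  us <- colSums(matrix(r[combs], nrow = na)) - na * (na + 1) / 2
  u_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  m <- ncol(combs)
  p_low <- sum(us <= u_obs) / m
  p_high <- sum(us >= u_obs) / m
  min(1, 2 * min(p_low, p_high))
}

#' Quade-style rank analysis of covariance
#'
#' Nonparametric group comparison adjusted for a covariate: the response
#' and the covariate are each ranked over all observations (mid-ranks for
#' ties), the response ranks are regressed on the covariate ranks by least
#' squares, and a one-way analysis of variance on the residuals tests the
#' group effect with `(k-1, N-k)` degrees of freedom. Pairwise post hoc
#' comparisons repeat the procedure per group pair with Bonferroni
#' adjustment (p multiplied by the number of pairs, capped at 1).
#'
#' @param values numeric response
#' @param groups group labels (at least 2 groups, each n >= 3)
#' @param covariate numeric covariate (e.g. age)
#' @param posthoc compute pairwise comparisons
#' @param covariate_name label carried into the result
#' @return object of class `rank_ancova`: `statistic` (F), `df`,
#'   `p_omnibus`, `pairwise` data frame, `degenerate` flag
#' @export
rank_ancova <- function(values, groups, covariate, posthoc = TRUE,
                        covariate_name = "age") {
  ok <- !is.na(values) & !is.na(groups) & !is.na(covariate)
  values <- values[ok]; covariate <- covariate[ok]
  groups <- factor(groups[ok])
  k <- nlevels(groups)
  if (k < 2) stop("rank_ancova: need at least 2 groups")
  if (any(table(groups) < 3)) stop("rank_ancova: every group needs n >= 3")
  if (!is.numeric(covariate)) stop("rank_ancova: covariate must be numeric")
  core <- .quade_core(values, groups, covariate)
  pairwise <- NULL
  if (posthoc && k > 2) {
    levs <- levels(groups)
    pairs <- utils::combn(levs, 2)
    m <- ncol(pairs)
    pairwise <- do.call(rbind, lapply(seq_len(m), function(j) {
      sel <- groups %in% pairs[, j]
      res <- .quade_core(values[sel], droplevels(groups[sel]), covariate[sel])
      data.frame(group_1 = pairs[1, j], group_2 = pairs[2, j],
                 statistic = res$statistic, p_raw = res$p,
                 p_adjusted = min(1, res$p * m), stringsAsFactors = FALSE)
    }))
  }
  structure(list(method = "rank ANCOVA (Quade residuals-of-ranks)",
                 statistic = core$statistic, df = core$df,
                 p_omnibus = core$p, pairwise = pairwise,
                 covariate = covariate_name, degenerate = core$degenerate),
            class = "rank_ancova")
}

# residuals-of-ranks F test; constant residuals -> p = 1, flagged
.quade_core <- function(values, groups, covariate) {
  ry <- rank(values); rx <- rank(covariate)
  N <- length(ry); k <- nlevels(groups)
  vx <- stats::var(rx)
  slope <- if (vx > 0) stats::cov(ry, rx) / vx else 0
  res <- ry - mean(ry) - slope * (rx - mean(rx))
  if (stats::var(res) < .Machine$double.eps)
    return(list(statistic = 0, df = c(k - 1, N - k), p = 1, degenerate = TRUE))
  gm <- tapply(res, groups, mean)
  ng <- tapply(res, groups, length)
  ssb <- sum(ng * (gm - mean(res))^2)
  ssw <- sum((res - gm[groups])^2)
  f <- (ssb / (k - 1)) / (ssw / (N - k))
  list(statistic = f, df = c(k - 1, N - k),
       p = stats::pf(f, k - 1, N - k, lower.tail = FALSE), degenerate = FALSE)
}

#' @export
print.rank_ancova <- function(x, ...) {
  cat(x$method, "\nF =", format(x$statistic, digits = 4),
      "on", x$df[1], "and", x$df[2], "df, p =", format(x$p_omnibus, digits = 4),
      "(covariate:", paste0(x$covariate, ")"), "\n")
  if (!is.null(x$pairwise)) {
    cat("pairwise (Bonferroni):\n")
    print(x$pairwise, digits = 4)
  }
  invisible(x)
}

#' Kruskal-Wallis test with Dunn post hoc
#'
#' Tie-corrected Kruskal-Wallis omnibus (chi-squared on k-1 df) followed by
#' Dunn z-tests per group pair, p-values multiplied by the number of
#' pairwise comparisons (capped at 1). With 2 groups the comparison
#' delegates to [mann_whitney()].
#'
#' @param values numeric response
#' @param groups group labels; every group must be non-empty
#' @return list with `method`, `statistic` (H), `df`, `p_omnibus`,
#'   `pairwise` data frame
#' @export
kruskal_dunn <- function(values, groups) {
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]
  groups <- if (is.factor(groups)) groups[ok] else factor(groups[ok])
  if (any(table(groups) == 0) || nlevels(groups) < 2)
    stop("kruskal_dunn: every group must contain observations")
  if (nlevels(groups) == 2) {
    levs <- levels(groups)
    mw <- mann_whitney(values[groups == levs[1]], values[groups == levs[2]])
    return(list(method = mw$method, statistic = mw$statistic, df = NA_integer_,
                p_omnibus = mw$p_value,
                pairwise = data.frame(group_1 = levs[1], group_2 = levs[2],
                                      statistic = mw$statistic,
                                      p_raw = mw$p_value, p_adjusted = mw$p_value,
                                      stringsAsFactors = FALSE)))
  }
  kw <- stats::kruskal.test(values, groups)
  N <- length(values)
  r <- rank(values)
  rbar <- tapply(r, groups, mean)
  ng <- tapply(r, groups, length)
  tie_tab <- table(values)
  tie_corr <- sum(tie_tab^3 - tie_tab) / (12 * (N - 1))
  pairs <- utils::combn(levels(groups), 2)
  m <- ncol(pairs)
  pw <- do.call(rbind, lapply(seq_len(m), function(j) {
    g1 <- pairs[1, j]; g2 <- pairs[2, j]
    se <- sqrt((N * (N + 1) / 12 - tie_corr) * (1 / ng[g1] + 1 / ng[g2]))
    z <- (rbar[g1] - rbar[g2]) / se
    p <- 2 * stats::pnorm(-abs(z))
    data.frame(group_1 = g1, group_2 = g2, statistic = as.numeric(z),
               p_raw = p, p_adjusted = min(1, p * m), stringsAsFactors = FALSE)
  }))
  rownames(pw) <- NULL
  list(method = "Kruskal-Wallis with Dunn post hoc",
       statistic = unname(kw$statistic), df = unname(kw$parameter),
       p_omnibus = kw$p.value, pairwise = pw)
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks on pairwise-complete observations,
#' p-value via the t approximation. A constant vector has no defined rank
#' correlation and is flagged degenerate.
#'
#' @param x,y paired numeric vectors (at least 3 complete pairs)
#' @return list with `rho`, `p_value`, `n`, `degenerate`
#' @export
spearman_cor <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("spearman_cor: need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(rho = NA_real_, p_value = NA_real_, n = length(x),
                degenerate = TRUE))
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = length(x),
       degenerate = FALSE)
}

#' Pearson chi-squared test on a contingency table
#'
#' Without continuity correction, df = (r-1)(c-1). Tables with a zero
#' marginal have no defined expected counts and are rejected.
#'
#' @param counts r x c matrix of non-negative counts
#' @return list with `statistic`, `df`, `p_value`
#' @export
chi_squared <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || sum(counts) == 0)
    stop("chi_squared: counts must be non-negative with positive total")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("chi_squared: zero marginal row/column")
  ct <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = ct$p.value)
}

#' ROC area under the curve by the rank formulation
#'
#' `AUC = (R_pos - n_pos(n_pos+1)/2) / (n_pos * n_neg)` where `R_pos` is
#' the rank sum of the positive-class scores; tied scores contribute 1/2.
#' This equals `U / (n_pos * n_neg)` of the Mann-Whitney statistic, i.e.
#' the probability that a random positive outranks a random negative.
#'
#' @param scores numeric scores
#' @param labels class labels
#' @param positive_group label treated as positive
#' @param auto_orient report `max(auc, 1 - auc)` instead of the oriented
#'   value
#' @return list with `auc`, `positive_group`, `n_pos`, `n_neg`
#' @export
roc_auc <- function(scores, labels, positive_group, auto_orient = FALSE) {
  ok <- !is.na(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- labels[ok]
  pos <- labels == positive_group
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos == 0 || n_neg == 0)
    stop("roc_auc: both classes must be present")
  r <- rank(scores)
  auc <- (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  if (auto_orient) auc <- max(auc, 1 - auc)
  list(auc = auc, positive_group = positive_group, n_pos = n_pos, n_neg = n_neg)
}

#' Bonferroni adjustment
#'
#' `min(1, m * p)` elementwise; `m` defaults to the number of p-values.
#'
#' @param p_list p-values in `(0, 1]`
#' @param m number of comparisons, `>= 1`
#' @return adjusted p-values (never below the raw ones)
#' @export
bonferroni_adjust <- function(p_list, m = length(p_list)) {
  if (m < 1) stop("bonferroni_adjust: m must be >= 1")
  if (any(p_list <= 0 | p_list > 1, na.rm = TRUE))
    stop("bonferroni_adjust: p-values must lie in (0, 1]")
  pmin(1, p_list * m)
}

#' Per-peptide group-comparison table for SRM quantities
#'
#' Produces the validation-stage statistics for each peptide: group means
#' and SDs of the normalized ratios, the age-adjusted rank-ANCOVA omnibus
#' p with Bonferroni pairwise comparisons, plain Mann-Whitney p for
#' PD vs AP and PD vs MSA, and the PD-vs-AP AUC (AP treated as positive;
#' AP pools MSA and PSP).
#'
#' @param quant per-sample peptide quantities (`sample_id`, `peptide_id`,
#'   `normalized_ratio`), QC pools excluded automatically
#' @param metadata sample metadata with `sample_id`, `group`, `age`
#' @return data frame, one row per peptide
#' @export
peptide_group_stats <- function(quant, metadata) {
  q <- if ("is_qc_pool" %in% names(quant)) quant[!quant$is_qc_pool, ] else quant
  q <- merge(q, metadata[, c("sample_id", "group", "age")], by = "sample_id")
  q$group3 <- ifelse(q$group %in% c("MSA", "PSP"), "AP", q$group)
  rows <- lapply(split(q, q$peptide_id), function(d) {
    d <- d[!is.na(d$normalized_ratio), ]
    out <- data.frame(peptide_id = d$peptide_id[1], stringsAsFactors = FALSE)
    for (g in c("control", "PD", "MSA", "PSP")) {
      v <- d$normalized_ratio[d$group == g]
      out[[paste0("mean_", g)]] <- if (length(v)) mean(v) else NA_real_
      out[[paste0("sd_", g)]] <- if (length(v) > 1) stats::sd(v) else NA_real_
    }
    ra <- tryCatch(rank_ancova(d$normalized_ratio, d$group3, d$age),
                   error = function(e) NULL)
    out$p_ancova <- if (is.null(ra)) NA_real_ else ra$p_omnibus
    pd <- d$normalized_ratio[d$group3 == "PD"]
    ap <- d$normalized_ratio[d$group3 == "AP"]
    msa <- d$normalized_ratio[d$group == "MSA"]
    out$p_pd_vs_ap <- if (length(pd) && length(ap))
      mann_whitney(pd, ap)$p_value else NA_real_
    out$p_pd_vs_msa <- if (length(pd) && length(msa))
      mann_whitney(pd, msa)$p_value else NA_real_
    out$auc_pd_vs_ap <- if (length(pd) && length(ap))
      roc_auc(d$normalized_ratio[d$group3 %in% c("PD", "AP")],
              d$group3[d$group3 %in% c("PD", "AP")], positive_group = "AP",
              auto_orient = TRUE)$auc else NA_real_
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
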