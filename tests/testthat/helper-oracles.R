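# Independent oracles used to cross-check pipeline operations.

# exact two-sided Mann-Whitney p by full enumeration of group assignments
# (two-sided as the probability of a U at least as extreme on either tail,
# doubled and capped at 1)
oracle_mw_exact <- function(a, b) {
  pooled <- c(a, b)
  na <- length(a)
  r <- rank(pooled)
  combs <- utils::combn(length(pooled), na)
  us <- colSums(matrix(r[combs], nrow = na)) - na * (na + 1) / 2
  u_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
}

# Monte-Carlo permutation two-sided Mann-Whitney p (for tied data)
oracle_mw_permutation <- function(a, b, n_perm = 10000, seed = 1) {
  set.seed(seed)
  pooled <- c(a, b)
  na <- length(a)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  mu <- na * length(b) / 2
  us <- replicate(n_perm, {
    idx <- sample(length(pooled), na)
    sum(r[idx]) - na * (na + 1) / 2
  })
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# criterion-by-criterion re-evaluation of the SRM candidate rules,
# written independently of select_candidates()
oracle_select <- function(differentials, annotations, values, group_of,
                          p_cutoff = 0.05, ratio_cutoff = 1.5,
                          detection_fraction = 0.75, max_length = 20) {
  sel <- character(0)
  for (i in seq_len(nrow(differentials))) {
    pid <- differentials$peptide_id[i]
    ann <- annotations[annotations$peptide_id == pid, ]
    if (nrow(ann) == 0) next
    seqc <- strsplit(ann$sequence, "")[[1]]
    ok_det <- TRUE
    for (g in c("PD", "MSA")) {
      cols <- names(group_of)[group_of == g]
      v <- values[pid, cols]
      if (mean(!is.na(v) & v > 0) < detection_fraction) ok_det <- FALSE
    }
    liab_free <- !("M" %in% seqc) && !("C" %in% seqc) &&
      !grepl("NG", ann$sequence, fixed = TRUE) && !(seqc[1] %in% c("Q", "E"))
    p_ok <- !is.na(differentials$p_value[i]) && differentials$p_value[i] < p_cutoff
    r_ok <- !is.na(differentials$fold_ratio[i]) &&
      differentials$fold_ratio[i] >= ratio_cutoff
    if (p_ok && r_ok && ok_det && nchar(ann$sequence) <= max_length &&
        isTRUE(as.logical(ann$is_unique)) &&
        isTRUE(as.logical(ann$in_knowledge_base)) && liab_free)
      sel <- c(sel, pid)
  }
  sel
}

# brute-force per-key transition summation
oracle_aggregate <- function(report) {
  keys <- unique(report[, c("sample_id", "peptide_id", "label")])
  keys$area <- NA_real_
  for (i in seq_len(nrow(keys))) {
    sel <- report$sample_id == keys$sample_id[i] &
      report$peptide_id == keys$peptide_id[i] & report$label == keys$label[i]
    keys$area[i] <- sum(report$area[sel])
  }
  keys
}
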