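#' Endogenous-control candidacy criteria
#'
#' A probe is an EC candidate when, in every retained sample, it amplified
#' with AmpScore at or above `amp_score_min`, Cq strictly below `cq_max`, and
#' Cq confidence strictly above `cq_conf_min`, and the probe is an annotated
#' miRNA (not a control or withdrawn probe).
#'
#' @param detect_frac Required fraction of samples meeting all per-reaction
#'   criteria (default 1.0, i.e. every sample).
#' @param amp_score_min Minimum amplification score (default 1).
#' @param cq_max Strict upper Cq bound (default 30).
#' @param cq_conf_min Strict lower Cq-confidence bound (default 0.8).
#' @return Object of class `ec_criteria`.
#' @export
ec_criteria <- function(detect_frac = 1.0, amp_score_min = 1,
                        cq_max = 30, cq_conf_min = 0.8) {
  structure(list(detect_frac = detect_frac, amp_score_min = amp_score_min,
                 cq_max = cq_max, cq_conf_min = cq_conf_min),
            class = "ec_criteria")
}

#' Screen for endogenous-control candidates
#'
#' @param records An `amp_records` data.frame.
#' @param panel A [probe_panel()]; control and withdrawn probes are not
#'   eligible.
#' @param crit An [ec_criteria()].
#' @return Character vector of candidate probe ids (lexicographic order).
#' @export
select_ec_candidates <- function(records, panel = NULL, crit = ec_criteria()) {
  df <- as.data.frame(records)
  eligible <- unique(df$mirna_id)
  if (!is.null(panel))
    eligible <- intersect(eligible, analyzable_ids(panel))
  n_samples <- length(unique(df$sample_id))
  ok <- !is.na(df$cq) & df$cq < crit$cq_max &
    !is.na(df$amp_score) & df$amp_score >= crit$amp_score_min &
    !is.na(df$cq_conf) & df$cq_conf > crit$cq_conf_min
  n_ok <- table(factor(df$mirna_id[ok], levels = eligible))
  cand <- sort(names(n_ok)[as.vector(n_ok) >= crit$detect_frac * n_samples])
  if (length(cand) < 3L)
    stop("select_ec_candidates: insufficient EC candidates (",
         length(cand), " < 3)")
  cand
}

# Pairwise SD matrix of Cq differences: sd(Cq_j - Cq_k) over samples,
# obtained from the column covariance, var(x_j - x_k) = C_jj + C_kk - 2C_jk.
# The geNorm stability M of gene j within a set is the mean of row j of this
# matrix over the other members; removing a gene only drops a row/column,
# so the matrix is computed once.
.pairwise_sd <- function(cq_tab) {
  cv <- stats::cov(cq_tab)
  d <- diag(cv)
  v <- outer(d, d, `+`) - 2 * cv
  v[v < 0] <- 0  # numeric noise
  sq <- sqrt(v)
  diag(sq) <- 0
  dimnames(sq) <- list(colnames(cq_tab), colnames(cq_tab))
  sq
}

.genorm_m_from_sd <- function(sd_mat) {
  p <- ncol(sd_mat)
  m <- rowSums(sd_mat) / (p - 1)
  names(m) <- colnames(sd_mat)
  m
}

#' geNorm stability ranking with pairwise-variation stopping
#'
#' Ranks endogenous-control candidates by the geNorm expression-stability
#' measure M (mean, over all other candidates, of the SD across samples of
#' the per-sample Cq difference), computed directly on Cq since Cq is already
#' log-scale. Candidates are iteratively removed worst-first to produce the
#' ranking; the pairwise variation V_k is the SD across samples of the
#' difference between the log-scale normalization factors (mean Cq) of the
#' top-k and top-(k+1) sets. The selected set is the smallest k >= 2 with
#' V_k below `v_threshold`, or all candidates if none qualifies.
#'
#' @param cq_table Numeric matrix, samples x candidates, complete (candidacy
#'   guarantees no missing Cq). Column names are candidate ids.
#' @param v_threshold Pairwise-variation stopping threshold (default 0.1527).
#' @return Object of class `stability_ranking`: list with `candidates`
#'   (ranked ids, most stable first), `M` (stability values of the full
#'   candidate set, in ranked order), `V` (named vector V_2 ... V_{n-1}),
#'   `selected_ecs`, `v_threshold`.
#' @export
stability_rank <- function(cq_table, v_threshold = 0.1527) {
  cq_table <- as.matrix(cq_table)
  stopifnot(!anyNA(cq_table), ncol(cq_table) >= 3L)
  ids <- colnames(cq_table)
  if (is.null(ids)) ids <- paste0("candidate", seq_len(ncol(cq_table)))
  colnames(cq_table) <- ids

  sd_mat <- .pairwise_sd(cq_table)
  m_full <- .genorm_m_from_sd(sd_mat)

  # worst-first removal; ties removed in reverse lexicographic order so the
  # lexicographically smaller id ranks as more stable
  remaining <- ids
  removal <- character(0)
  while (length(remaining) > 2L) {
    m_cur <- .genorm_m_from_sd(sd_mat[remaining, remaining, drop = FALSE])
    tied <- remaining[m_cur == max(m_cur)]
    worst <- sort(tied, decreasing = TRUE)[1L]
    removal <- c(removal, worst)
    remaining <- setdiff(remaining, worst)
  }
  ranked <- c(sort(remaining), rev(removal))

  n <- length(ranked)
  v <- numeric(0)
  if (n >= 3L) {
    ks <- 2:(n - 1L)
    v <- vapply(ks, function(k) {
      nf_k  <- rowMeans(cq_table[, ranked[seq_len(k)], drop = FALSE])
      nf_k1 <- rowMeans(cq_table[, ranked[seq_len(k + 1L)], drop = FALSE])
      stats::sd(nf_k - nf_k1)
    }, numeric(1))
    names(v) <- paste0("V", ks)
  }
  k_sel <- if (length(v) && any(v < v_threshold)) {
    1L + which(v < v_threshold)[1L]  # smallest k with V_k < threshold
  } else n
  structure(list(candidates = ranked,
                 M = m_full[ranked],
                 V = v,
                 selected_ecs = ranked[seq_len(k_sel)],
                 v_threshold = v_threshold),
            class = "stability_ranking")
}

#' @export
print.stability_ranking <- function(x, ...) {
  cat("geNorm stability ranking of", length(x$candidates), "candidates\n")
  cat("selected ECs (V threshold ", x$v_threshold, "): ",
      paste(x$selected_ecs, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Build a delta-Cq expression matrix by endogenous-control normalization
#'
#' For each sample the normalizer g_s is the geometric mean of the EC Cq
#' values; delta-Cq of a good cell is Cq - g_s. Censored cells (below the
#' detection limit) carry the sample-specific censoring threshold
#' `cq_ceiling - g_s` as their value with the censoring mask set; excluded
#' cells (technical failures) carry no value. Samples lacking a good-flag Cq
#' for any EC are dropped with a warning.
#'
#' @param records An `amp_records` data.frame.
#' @param ecs Character vector of EC probe ids (>= 2).
#' @param qc A [qc_params()] (supplies the Cq ceiling).
#' @param mirnas Optional probe ids to include (default: all probes present).
#' @return Object of class `expr_matrix`: list with numeric matrix `dcq`
#'   (samples x miRNAs), logical matrices `censored`, `excluded`, numeric
#'   `censor_threshold` per sample, plus `samples`, `mirnas`, `ecs`,
#'   `cq_ceiling`.
#' @export
normalize_dcq <- function(records, ecs, qc = qc_params(), mirnas = NULL) {
  stopifnot(length(ecs) >= 2L)
  df <- as.data.frame(records)
  samples <- unique(df$sample_id)
  if (is.null(mirnas)) mirnas <- sort(unique(df$mirna_id))

  ec_rows <- df[df$mirna_id %in% ecs & df$flag == "good", ]
  n_ec <- table(factor(ec_rows$sample_id, levels = samples))
  keep <- names(n_ec)[as.vector(n_ec) == length(ecs)]
  dropped <- setdiff(samples, keep)
  if (length(dropped))
    warning("normalize_dcq: dropping sample(s) missing an EC: ",
            paste(dropped, collapse = ", "))
  samples <- keep
  ec_rows <- ec_rows[ec_rows$sample_id %in% samples, ]
  g <- tapply(ec_rows$cq, factor(ec_rows$sample_id, levels = samples),
              function(x) exp(mean(log(x))))
  g <- as.numeric(g); names(g) <- samples

  df <- df[df$sample_id %in% samples & df$mirna_id %in% mirnas, ]
  si <- match(df$sample_id, samples)
  mi <- match(df$mirna_id, mirnas)
  dims <- c(length(samples), length(mirnas))
  dn <- list(samples, mirnas)
  dcq <- matrix(NA_real_, dims[1], dims[2], dimnames = dn)
  censored <- matrix(FALSE, dims[1], dims[2], dimnames = dn)
  excluded <- matrix(TRUE, dims[1], dims[2], dimnames = dn)  # absent = excluded
  idx <- cbind(si, mi)
  excluded[idx] <- df$flag == "excluded"
  censored[idx] <- df$flag == "censored"
  good <- df$flag == "good"
  dcq[idx[good, , drop = FALSE]] <- df$cq[good] - g[si[good]]
  cen <- df$flag == "censored"
  dcq[idx[cen, , drop = FALSE]] <- qc$cq_ceiling - g[si[cen]]

  structure(list(dcq = dcq, censored = censored, excluded = excluded,
                 censor_threshold = qc$cq_ceiling - g,
                 samples = samples, mirnas = mirnas, ecs = ecs,
                 cq_ceiling = qc$cq_ceiling),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat("expr_matrix:", length(x$samples), "samples x", length(x$mirnas),
      "miRNAs;", sum(x$censored), "censored,", sum(x$excluded),
      "excluded cells\n")
  invisible(x)
}

#' Subset an expression matrix by miRNA and/or sample
#' @param em An `expr_matrix`.
#' @param mirnas,samples Ids to keep (default all).
#' @return An `expr_matrix`.
#' @export
subset_expr <- function(em, mirnas = em$mirnas, samples = em$samples) {
  em$dcq <- em$dcq[samples, mirnas, drop = FALSE]
  em$censored <- em$censored[samples, mirnas, drop = FALSE]
  em$excluded <- em$excluded[samples, mirnas, drop = FALSE]
  em$censor_threshold <- em$censor_threshold[samples]
  em$samples <- samples
  em$mirnas <- mirnas
  em
}

#' Filter miRNAs by failure and detection fractions
#'
#' Drops miRNAs whose excluded-cell (technical failure) fraction exceeds
#' `fail_frac_max`, then keeps, of the remainder, those whose good-cell
#' (detected) fraction is at least `detect_frac_min`. Censored cells count
#' toward neither failure nor detection. Denominator is the number of
#' samples in the matrix.
#'
#' @param em An `expr_matrix`.
#' @param fail_frac_max Strict upper bound on failure fraction (default 0.20).
#' @param detect_frac_min Inclusive lower bound on detection fraction
#'   (default 0.10).
#' @return Filtered `expr_matrix`.
#' @export
filter_mirnas <- function(em, fail_frac_max = 0.20, detect_frac_min = 0.10) {
  n <- length(em$samples)
  fail_frac <- colSums(em$excluded) / n
  good_frac <- colSums(!em$excluded & !em$censored) / n
  keep <- em$mirnas[fail_frac <= fail_frac_max & good_frac >= detect_frac_min]
  subset_expr(em, mirnas = keep)
}

#' Write an expression matrix as plain-text CSVs
#'
#' Writes the wide delta-Cq matrix, the companion censoring/exclusion masks
#' and the per-sample censoring thresholds.
#'
#' @param em An `expr_matrix`.
#' @param prefix Path prefix; files `<prefix>_dcq.csv`, `<prefix>_mask.csv`,
#'   `<prefix>_thresholds.csv` are created.
#' @return The three paths, invisibly.
#' @export
write_expr_matrix <- function(em, prefix) {
  p1 <- paste0(prefix, "_dcq.csv")
  p2 <- paste0(prefix, "_mask.csv")
  p3 <- paste0(prefix, "_thresholds.csv")
  utils::write.csv(data.frame(sample_id = em$samples, em$dcq,
                              check.names = FALSE), p1, row.names = FALSE)
  mask <- matrix("good", length(em$samples), length(em$mirnas),
                 dimnames = dimnames(em$dcq))
  mask[em$censored] <- "censored"
  mask[em$excluded] <- "excluded"
  utils::write.csv(data.frame(sample_id = em$samples, mask,
                              check.names = FALSE), p2, row.names = FALSE)
  utils::write.csv(data.frame(sample_id = em$samples,
                              censor_threshold = em$censor_threshold,
                              cq_ceiling = em$cq_ceiling),
                   p3, row.names = FALSE)
  invisible(c(p1, p2, p3))
}

#' Read an expression matrix written by [write_expr_matrix()]
#' @param prefix Path prefix used when writing.
#' @return An `expr_matrix`.
#' @export
read_expr_matrix <- function(prefix) {
  d <- utils::read.csv(paste0(prefix, "_dcq.csv"), check.names = FALSE)
  m <- utils::read.csv(paste0(prefix, "_mask.csv"), check.names = FALSE)
  th <- utils::read.csv(paste0(prefix, "_thresholds.csv"), check.names = FALSE)
  samples <- as.character(d$sample_id)
  mirnas <- setdiff(names(d), "sample_id")
  dcq <- as.matrix(d[mirnas]); rownames(dcq) <- samples
  mask <- as.matrix(m[mirnas]); rownames(mask) <- samples
  thr <- th$censor_threshold; names(thr) <- as.character(th$sample_id)
  structure(list(dcq = dcq, censored = mask == "censored",
                 excluded = mask == "excluded",
                 censor_threshold = thr[samples],
                 samples = samples, mirnas = mirnas, ecs = character(),
                 cq_ceiling = th$cq_ceiling[1L]),
            class = "expr_matrix")
}

#' Write the endogenous-control selection report
#' @param ranking A `stability_ranking`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_ec_report <- function(ranking, path) {
  n <- length(ranking$candidates)
  v_col <- rep(NA_real_, n)
  if (length(ranking$V))
    v_col[seq_along(ranking$V) + 1L] <- ranking$V
  utils::write.csv(data.frame(rank = seq_len(n),
                              mirna_id = ranking$candidates,
                              M = as.numeric(ranking$M),
                              V = v_col,
                              selected = ranking$candidates %in% ranking$selected_ecs),
                   path, row.names = FALSE)
  invisible(path)
}
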