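#' Two-group log-rank test for right-censored delta-Cq
#'
#' Delta-Cq is treated as the time-like axis: higher delta-Cq means lower
#' abundance, and an undetected cell is right-censored at its sample's
#' censoring threshold. The statistic is the standard two-group log-rank
#' with hypergeometric variance and pooled ties; p is from chi-square with
#' one degree of freedom.
#'
#' @param x,y Numeric delta-Cq values of the two groups (censored cells at
#'   their thresholds).
#' @param x_censored,y_censored Logical censoring masks.
#' @return List with `chisq`, `p`, `n_test`, `n_ref`; `chisq` and `p` are
#'   `NA` when a group has no usable cells or no events occur.
#' @export
logrank_censored <- function(x, x_censored = rep(FALSE, length(x)),
                             y, y_censored = rep(FALSE, length(y))) {
  ok_x <- !is.na(x); ok_y <- !is.na(y)
  x <- x[ok_x]; x_censored <- x_censored[ok_x]
  y <- y[ok_y]; y_censored <- y_censored[ok_y]
  out <- list(chisq = NA_real_, p = NA_real_,
              n_test = length(x), n_ref = length(y))
  if (!length(x) || !length(y)) return(out)
  time <- c(x, y)
  event <- !c(x_censored, y_censored)
  grp1 <- c(rep(TRUE, length(x)), rep(FALSE, length(y)))
  if (!any(event)) return(out)

  ord <- order(time)
  time <- time[ord]; event <- event[ord]; grp1 <- grp1[ord]
  ev_times <- unique(time[event])
  n <- length(time)
  oe <- 0; v <- 0
  for (t in ev_times) {
    at_risk <- time >= t
    nj <- sum(at_risk)
    n1j <- sum(at_risk & grp1)
    ev <- event & time == t
    dj <- sum(ev)
    d1j <- sum(ev & grp1)
    e1j <- dj * n1j / nj
    oe <- oe + d1j - e1j
    if (nj > 1)
      v <- v + dj * (n1j / nj) * (1 - n1j / nj) * (nj - dj) / (nj - 1)
  }
  if (v <= 0) {
    out$chisq <- 0; out$p <- 1
    return(out)
  }
  out$chisq <- oe^2 / v
  out$p <- stats::pchisq(out$chisq, df = 1, lower.tail = FALSE)
  out
}

.km_median <- function(x, censored) {
  # Kaplan-Meier median of the delta-Cq "survival" curve
  ord <- order(x)
  x <- x[ord]; event <- !censored[ord]
  n <- length(x)
  s <- 1
  for (i in seq_len(n)) {
    if (event[i]) {
      at_risk <- n - i + 1
      s <- s * (1 - 1 / at_risk)
      if (s <= 0.5) return(x[i])
    }
  }
  NA_real_
}

#' Fold change by the 2^-ddCq relative-quantitation convention
#'
#' Group means of delta-Cq are computed with censored cells substituted at
#' their censoring thresholds (default policy) or replaced by Kaplan-Meier
#' group medians (`policy = "km_median"`). ddCq is mean(test) - mean(ref),
#' the fold change is 2^-ddCq, and the interval follows the relative
#' quantitation convention 2^-(ddCq +/- s) with s the combined group SD,
#' sqrt(sd_test^2 + sd_ref^2), bounds ordered.
#'
#' @param x,y Delta-Cq values for test and reference group.
#' @param x_censored,y_censored Logical censoring masks.
#' @param policy "substitute" (censored at threshold; default) or
#'   "km_median" (ddCq from Kaplan-Meier medians; interval from detected
#'   cells only).
#' @return List with `fc`, `fc_lo`, `fc_hi`, `ddcq`; interval is `NA` when
#'   either group has fewer than two observations.
#' @export
fold_change <- function(x, x_censored = rep(FALSE, length(x)),
                        y, y_censored = rep(FALSE, length(y)),
                        policy = c("substitute", "km_median")) {
  policy <- match.arg(policy)
  ok_x <- !is.na(x); ok_y <- !is.na(y)
  x <- x[ok_x]; x_censored <- x_censored[ok_x]
  y <- y[ok_y]; y_censored <- y_censored[ok_y]
  if (!length(x) || !length(y))
    return(list(fc = NA_real_, fc_lo = NA_real_, fc_hi = NA_real_,
                ddcq = NA_real_))
  if (policy == "substitute") {
    ddcq <- mean(x) - mean(y)
    s <- if (length(x) > 1 && length(y) > 1)
      sqrt(stats::var(x) + stats::var(y)) else NA_real_
  } else {
    mx <- .km_median(x, x_censored); my <- .km_median(y, y_censored)
    ddcq <- mx - my
    xd <- x[!x_censored]; yd <- y[!y_censored]
    s <- if (length(xd) > 1 && length(yd) > 1)
      sqrt(stats::var(xd) + stats::var(yd)) else NA_real_
  }
  fc <- 2^(-ddcq)
  if (is.na(s)) {
    lo <- hi <- NA_real_
  } else {
    bounds <- sort(2^(-(ddcq + c(-s, s))))
    lo <- bounds[1]; hi <- bounds[2]
  }
  list(fc = fc, fc_lo = lo, fc_hi = hi, ddcq = ddcq)
}

.default_contrasts <- list(c("DepTBI", "ComC"), c("DepC", "ComC"),
                           c("DepTBI", "DepC"))

.contrast_label <- function(ct) paste(ct[1], "vs", ct[2])

#' Differential expression across group contrasts
#'
#' Runs the censored log-rank test and 2^-ddCq fold change for every miRNA
#' in every contrast, with Benjamini-Hochberg FDR within contrast.
#' Significance is raw p < `alpha` (FDR is reported, not used for the flag).
#'
#' @param em A filtered `expr_matrix`.
#' @param phenos A `pheno_table`.
#' @param alpha Significance level on raw p (default 0.025).
#' @param contrasts List of (test, reference) group pairs; default the three
#'   contrasts DepTBI vs ComC, DepC vs ComC, DepTBI vs DepC.
#' @param fc_policy Censoring policy passed to [fold_change()].
#' @return data.frame of class `de_results`: one row per (miRNA, contrast)
#'   with chisq, p, fc, fc_lo, fc_hi, fdr, n_test, n_ref, significant.
#' @export
run_contrasts <- function(em, phenos, alpha = 0.025,
                          contrasts = .default_contrasts,
                          fc_policy = "substitute") {
  grp <- phenos$group[match(em$samples, phenos$sample_id)]
  rows <- list()
  for (ct in contrasts) {
    lab <- .contrast_label(ct)
    s_test <- which(grp == ct[1]); s_ref <- which(grp == ct[2])
    res <- lapply(seq_along(em$mirnas), function(j) {
      use_t <- s_test[!em$excluded[s_test, j]]
      use_r <- s_ref[!em$excluded[s_ref, j]]
      xt <- em$dcq[use_t, j]; ct_c <- em$censored[use_t, j]
      xr <- em$dcq[use_r, j]; cr_c <- em$censored[use_r, j]
      lr <- list(chisq = NA_real_, p = NA_real_,
                 n_test = length(use_t), n_ref = length(use_r))
      fc <- list(fc = NA_real_, fc_lo = NA_real_, fc_hi = NA_real_,
                 ddcq = NA_real_)
      # each group needs at least one uncensored observation
      if (length(use_t) && length(use_r) && any(!ct_c) && any(!cr_c)) {
        lr <- logrank_censored(xt, ct_c, xr, cr_c)
        fc <- fold_change(xt, ct_c, xr, cr_c, policy = fc_policy)
      }
      data.frame(mirna_id = em$mirnas[j], contrast = lab,
                 n_test = lr$n_test, n_ref = lr$n_ref,
                 chisq = lr$chisq, p = lr$p, ddcq = fc$ddcq,
                 fc = fc$fc, fc_lo = fc$fc_lo, fc_hi = fc$fc_hi,
                 stringsAsFactors = FALSE)
    })
    tab <- do.call(rbind, res)
    tab$fdr <- stats::p.adjust(tab$p, method = "BH")
    tab$significant <- !is.na(tab$p) & tab$p < alpha
    rows[[lab]] <- tab
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("de_results", "data.frame")
  out
}
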