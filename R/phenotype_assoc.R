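#' Simple linear regression of miRNA expression on a covariate
#'
#' Ordinary least squares of delta-Cq on the covariate over complete,
#' uncensored pairs. Censored cells are excluded: substituting them at the
#' detection bound would fabricate linear signal there.
#'
#' @param dcq Delta-Cq values.
#' @param censored Logical censoring mask.
#' @param covariate Covariate values (same length).
#' @return List with `slope`, `p`, `r2`, `n`; all `NA` (with a warning for a
#'   constant covariate) when no fit is possible.
#' @export
regress_mirna_on_covariate <- function(dcq, censored, covariate) {
  keep <- !is.na(dcq) & !censored & !is.na(covariate)
  y <- dcq[keep]; x <- covariate[keep]
  out <- list(slope = NA_real_, p = NA_real_, r2 = NA_real_, n = length(y))
  if (length(y) < 3L) return(out)
  if (stats::sd(x) == 0) {
    warning("regress_mirna_on_covariate: constant covariate")
    return(out)
  }
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  out$slope <- unname(stats::coef(fit)[2L])
  out$p <- sm$coefficients[2L, 4L]
  out$r2 <- sm$r.squared
  out
}

#' Per-group regressions of miRNAs on biological variables
#'
#' One OLS fit per (miRNA, group, covariate); uncorrected p and R-squared
#' are reported, as is the number of uncensored complete pairs per fit.
#'
#' @param em An `expr_matrix`.
#' @param phenos A `pheno_table`.
#' @param mirnas miRNAs to test (default all in `em`).
#' @param covariates Phenotype column names (default the continuous
#'   biological variables present).
#' @param groups Groups to fit within (default the three study groups).
#' @return data.frame of class `assoc_results`.
#' @export
run_associations <- function(em, phenos, mirnas = em$mirnas,
                             covariates = NULL,
                             groups = c("ComC", "DepC", "DepTBI")) {
  if (is.null(covariates)) {
    cand <- c("age", "bmi", "mmse", "abeta42", "ttau", "ptau181",
              "abeta_ttau", "abeta_ptau", "ptau_ttau",
              "n_tbi", "years_since_tbi")
    covariates <- intersect(cand, names(phenos))
  }
  grp <- phenos$group[match(em$samples, phenos$sample_id)]
  rows <- list()
  for (g in groups) {
    s <- which(grp == g)
    for (m in mirnas) {
      j <- match(m, em$mirnas)
      use <- s[!em$excluded[s, j]]
      for (cv in covariates) {
        cvv <- phenos[[cv]][match(em$samples[use], phenos$sample_id)]
        r <- suppressWarnings(
          regress_mirna_on_covariate(em$dcq[use, j], em$censored[use, j], cvv))
        rows[[length(rows) + 1L]] <- data.frame(
          mirna_id = m, group = g, covariate = cv,
          slope = r$slope, p = r$p, r2 = r$r2, n = r$n,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("assoc_results", "data.frame")
  out
}

#' Correlation between two assay runs of the same samples
#'
#' For discovery-vs-verification comparisons: Pearson correlation per sample
#' across shared miRNAs, and per miRNA across shared samples, using only
#' cells uncensored and present in both runs. Correlations with fewer than
#' three shared cells are absent.
#'
#' @param run_a,run_b `expr_matrix` objects (or plain samples x miRNAs
#'   matrices with `NA` for unusable cells).
#' @return List with data.frames `per_sample` and `per_mirna`
#'   (id, r, n_shared) and a `summary` data.frame with median and range of
#'   each set of correlations.
#' @export
paired_run_correlation <- function(run_a, run_b) {
  as_mat <- function(r) {
    if (inherits(r, "expr_matrix")) {
      m <- r$dcq
      m[r$censored | r$excluded] <- NA
      m
    } else as.matrix(r)
  }
  a <- as_mat(run_a); b <- as_mat(run_b)
  samples <- intersect(rownames(a), rownames(b))
  mirnas <- intersect(colnames(a), colnames(b))
  a <- a[samples, mirnas, drop = FALSE]
  b <- b[samples, mirnas, drop = FALSE]
  cor_pair <- function(u, v) {
    ok <- !is.na(u) & !is.na(v)
    if (sum(ok) < 3L || stats::sd(u[ok]) == 0 || stats::sd(v[ok]) == 0)
      return(c(NA_real_, sum(ok)))
    c(stats::cor(u[ok], v[ok]), sum(ok))
  }
  ps <- t(vapply(samples, function(s) cor_pair(a[s, ], b[s, ]), numeric(2)))
  pm <- t(vapply(mirnas, function(m) cor_pair(a[, m], b[, m]), numeric(2)))
  per_sample <- data.frame(id = samples, r = ps[, 1], n_shared = ps[, 2],
                           stringsAsFactors = FALSE, row.names = NULL)
  per_mirna <- data.frame(id = mirnas, r = pm[, 1], n_shared = pm[, 2],
                          stringsAsFactors = FALSE, row.names = NULL)
  summarize <- function(r) {
    r <- r[!is.na(r)]
    if (!length(r)) return(c(median = NA_real_, min = NA_real_, max = NA_real_))
    c(median = stats::median(r), min = min(r), max = max(r))
  }
  list(per_sample = per_sample, per_mirna = per_mirna,
       summary = data.frame(level = c("sample", "mirna"),
                            rbind(summarize(per_sample$r),
                                  summarize(per_mirna$r)),
                            row.names = NULL))
}
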