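# Independent oracles, deliberately written as direct transcriptions of the
# defining formulas (loops, no shared code with the package internals).

oracle_entropy <- function(counts) {
  p <- as.numeric(counts) / sum(counts)
  h <- 0
  for (pi in p) if (pi > 0) h <- h - pi * log2(pi)
  h
}

oracle_mi <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  mi <- 0
  for (a in unique(x)) for (b in unique(y)) {
    pab <- sum(x == a & y == b) / n
    if (pab > 0)
      mi <- mi + pab * log2(pab / ((sum(x == a) / n) * (sum(y == b) / n)))
  }
  mi
}

oracle_delta <- function(m, p, s) {
  ok <- !is.na(m) & !is.na(p) & !is.na(s)
  m <- m[ok]; p <- p[ok]; s <- s[ok]
  h <- function(...) oracle_entropy(table(...))
  i_mp <- h(m) + h(p) - h(m, p)
  i_ms <- h(m) + h(s) - h(m, s)
  i_ps <- h(p) + h(s) - h(p, s)
  i_mp_g_s <- h(m, s) + h(p, s) - h(s) - h(m, p, s)
  i3 <- i_mp - i_mp_g_s
  d_m <- i3 - i_ps; d_p <- i3 - i_ms; d_s <- i3 - i_mp
  list(i3 = i3, delta_m = d_m, delta_p = d_p, delta_s = d_s,
       delta_bar = d_m * d_p * d_s)
}

# geNorm stability by direct definition: mean over partners of the SD of the
# per-sample Cq difference
oracle_genorm_m <- function(tab) {
  p <- ncol(tab)
  m <- numeric(p)
  for (j in 1:p) {
    acc <- c()
    for (k in 1:p) if (k != j) acc <- c(acc, sd(tab[, j] - tab[, k]))
    m[j] <- mean(acc)
  }
  names(m) <- colnames(tab)
  m
}

# Two-sided Fisher p by exhaustive enumeration over tables with the observed
# margins: sum hypergeometric probabilities <= that of the observed table
oracle_fisher_p <- function(tab) {
  a <- tab[1, 1]
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1])
  lo <- max(0, c1 - r2); hi <- min(r1, c1)
  p_obs <- dhyper(a, r1, r2, c1)
  px <- dhyper(lo:hi, r1, r2, c1)
  min(1, sum(px[px <= p_obs * (1 + 1e-7)]))
}

# expr_matrix built directly from components, bypassing normalize_dcq
make_em <- function(dcq, censored = NULL, excluded = NULL,
                    censor_threshold = NULL, cq_ceiling = 34) {
  dcq <- as.matrix(dcq)
  if (is.null(rownames(dcq))) rownames(dcq) <- sprintf("S%02d", seq_len(nrow(dcq)))
  if (is.null(colnames(dcq))) colnames(dcq) <- sprintf("m%02d", seq_len(ncol(dcq)))
  if (is.null(censored)) censored <- matrix(FALSE, nrow(dcq), ncol(dcq))
  if (is.null(excluded)) excluded <- matrix(FALSE, nrow(dcq), ncol(dcq))
  dimnames(censored) <- dimnames(excluded) <- dimnames(dcq)
  if (is.null(censor_threshold))
    censor_threshold <- rep(14, nrow(dcq))
  names(censor_threshold) <- rownames(dcq)
  structure(list(dcq = dcq, censored = censored, excluded = excluded,
                 censor_threshold = censor_threshold,
                 samples = rownames(dcq), mirnas = colnames(dcq),
                 ecs = character(), cq_ceiling = cq_ceiling),
            class = "expr_matrix")
}

make_phenos <- function(groups, ...) {
  qpcrcens::pheno_table(data.frame(
    sample_id = sprintf("S%02d", seq_along(groups)), group = groups,
    ..., stringsAsFactors = FALSE))
}

# absolute-tolerance scalar comparison (the 1e-12 oracle criteria are
# absolute; testthat's default tolerance is relative)
expect_close <- function(a, b, tol = 1e-12) {
  testthat::expect_lt(abs(a - b), tol)
}
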