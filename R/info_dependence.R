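#' Plug-in Shannon entropy in bits
#'
#' Maximum-likelihood entropy of a discrete distribution given as a
#' (possibly multi-way) table of counts; 0 log 0 = 0.
#'
#' @param counts Nonnegative counts (vector, matrix or array) with a
#'   positive total.
#' @return Entropy in bits.
#' @export
entropy_bits <- function(counts) {
  n <- sum(counts)
  if (n <= 0) stop("entropy_bits: empty table")
  p <- as.numeric(counts) / n
  p <- p[p > 0]
  -sum(p * log2(p))
}

.complete <- function(...) {
  vars <- list(...)
  ok <- Reduce(`&`, lapply(vars, function(v) !is.na(v)))
  lapply(vars, function(v) v[ok])
}

#' Mutual information of two discrete variables (bits)
#'
#' I(X,Y) = H(X) + H(Y) - H(X,Y), plug-in estimate over complete pairs.
#'
#' @param x,y Integer codes (NA allowed; complete-case).
#' @return Mutual information in bits (0 when fewer than one complete pair
#'   would make the estimate undefined raises an error).
#' @export
mutual_information <- function(x, y) {
  cc <- .complete(x, y)
  if (!length(cc[[1]])) stop("mutual_information: no complete pairs")
  tab <- table(cc[[1]], cc[[2]])
  entropy_bits(rowSums(tab)) + entropy_bits(colSums(tab)) - entropy_bits(tab)
}

.cond_mi <- function(x, y, z) {
  # I(X,Y|Z) = H(X,Z) + H(Y,Z) - H(Z) - H(X,Y,Z), same complete-case set
  txz <- table(x, z); tyz <- table(y, z); tz <- table(z)
  txyz <- table(x, y, z)
  entropy_bits(txz) + entropy_bits(tyz) - entropy_bits(tz) - entropy_bits(txyz)
}

#' Interaction information and symmetric delta of three variables
#'
#' Interaction information I3 = I(M,P) - I(M,P|S); the asymmetric deltas
#' subtract the pairwise mutual information of the remaining pair,
#' Delta_M = I3 - I(P,S), Delta_P = I3 - I(M,S), Delta_S = I3 - I(M,P);
#' the symmetric delta is their product. All quantities are computed on the
#' complete-case triple so the decomposition is internally consistent. The
#' symmetric delta is zero whenever one variable is independent of the
#' other two, and for synergistic triples the deltas are negative.
#'
#' @param m,p,s Integer codes (NA allowed; complete-case over the triple).
#' @return List with `i3`, `delta_m`, `delta_p`, `delta_s`, `delta_bar`,
#'   `n` (complete triples used).
#' @export
symmetric_delta <- function(m, p, s) {
  cc <- .complete(m, p, s)
  m <- cc[[1]]; p <- cc[[2]]; s <- cc[[3]]
  if (!length(m)) stop("symmetric_delta: no complete triples")
  i_mp <- mutual_information(m, p)
  i_ms <- mutual_information(m, s)
  i_ps <- mutual_information(p, s)
  i3 <- i_mp - .cond_mi(m, p, s)
  d_m <- i3 - i_ps
  d_p <- i3 - i_ms
  d_s <- i3 - i_mp
  list(i3 = i3, delta_m = d_m, delta_p = d_p, delta_s = d_s,
       delta_bar = d_m * d_p * d_s, n = length(m))
}

#' Equal-frequency three-bin discretization around mu +/- f s
#'
#' Grid-searches the factor f over (0, 2] in steps of 0.01; thresholds
#' mu - f s and mu + f s cut the values into three bins and f is chosen to
#' minimize the maximum absolute deviation of bin counts from n/3 (ties go
#' to the smallest f). Values equal to a threshold fall in the lower bin.
#' Codes 0/1/2 are in ascending value order.
#'
#' @param values Numeric vector (NA allowed; at least 6 non-missing).
#' @param f_grid Candidate factors (default `seq(0.01, 2, by = 0.01)`).
#' @return Object of class `binned_variable`: list with `codes` (integer,
#'   NA preserved), `n_bins = 3`, `scheme = "tertile-musigma"`, `f`,
#'   `edges` (mu - f s, mu + f s), `mu`, `s`.
#' @export
bin_tertile <- function(values, f_grid = seq(0.01, 2, by = 0.01)) {
  v <- values[!is.na(values)]
  if (length(v) < 6L) stop("bin_tertile: need at least 6 non-missing values")
  mu <- mean(v); s <- stats::sd(v)
  if (s == 0) stop("bin_tertile: zero variance, single-bin degenerate")
  target <- length(v) / 3
  best_f <- NA_real_; best_dev <- Inf
  for (f in f_grid) {
    lo <- mu - f * s; hi <- mu + f * s
    n0 <- sum(v <= lo); n2 <- sum(v > hi); n1 <- length(v) - n0 - n2
    dev <- max(abs(c(n0, n1, n2) - target))
    if (dev < best_dev - 1e-12) { best_dev <- dev; best_f <- f }
  }
  lo <- mu - best_f * s; hi <- mu + best_f * s
  codes <- ifelse(is.na(values), NA_integer_,
                  ifelse(values <= lo, 0L, ifelse(values <= hi, 1L, 2L)))
  structure(list(codes = codes, n_bins = 3L, scheme = "tertile-musigma",
                 f = best_f, edges = c(lo, hi), mu = mu, s = s),
            class = "binned_variable")
}

#' Two-bin mean split
#'
#' Code 0 below the mean, 1 at or above it.
#' @param values Numeric vector (NA preserved).
#' @return A `binned_variable` with `scheme = "mean-split"`.
#' @export
bin_mean_split <- function(values) {
  v <- values[!is.na(values)]
  if (!length(v)) stop("bin_mean_split: no values")
  mu <- mean(v)
  codes <- ifelse(is.na(values), NA_integer_, ifelse(values < mu, 0L, 1L))
  structure(list(codes = codes, n_bins = 2L, scheme = "mean-split",
                 edges = mu),
            class = "binned_variable")
}

#' Categorical-to-integer mapping with merging
#'
#' Maps category labels 1-to-1 onto integer codes; when there are more than
#' `max_bins` categories, the most frequent `max_bins - 1` keep their own
#' code and the rest merge into a trailing "other" bin. Ties in frequency
#' are broken lexicographically.
#'
#' @param values Character/factor vector (NA preserved).
#' @param max_bins Maximum number of bins (default 3).
#' @return A `binned_variable` with `scheme = "categorical-map"` and a
#'   `levels` element naming each code.
#' @export
bin_categorical <- function(values, max_bins = 3L) {
  values <- as.character(values)
  v <- values[!is.na(values)]
  if (!length(v)) stop("bin_categorical: no values")
  freq <- sort(table(v), decreasing = TRUE)
  cats <- names(freq)[order(-as.vector(freq), names(freq))]
  if (length(cats) > max_bins) {
    keep <- cats[seq_len(max_bins - 1L)]
    lv <- c(keep, "other")
    codes <- ifelse(is.na(values), NA_integer_,
                    ifelse(values %in% keep,
                           match(values, keep) - 1L, max_bins - 1L))
  } else {
    lv <- cats
    codes <- match(values, cats) - 1L
  }
  structure(list(codes = as.integer(codes), n_bins = length(lv),
                 scheme = "categorical-map", levels = lv),
            class = "binned_variable")
}

#' Bin the secondary phenotypes
#'
#' Age and BMI get the three-bin mu +/- f s scheme; MMSE, the three CSF
#' biomarkers and their three ratios are split on the mean; APOE genotype is
#' category-mapped; `apoe4` is 1 iff the genotype contains the e4 allele;
#' smoking and race are category-mapped with merging beyond three levels.
#'
#' @param phenos A `pheno_table`.
#' @return Named list of `binned_variable`s for the 13 secondary phenotypes
#'   (those whose columns are present): age, bmi, mmse, abeta, ttau, ptau,
#'   abeta_ttau, abeta_ptau, ptau_ttau, apoe, apoe4, smoke, race.
#' @export
bin_secondary <- function(phenos) {
  out <- list()
  if ("age" %in% names(phenos)) out$age <- bin_tertile(phenos$age)
  if ("bmi" %in% names(phenos)) out$bmi <- bin_tertile(phenos$bmi)
  mean_split <- c(mmse = "mmse", abeta = "abeta42", ttau = "ttau",
                  ptau = "ptau181", abeta_ttau = "abeta_ttau",
                  abeta_ptau = "abeta_ptau", ptau_ttau = "ptau_ttau")
  for (nm in names(mean_split)) {
    col <- mean_split[[nm]]
    if (col %in% names(phenos)) out[[nm]] <- bin_mean_split(phenos[[col]])
  }
  if ("apoe" %in% names(phenos)) {
    out$apoe <- bin_categorical(phenos$apoe, max_bins = 3L)
    has_e4 <- grepl("4", phenos$apoe)
    codes <- ifelse(is.na(phenos$apoe), NA_integer_, as.integer(has_e4))
    out$apoe4 <- structure(list(codes = codes, n_bins = 2L,
                                scheme = "categorical-map",
                                levels = c("no-e4", "e4")),
                           class = "binned_variable")
  }
  if ("smoke" %in% names(phenos)) {
    sm <- as.character(phenos$smoke)
    bad <- !is.na(sm) & !(sm %in% c("no", "yes", "unknown"))
    if (any(bad))
      stop("bin_secondary: unknown smoke label(s): ",
           paste(unique(sm[bad]), collapse = ", "))
    out$smoke <- bin_categorical(sm, max_bins = 3L)
  }
  if ("race" %in% names(phenos)) out$race <- bin_categorical(phenos$race, 3L)
  out
}

#' Build the three primary binned variables from group labels
#'
#' `deployment` contrasts ComC (0) against combined DepC and DepTBI (1);
#' `tbi` contrasts combined ComC and DepC (0) against DepTBI (1); `exp_grp`
#' keeps the three groups apart (ComC 0, DepC 1, DepTBI 2).
#'
#' @param phenos A `pheno_table`.
#' @return Named list of three `binned_variable`s.
#' @export
build_primaries <- function(phenos) {
  g <- phenos$group
  mk <- function(codes, n_bins, levels) {
    structure(list(codes = as.integer(codes), n_bins = n_bins,
                   scheme = "categorical-map", levels = levels),
              class = "binned_variable")
  }
  list(
    deployment = mk(ifelse(g == "ComC", 0L, 1L), 2L, c("ComC", "Dep")),
    tbi = mk(ifelse(g == "DepTBI", 1L, 0L), 2L, c("noTBI", "TBI")),
    exp_grp = mk(match(g, c("ComC", "DepC", "DepTBI")) - 1L, 3L,
                 c("ComC", "DepC", "DepTBI")))
}

#' Discretize miRNA expression for the dependency search
#'
#' Each miRNA is three-binned by [bin_tertile()] fitted on its uncensored
#' delta-Cq values; censored cells are then forced into the highest-delta-Cq
#' (lowest expression) bin, because detection failure is informative
#' (`censored_policy = "lowest_bin"`, default) or dropped
#' (`censored_policy = "drop"`). Excluded cells are always missing. Probes
#' with fewer than 6 uncensored values or no variance fall back to a binary
#' detected/censored coding so that every assayable miRNA is scored.
#'
#' @param em An `expr_matrix` (typically unfiltered: the search scores the
#'   whole panel as background).
#' @param censored_policy "lowest_bin" or "drop".
#' @return Named list of `binned_variable`s, one per miRNA, each with a
#'   `codes` vector aligned to `em$samples`.
#' @export
bin_mirnas <- function(em, censored_policy = c("lowest_bin", "drop")) {
  censored_policy <- match.arg(censored_policy)
  out <- vector("list", length(em$mirnas))
  names(out) <- em$mirnas
  for (j in seq_along(em$mirnas)) {
    good <- !em$excluded[, j] & !em$censored[, j]
    vals <- em$dcq[, j]
    bv <- tryCatch({
      b <- bin_tertile(ifelse(good, vals, NA))
      codes <- b$codes
      if (censored_policy == "lowest_bin")
        codes[em$censored[, j]] <- b$n_bins - 1L
      b$codes <- codes
      b
    }, error = function(e) {
      # sparse/degenerate probe: detected (0) vs censored (1)
      codes <- rep(NA_integer_, length(vals))
      codes[good] <- 0L
      if (censored_policy == "lowest_bin") codes[em$censored[, j]] <- 1L
      structure(list(codes = codes, n_bins = 2L, scheme = "detected-split",
                     f = NA_real_, edges = NULL),
                class = "binned_variable")
    })
    out[[j]] <- bv
  }
  out
}

.score_list <- function(scores, ids, top_k = 20L, z_min = 1) {
  # scores: raw magnitudes (larger = stronger dependence)
  mu <- mean(scores); sdv <- stats::sd(scores)
  z <- if (is.na(sdv) || sdv == 0) rep(0, length(scores)) else (scores - mu) / sdv
  ord <- order(-z, ids)
  rank <- rep(NA_integer_, length(scores))
  sel <- ord[z[ord] > z_min]
  sel <- sel[seq_len(min(length(sel), top_k))]
  rank[sel] <- seq_along(sel)
  list(z = z, rank = rank)
}

#' Dependency search over miRNAs and phenotypes
#'
#' Runs the full search: one pairwise mutual-information list per primary
#' phenotype, one three-way symmetric-delta list per (primary, secondary)
#' pair, and one collective three-way list of each miRNA with deployment and
#' tbi together. With 3 primaries and 13 secondaries this yields
#' 3 + 39 + 1 = 43 lists. Every list scores all assayable miRNAs
#' (complete-case per list), converts raw magnitudes (|delta| for the delta
#' lists) to within-list z-scores, and ranks the top `top_k` miRNAs whose
#' z exceeds `z_min`.
#'
#' @param binned_mirnas Output of [bin_mirnas()].
#' @param primaries Output of [build_primaries()].
#' @param secondaries Output of [bin_secondary()].
#' @param top_k Maximum ranked set size per list (default 20).
#' @param z_min Ranking deviation threshold in SD units (default 1).
#' @param n_min Minimum usable samples for a list (default 10); below it the
#'   list is emitted empty with a warning.
#' @return Object of class `dep_search`: list of data.frames (one per list
#'   id) with columns mirna_id, measure, raw, z, rank, n.
#' @export
run_search <- function(binned_mirnas, primaries, secondaries,
                       top_k = 20L, z_min = 1, n_min = 10L) {
  lists <- list()
  mids <- names(binned_mirnas)

  score_one <- function(fun, measure, n_min) {
    raw <- numeric(length(mids)); ns <- integer(length(mids))
    for (i in seq_along(mids)) {
      r <- fun(binned_mirnas[[i]]$codes)
      raw[i] <- r[1]; ns[i] <- r[2]
    }
    if (!any(ns >= n_min)) return(NULL)
    data.frame(mirna_id = mids, measure = measure, raw = raw,
               n = ns, stringsAsFactors = FALSE)
  }

  finalize <- function(df, list_id) {
    if (is.null(df)) {
      warning("run_search: list ", list_id,
              " has fewer than n_min usable samples")
      return(data.frame(mirna_id = character(), measure = character(),
                        raw = numeric(), z = numeric(), rank = integer(),
                        n = integer(), stringsAsFactors = FALSE))
    }
    ok <- !is.na(df$raw)
    df$z <- NA_real_; df$rank <- NA_integer_
    sc <- .score_list(abs(df$raw[ok]), df$mirna_id[ok],
                      top_k = top_k, z_min = z_min)
    df$z[ok] <- sc$z; df$rank[ok] <- sc$rank
    df[c("mirna_id", "measure", "raw", "z", "rank", "n")]
  }

  for (pn in names(primaries)) {
    p <- primaries[[pn]]$codes
    id <- paste0("MI:", pn)
    lists[[id]] <- finalize(score_one(function(mc) {
      cc <- .complete(mc, p)
      n <- length(cc[[1]])
      if (n < n_min) return(c(NA_real_, n))
      c(mutual_information(cc[[1]], cc[[2]]), n)
    }, "MI", n_min), id)
  }
  for (pn in names(primaries)) {
    p <- primaries[[pn]]$codes
    for (sn in names(secondaries)) {
      s <- secondaries[[sn]]$codes
      id <- paste0("delta:", pn, ":", sn)
      lists[[id]] <- finalize(score_one(function(mc) {
        cc <- .complete(mc, p, s)
        n <- length(cc[[1]])
        if (n < n_min) return(c(NA_real_, n))
        c(symmetric_delta(cc[[1]], cc[[2]], cc[[3]])$delta_bar, n)
      }, "delta", n_min), id)
    }
  }
  # collective three-way dependence of miRNA with deployment and tbi
  if (all(c("deployment", "tbi") %in% names(primaries))) {
    p1 <- primaries$deployment$codes; p2 <- primaries$tbi$codes
    id <- "delta3:deployment:tbi"
    lists[[id]] <- finalize(score_one(function(mc) {
      cc <- .complete(mc, p1, p2)
      n <- length(cc[[1]])
      if (n < n_min) return(c(NA_real_, n))
      c(symmetric_delta(cc[[1]], cc[[2]], cc[[3]])$delta_bar, n)
    }, "delta", n_min), id)
  }
  structure(lists, class = "dep_search")
}

#' @export
print.dep_search <- function(x, ...) {
  cat("dependency search:", length(x), "lists over",
      if (length(x)) nrow(x[[1]]) else 0, "miRNAs\n")
  invisible(x)
}

#' All miRNAs ranked in at least one list
#' @param search A `dep_search`.
#' @return Character vector of miRNA ids.
#' @export
listed_mirnas <- function(search) {
  sort(unique(unlist(lapply(search, function(df)
    df$mirna_id[!is.na(df$rank)]))))
}

.z_of <- function(search, list_id, mirna) {
  df <- search[[list_id]]
  if (is.null(df) || !nrow(df)) return(0)
  i <- match(mirna, df$mirna_id)
  if (is.na(i) || is.na(df$z[i])) return(0)
  df$z[i]
}

#' Composite dependency scores per primary phenotype
#'
#' Aggregates within-list z-scores into one score per miRNA and primary:
#' the pairwise mutual-information z, plus half of (the maximum z over the
#' three correlated biomarker-ratio delta lists plus the apoe4 delta z),
#' plus a third of the age, bmi and smoke delta z's. Delta terms are
#' down-weighted because delta scores fluctuate more on small samples;
#' age/bmi/smoke carry the smaller weight because their anticipated effect
#' is small. Absent list entries contribute 0.
#'
#' @param search A `dep_search`.
#' @param primary One of the primary names used in the search.
#' @return data.frame of class `composite_scores`: mirna_id, value, and the
#'   named component z-scores.
#' @export
composite_scores <- function(search, primary) {
  mids <- sort(unique(unlist(lapply(search, `[[`, "mirna_id"))))
  if (!length(mids)) {
    out <- data.frame(mirna_id = character(), primary = character(),
                      value = numeric(), z_mi = numeric(),
                      z_ratio_max = numeric(), z_apoe4 = numeric(),
                      z_age = numeric(), z_bmi = numeric(),
                      z_smoke = numeric(), stringsAsFactors = FALSE)
    class(out) <- c("composite_scores", "data.frame")
    return(out)
  }
  ratio_lists <- paste0("delta:", primary, ":",
                        c("ptau_ttau", "abeta_ttau", "abeta_ptau"))
  rows <- lapply(mids, function(m) {
    z_mi <- .z_of(search, paste0("MI:", primary), m)
    z_ratio <- max(vapply(ratio_lists, .z_of, numeric(1),
                          search = search, mirna = m))
    z_apoe4 <- .z_of(search, paste0("delta:", primary, ":apoe4"), m)
    z_age <- .z_of(search, paste0("delta:", primary, ":age"), m)
    z_bmi <- .z_of(search, paste0("delta:", primary, ":bmi"), m)
    z_smoke <- .z_of(search, paste0("delta:", primary, ":smoke"), m)
    value <- z_mi + 0.5 * (z_ratio + z_apoe4) +
      (1 / 3) * (z_age + z_bmi + z_smoke)
    data.frame(mirna_id = m, primary = primary, value = value,
               z_mi = z_mi, z_ratio_max = z_ratio, z_apoe4 = z_apoe4,
               z_age = z_age, z_bmi = z_bmi, z_smoke = z_smoke,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("composite_scores", "data.frame")
  out
}

#' Stringent distribution-based filtering of composite scores
#'
#' Retains miRNAs whose composite score exceeds mean + `k_sd` SD of the
#' all-miRNA composite distribution for at least one primary (union over
#' primaries), intersected with the QC-passing miRNA set when given.
#'
#' @param score_list List of `composite_scores` data.frames (one per
#'   primary).
#' @param qc_pass Optional character vector of QC-passing miRNA ids.
#' @param k_sd Cutoff in SD units above the mean (default 2).
#' @return Character vector of selected miRNA ids (lexicographic).
#' @export
stringent_filter <- function(score_list, qc_pass = NULL, k_sd = 2) {
  sel <- character(0)
  for (cs in score_list) {
    mu <- mean(cs$value); sdv <- stats::sd(cs$value)
    if (is.na(sdv) || sdv == 0) next
    sel <- union(sel, cs$mirna_id[cs$value > mu + k_sd * sdv])
  }
  if (!is.null(qc_pass)) sel <- intersect(sel, qc_pass)
  sort(sel)
}

#' Write dependency-search output as CSVs
#'
#' One CSV per list plus a wide matrix of ranked-entry z-scores (miRNA by
#' list), mirroring a candidate-overview heatmap.
#'
#' @param search A `dep_search`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_search <- function(search, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (id in names(search)) {
    fn <- file.path(dir, paste0("list_", gsub("[^A-Za-z0-9_.-]", "_", id), ".csv"))
    utils::write.csv(search[[id]], fn, row.names = FALSE)
  }
  ranked <- listed_mirnas(search)
  if (length(ranked)) {
    mat <- sapply(names(search), function(id) {
      df <- search[[id]]
      z <- rep(NA_real_, length(ranked))
      i <- match(ranked, df$mirna_id)
      hit <- !is.na(i) & !is.na(df$rank[i])
      z[hit] <- df$z[i][hit]
      z
    })
    utils::write.csv(data.frame(mirna_id = ranked, mat, check.names = FALSE),
                     file.path(dir, "ranked_z_matrix.csv"), row.names = FALSE)
  }
  invisible(dir)
}
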