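#' QC parameters for amplification flagging
#'
#' Thresholds applied to every amplification record. An amplification is a
#' technical failure (`excluded`) when its amplification score falls below
#' `amp_score_min`; otherwise it is `censored` when no Cq was called or the
#' Cq is at or beyond `cq_ceiling` (the instrument's detection limit), and
#' `good` otherwise.
#'
#' @param cq_ceiling Detection ceiling in cycles. Cq values at or above this
#'   are below the detection limit and censored there. Default 34.
#' @param amp_score_min Minimum amplification score for a usable reaction.
#'   Default 1.0.
#' @return An object of class `qc_params`.
#' @export
qc_params <- function(cq_ceiling = 34, amp_score_min = 1.0) {
  stopifnot(is.numeric(cq_ceiling), length(cq_ceiling) == 1L, cq_ceiling > 0,
            is.numeric(amp_score_min), length(amp_score_min) == 1L)
  structure(list(cq_ceiling = cq_ceiling, amp_score_min = amp_score_min),
            class = "qc_params")
}

#' Probe panel description
#'
#' The set of probes on an array card: all probe ids, probes withdrawn a
#' priori (sequences no longer annotated as miRNAs), and non-miRNA control
#' probes (U6-class small RNAs). The analyzable set is
#' `setdiff(mirna_ids, union(withdrawn_ids, control_ids))`.
#'
#' @param mirna_ids Ordered character vector of probe ids. The canonical id is
#'   the miRNA name plus the probe number (names alone are ambiguous across
#'   probe lots).
#' @param withdrawn_ids Probes excluded a priori.
#' @param control_ids Non-miRNA control probes.
#' @return An object of class `probe_panel`.
#' @export
probe_panel <- function(mirna_ids, withdrawn_ids = character(),
                        control_ids = character()) {
  mirna_ids <- as.character(mirna_ids)
  withdrawn_ids <- as.character(withdrawn_ids)
  control_ids <- as.character(control_ids)
  if (anyDuplicated(mirna_ids))
    stop("probe_panel: duplicated probe ids")
  structure(list(mirna_ids = mirna_ids,
                 withdrawn_ids = withdrawn_ids,
                 control_ids = control_ids),
            class = "probe_panel")
}

#' Analyzable probes of a panel
#' @param panel A [probe_panel()].
#' @return Character vector of probe ids that are neither withdrawn nor controls.
#' @export
analyzable_ids <- function(panel) {
  setdiff(panel$mirna_ids, union(panel$withdrawn_ids, panel$control_ids))
}

#' Flag amplifications by QC rules
#'
#' Total flagging function: every (Cq, amplification-score) pair receives
#' exactly one of `excluded`, `censored`, `good`. Exclusion (technical
#' failure) takes precedence over censoring.
#'
#' @param cq Numeric vector of Cq values; `NA` means no amplification called.
#' @param amp_score Numeric vector of amplification scores (recycled).
#' @param qc A [qc_params()].
#' @return Character vector of flags, one per input element.
#' @examples
#' flag_amplification(c(33, 35, NA, 33), c(1.2, 1.5, 1.1, 0.5))
#' @export
flag_amplification <- function(cq, amp_score, qc = qc_params()) {
  stopifnot(inherits(qc, "qc_params"))
  n <- max(length(cq), length(amp_score))
  cq <- rep_len(as.numeric(cq), n)
  amp_score <- rep_len(as.numeric(amp_score), n)
  if (any(!is.na(cq) & cq < 0))
    stop("flag_amplification: negative Cq is invalid")
  flag <- rep("good", n)
  flag[is.na(cq) | cq >= qc$cq_ceiling] <- "censored"
  # amp_score NA (e.g. wide-format input without scores) never excludes
  flag[!is.na(amp_score) & amp_score < qc$amp_score_min] <- "excluded"
  flag
}

.parse_cq <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  x <- trimws(as.character(x))
  x[x %in% c("", "NA", "Undetermined", "undetermined", "Undetected", "undetected")] <- NA
  suppressWarnings(as.numeric(x))
}

.read_delim_auto <- function(path) {
  header <- readLines(path, n = 1L)
  if (length(header) == 0L)
    return(utils::read.csv(text = "", stringsAsFactors = FALSE))
  sep <- if (grepl("\t", header)) "\t" else ","
  utils::read.delim(path, sep = sep, stringsAsFactors = FALSE,
                    check.names = FALSE)
}

# Map loosely-named instrument export columns onto canonical names.
.canon_amp_cols <- c(sample_id = "sample", mirna_id = "probe", cq = "cq",
                     amp_score = "ampscore", cq_conf = "cqconf")

.match_col <- function(nms, keys) {
  low <- tolower(gsub("[ ._-]", "", nms))
  for (k in keys) {
    hit <- which(low == k)
    if (length(hit)) return(hit[1L])
  }
  NA_integer_
}

#' Read amplification records from a delimited export
#'
#' Accepts the canonical long format (one row per reaction, columns for
#' sample, probe, Cq, amplification score and Cq confidence) or a wide
#' samples-by-probes Cq matrix, auto-detected from the header. Cq cells
#' reading "Undetermined", "Undetected", "NA" or empty are taken as absent.
#' Probes withdrawn in the panel are dropped; QC flags are assigned with
#' [flag_amplification()].
#'
#' @param path Path to a CSV/TSV file.
#' @param panel Optional [probe_panel()]; when given, rows for withdrawn
#'   probes are removed.
#' @param qc A [qc_params()].
#' @return A data.frame of class `amp_records` with columns `sample_id`,
#'   `mirna_id`, `cq`, `amp_score`, `cq_conf`, `flag`.
#' @export
read_amplifications <- function(path, panel = NULL, qc = qc_params()) {
  df <- .read_delim_auto(path)
  if (nrow(df) == 0L && ncol(df) <= 1L)
    return(amp_records(data.frame(sample_id = character(), mirna_id = character(),
                                  cq = numeric(), amp_score = numeric(),
                                  cq_conf = numeric()), qc = qc, panel = panel))
  nms <- names(df)
  i_sample <- .match_col(nms, c("sample", "sampleid", "samplename"))
  i_probe  <- .match_col(nms, c("probe", "probeid", "mirna", "mirnaid", "target",
                                "targetname", "assay"))
  if (is.na(i_sample))
    stop("read_amplifications: schema error, no sample column found")
  if (is.na(i_probe)) {
    # wide format: first column samples, remaining columns one probe each.
    # A metric column without a probe column is a malformed long file, not a
    # wide one.
    metric <- vapply(nms[-i_sample], function(nm)
      !is.na(.match_col(nm, c("cq", "ct", "cqvalue", "ampscore",
                              "amplificationscore", "cqconf",
                              "cqconfidence", "conf"))), logical(1))
    if (any(metric) || length(nms) < 2L)
      stop("read_amplifications: schema error, no probe column found")
    long <- data.frame(
      sample_id = rep(as.character(df[[i_sample]]), times = ncol(df) - 1L),
      mirna_id  = rep(nms[-i_sample], each = nrow(df)),
      cq        = .parse_cq(unlist(df[-i_sample], use.names = FALSE)),
      amp_score = NA_real_,
      cq_conf   = NA_real_,
      stringsAsFactors = FALSE)
    return(amp_records(long, qc = qc, panel = panel))
  }
  i_cq   <- .match_col(nms, c("cq", "ct", "cqvalue"))
  if (is.na(i_cq))
    stop("read_amplifications: schema error, no Cq column found")
  i_amp  <- .match_col(nms, c("ampscore", "amplificationscore"))
  i_conf <- .match_col(nms, c("cqconf", "cqconfidence", "conf"))
  long <- data.frame(
    sample_id = as.character(df[[i_sample]]),
    mirna_id  = as.character(df[[i_probe]]),
    cq        = .parse_cq(df[[i_cq]]),
    amp_score = if (is.na(i_amp)) NA_real_ else as.numeric(df[[i_amp]]),
    cq_conf   = if (is.na(i_conf)) NA_real_ else as.numeric(df[[i_conf]]),
    stringsAsFactors = FALSE)
  amp_records(long, qc = qc, panel = panel)
}

#' Construct an amplification record collection
#'
#' Validates, drops withdrawn probes, and (re)assigns QC flags.
#'
#' @param df data.frame with columns `sample_id`, `mirna_id`, `cq`,
#'   `amp_score`, `cq_conf`.
#' @param qc A [qc_params()].
#' @param panel Optional [probe_panel()].
#' @return data.frame of class `amp_records`.
#' @export
amp_records <- function(df, qc = qc_params(), panel = NULL) {
  need <- c("sample_id", "mirna_id", "cq", "amp_score", "cq_conf")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("amp_records: schema error, missing column(s): ",
         paste(miss, collapse = ", "))
  df <- df[need]
  df$sample_id <- as.character(df$sample_id)
  df$mirna_id <- as.character(df$mirna_id)
  if (!is.null(panel))
    df <- df[!(df$mirna_id %in% panel$withdrawn_ids), , drop = FALSE]
  key <- paste(df$sample_id, df$mirna_id, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup))
    stop("amp_records: duplicate (sample, probe) pair: ",
         df$sample_id[dup[1L]], " / ", df$mirna_id[dup[1L]])
  df$flag <- flag_amplification(df$cq, df$amp_score, qc)
  rownames(df) <- NULL
  attr(df, "qc") <- qc
  class(df) <- c("amp_records", "data.frame")
  df
}

#' Write amplification records to canonical long CSV
#' @param records An `amp_records` data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_amplifications <- function(records, path) {
  utils::write.csv(as.data.frame(records), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Per-miRNA QC flag summary
#'
#' Counts of good/censored/excluded reactions per probe, optionally split by
#' participant group (mirrors the per-group flag summary of array QC reports).
#'
#' @param records An `amp_records` data.frame.
#' @param phenos Optional phenotype table with `sample_id` and `group`.
#' @return data.frame with one row per probe (and group, if given).
#' @export
qc_summary <- function(records, phenos = NULL) {
  df <- as.data.frame(records)
  if (!is.null(phenos)) {
    df$group <- phenos$group[match(df$sample_id, phenos$sample_id)]
    tab <- as.data.frame(table(mirna_id = df$mirna_id, group = df$group,
                               flag = df$flag))
    out <- stats::reshape(tab, idvar = c("mirna_id", "group"),
                          timevar = "flag", direction = "wide")
  } else {
    tab <- as.data.frame(table(mirna_id = df$mirna_id, flag = df$flag))
    out <- stats::reshape(tab, idvar = "mirna_id", timevar = "flag",
                          direction = "wide")
  }
  names(out) <- sub("^Freq\\.", "n_", names(out))
  for (f in c("n_good", "n_censored", "n_excluded"))
    if (!f %in% names(out)) out[[f]] <- 0L
  rownames(out) <- NULL
  out
}

.pheno_groups <- c("ComC", "DepC", "DepTBI")

#' Read a per-sample phenotype table
#'
#' Expected columns: `sample_id`, `group` (one of ComC/DepC/DepTBI), and any
#' of `age`, `bmi`, `mmse`, `abeta42`, `ttau`, `ptau181`, `apoe`, `smoke`,
#' `race`, `n_tbi`, `years_since_tbi`. Biomarker ratios `abeta_ttau`,
#' `abeta_ptau` and `ptau_ttau` are derived where both components are
#' present. Missing cells are permitted everywhere except `group`.
#'
#' @param path Path to a CSV/TSV file.
#' @param samples Optional character vector of expected sample ids (e.g. from
#'   the amplification data); mismatches raise a warning, not an error.
#' @return data.frame of class `pheno_table`.
#' @export
read_phenotypes <- function(path, samples = NULL) {
  df <- .read_delim_auto(path)
  pheno_table(df, samples = samples)
}

#' Construct/validate a phenotype table
#' @param df data.frame with at least `sample_id` and `group`.
#' @param samples Optional expected sample ids.
#' @return data.frame of class `pheno_table` with derived ratio columns.
#' @export
pheno_table <- function(df, samples = NULL) {
  if (!all(c("sample_id", "group") %in% names(df)))
    stop("pheno_table: schema error, need sample_id and group columns")
  df$sample_id <- as.character(df$sample_id)
  df$group <- as.character(df$group)
  if (anyNA(df$group) || !all(df$group %in% .pheno_groups))
    stop("pheno_table: schema error, group must be one of ",
         paste(.pheno_groups, collapse = "/"))
  num_cols <- c("age", "bmi", "mmse", "abeta42", "ttau", "ptau181",
                "n_tbi", "years_since_tbi")
  for (cc in intersect(num_cols, names(df)))
    df[[cc]] <- suppressWarnings(as.numeric(df[[cc]]))
  if (all(c("abeta42", "ttau") %in% names(df)))
    df$abeta_ttau <- df$abeta42 / df$ttau
  if (all(c("abeta42", "ptau181") %in% names(df)))
    df$abeta_ptau <- df$abeta42 / df$ptau181
  if (all(c("ptau181", "ttau") %in% names(df)))
    df$ptau_ttau <- df$ptau181 / df$ttau
  if (!is.null(samples)) {
    only_p <- setdiff(df$sample_id, samples)
    only_a <- setdiff(samples, df$sample_id)
    if (length(only_p) || length(only_a))
      warning("pheno_table: sample ids not matching amplification data: ",
              paste(c(only_p, only_a), collapse = ", "))
  }
  rownames(df) <- NULL
  class(df) <- c("pheno_table", "data.frame")
  df
}
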