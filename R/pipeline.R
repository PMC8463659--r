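#' Pipeline run configuration
#'
#' All tunable thresholds of the pipeline in one serializable object.
#' Defaults are the analysis defaults: Cq ceiling 34, AmpScore minimum 1.0,
#' geNorm pairwise-variation threshold 0.1527, failure/detection filter
#' fractions 0.20/0.10, significance level 0.025 on raw p, binning factor
#' grid (0, 2] in 0.01 steps, composite weights 1, 1/2, 1/3, stringent
#' cutoff mean + 2 SD.
#'
#' @param cq_ceiling,amp_score_min See [qc_params()].
#' @param ec_detect_frac,ec_amp_score_min,ec_cq_max,ec_cq_conf_min See
#'   [ec_criteria()].
#' @param v_threshold geNorm stopping threshold.
#' @param fail_frac_max,detect_frac_min See [filter_mirnas()].
#' @param alpha Significance level for both contrast analyses.
#' @param f_max,f_step Binning factor grid upper bound and step.
#' @param top_k,z_min,n_min Dependency-search ranking parameters.
#' @param stringent_k_sd Stringent-filter cutoff in SD units.
#' @param censored_policy miRNA binning policy, see [bin_mirnas()].
#' @param fc_policy Fold-change censoring policy, see [fold_change()].
#' @param seed RNG seed for the simulate stage.
#' @return Object of class `run_config`.
#' @export
run_config <- function(cq_ceiling = 34, amp_score_min = 1.0,
                       ec_detect_frac = 1.0, ec_amp_score_min = 1,
                       ec_cq_max = 30, ec_cq_conf_min = 0.8,
                       v_threshold = 0.1527,
                       fail_frac_max = 0.20, detect_frac_min = 0.10,
                       alpha = 0.025, f_max = 2, f_step = 0.01,
                       top_k = 20L, z_min = 1, n_min = 10L,
                       stringent_k_sd = 2,
                       censored_policy = "lowest_bin",
                       fc_policy = "substitute", seed = 1L) {
  cfg <- as.list(environment())
  int_fields <- c("top_k", "n_min", "seed")
  chr_fields <- c("censored_policy", "fc_policy")
  for (nm in names(cfg)) {
    cfg[[nm]] <- if (nm %in% int_fields) as.integer(cfg[[nm]])
    else if (nm %in% chr_fields) as.character(cfg[[nm]])
    else as.numeric(cfg[[nm]])
  }
  stopifnot(cq_ceiling > 0, amp_score_min > 0, v_threshold > 0,
            fail_frac_max > 0, detect_frac_min > 0, alpha > 0,
            f_max > 0, f_step > 0, top_k > 0, z_min > 0, n_min > 0,
            stringent_k_sd > 0)
  structure(cfg, class = "run_config")
}

#' Serialize / restore a run configuration (JSON, round-trip identical)
#' @param config A [run_config()].
#' @param path File path.
#' @return `path` (write) or a `run_config` (read).
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, x)
}

.stage_log <- function(stage, n_in, n_out, note = "") {
  message(sprintf("[%s] n_in=%s n_out=%s %s", stage, n_in, n_out, note))
}

#' Run the full analysis pipeline
#'
#' Executes QC flagging, endogenous-control selection, delta-Cq
#' normalization, miRNA filtering, differential expression and detection,
#' per-group covariate regressions, the dependency search, composite scoring
#' and stringent filtering; writes every stage table as CSV plus a JSON run
#' manifest with per-stage counts.
#'
#' @param records An `amp_records` data.frame.
#' @param phenos A `pheno_table`.
#' @param panel Optional [probe_panel()].
#' @param config A [run_config()].
#' @param out_dir Output directory (created).
#' @return Invisibly, a list with every stage result and the manifest.
#' @export
run_all <- function(records, phenos, panel = NULL, config = run_config(),
                    out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  qc <- qc_params(config$cq_ceiling, config$amp_score_min)
  crit <- ec_criteria(config$ec_detect_frac, config$ec_amp_score_min,
                      config$ec_cq_max, config$ec_cq_conf_min)

  write_amplifications(records, file.path(out_dir, "amplifications_qc.csv"))
  utils::write.csv(qc_summary(records, phenos),
                   file.path(out_dir, "qc_summary.csv"), row.names = FALSE)

  cand <- select_ec_candidates(records, panel, crit)
  df <- as.data.frame(records)
  cand_rows <- df[df$mirna_id %in% cand, ]
  cq_tab <- tapply(cand_rows$cq,
                   list(cand_rows$sample_id, cand_rows$mirna_id), mean)
  ranking <- stability_rank(cq_tab, v_threshold = config$v_threshold)
  write_ec_report(ranking, file.path(out_dir, "ec_report.csv"))
  .stage_log("ec_selection", length(cand), length(ranking$selected_ecs))

  analyzable <- if (is.null(panel)) NULL else analyzable_ids(panel)
  em_full <- normalize_dcq(records, ranking$selected_ecs, qc,
                           mirnas = analyzable)
  write_expr_matrix(em_full, file.path(out_dir, "expression_full"))
  em <- filter_mirnas(em_full, config$fail_frac_max, config$detect_frac_min)
  write_expr_matrix(em, file.path(out_dir, "expression_filtered"))
  .stage_log("filter_mirnas", length(em_full$mirnas), length(em$mirnas))

  de <- run_contrasts(em, phenos, alpha = config$alpha,
                      fc_policy = config$fc_policy)
  utils::write.csv(de, file.path(out_dir, "differential_expression.csv"),
                   row.names = FALSE)
  det <- run_detection_contrasts(em, phenos, alpha = config$alpha)
  utils::write.csv(det, file.path(out_dir, "differential_detection.csv"),
                   row.names = FALSE)
  sig_mirnas <- union(de$mirna_id[de$significant],
                      det$mirna_id[det$significant])
  assoc <- if (length(sig_mirnas))
    run_associations(em, phenos, mirnas = intersect(sig_mirnas, em$mirnas))
  else NULL
  if (!is.null(assoc))
    utils::write.csv(assoc, file.path(out_dir, "associations.csv"),
                     row.names = FALSE)

  bm <- bin_mirnas(em_full, censored_policy = config$censored_policy)
  primaries <- build_primaries(phenos)
  # align phenotype codes to the matrix sample order
  idx <- match(em_full$samples, phenos$sample_id)
  primaries <- lapply(primaries, function(b) { b$codes <- b$codes[idx]; b })
  secondaries <- lapply(bin_secondary(phenos),
                        function(b) { b$codes <- b$codes[idx]; b })
  search <- run_search(bm, primaries, secondaries, top_k = config$top_k,
                       z_min = config$z_min, n_min = config$n_min)
  write_search(search, file.path(out_dir, "dependency_lists"))

  cs <- lapply(names(primaries), function(pn) composite_scores(search, pn))
  names(cs) <- names(primaries)
  for (pn in names(cs))
    utils::write.csv(cs[[pn]],
                     file.path(out_dir, paste0("composite_", pn, ".csv")),
                     row.names = FALSE)
  filtered <- stringent_filter(cs, qc_pass = em$mirnas,
                               k_sd = config$stringent_k_sd)
  utils::write.csv(data.frame(mirna_id = filtered),
                   file.path(out_dir, "stringent_candidates.csv"),
                   row.names = FALSE)

  manifest <- list(
    config = unclass(config),
    counts = list(
      samples = length(unique(records$sample_id)),
      probes_assayed = length(unique(records$mirna_id)),
      ec_candidates = length(cand),
      ecs_selected = length(ranking$selected_ecs),
      mirnas_qc_passed = length(em$mirnas),
      de_significant = sum(de$significant, na.rm = TRUE),
      de_by_contrast = as.list(tapply(de$significant, de$contrast, sum)),
      det_significant = sum(det$significant, na.rm = TRUE),
      det_by_contrast = as.list(tapply(det$significant, det$contrast, sum)),
      dependency_lists = length(search),
      mirnas_listed = length(listed_mirnas(search)),
      stringent_candidates = length(filtered)))
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(ec_candidates = cand, ranking = ranking, em_full = em_full,
                 em = em, de = de, det = det, assoc = assoc, search = search,
                 composite = cs, stringent = filtered, manifest = manifest))
}

#' Command-line entry point
#'
#' Subcommands: `simulate` (write synthetic records, phenotypes and truth
#' manifest), `all` (run the full pipeline on amplification and phenotype
#' CSVs), and the single-stage commands `qc`, `normalize`, `de`, `detect`,
#' `assoc`, `deps`, `composite`, `filter`, which re-run one stage from the
#' CSVs a previous `all` (or earlier stage) left in `--out-dir`. Global
#' flags: `--config` (JSON run configuration), `--seed`, `--out-dir`,
#' `--records`, `--phenotypes`.
#'
#' @param args Character vector of command-line arguments (default: the
#'   process arguments).
#' @return Exit status 0, invisibly.
#' @export
qpcr_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args))
    stop("usage: qpcrcens <simulate|all|qc|normalize|de|detect|assoc|deps|",
         "composite|filter> [--config F] [--seed N] [--out-dir D] ",
         "[--records F] [--phenotypes F]")
  cmd <- args[1L]
  opts <- list(seed = 1L, out_dir = "qpcrcens_out", config = NULL,
               records = NULL, phenotypes = NULL)
  i <- 2L
  while (i <= length(args)) {
    key <- sub("^--", "", args[i])
    key <- gsub("-", "_", key)
    if (!key %in% names(opts)) stop("unknown flag: ", args[i])
    opts[[key]] <- args[i + 1L]
    i <- i + 2L
  }
  cfg <- if (!is.null(opts$config)) read_run_config(opts$config)
  else run_config()
  cfg$seed <- as.integer(opts$seed)
  dir.create(opts$out_dir, showWarnings = FALSE, recursive = TRUE)

  load_inputs <- function() {
    stopifnot(!is.null(opts$records), !is.null(opts$phenotypes))
    qc <- qc_params(cfg$cq_ceiling, cfg$amp_score_min)
    records <- read_amplifications(opts$records, qc = qc)
    phenos <- read_phenotypes(opts$phenotypes,
                              samples = unique(records$sample_id))
    list(records = records, phenos = phenos)
  }

  if (cmd == "simulate") {
    sim <- simulate_qpcr(sim_config(seed = cfg$seed))
    write_amplifications(sim$records,
                         file.path(opts$out_dir, "amplifications.csv"))
    utils::write.csv(as.data.frame(sim$phenotypes),
                     file.path(opts$out_dir, "phenotypes.csv"),
                     row.names = FALSE, na = "")
    jsonlite::write_json(
      list(seed = sim$truth$seed, ecs = sim$truth$ecs,
           group_sizes = as.list(sim$truth$group_sizes),
           flaky_probes = sim$truth$flaky_probes,
           level_effects = sim$truth$level_effects,
           detection_effects = sim$truth$detection_effects,
           synergy_effects = sim$truth$synergy_effects),
      file.path(opts$out_dir, "truth_manifest.json"),
      auto_unbox = TRUE, digits = NA)
  } else if (cmd == "all") {
    inp <- load_inputs()
    run_all(inp$records, inp$phenos, config = cfg, out_dir = opts$out_dir)
  } else if (cmd == "qc") {
    inp <- load_inputs()
    write_amplifications(inp$records,
                         file.path(opts$out_dir, "amplifications_qc.csv"))
    utils::write.csv(qc_summary(inp$records, inp$phenos),
                     file.path(opts$out_dir, "qc_summary.csv"),
                     row.names = FALSE)
  } else if (cmd == "normalize") {
    inp <- load_inputs()
    qc <- qc_params(cfg$cq_ceiling, cfg$amp_score_min)
    cand <- select_ec_candidates(inp$records,
                                 crit = ec_criteria(cfg$ec_detect_frac,
                                                    cfg$ec_amp_score_min,
                                                    cfg$ec_cq_max,
                                                    cfg$ec_cq_conf_min))
    df <- as.data.frame(inp$records)
    cr <- df[df$mirna_id %in% cand, ]
    cq_tab <- tapply(cr$cq, list(cr$sample_id, cr$mirna_id), mean)
    ranking <- stability_rank(cq_tab, v_threshold = cfg$v_threshold)
    write_ec_report(ranking, file.path(opts$out_dir, "ec_report.csv"))
    em <- normalize_dcq(inp$records, ranking$selected_ecs, qc)
    write_expr_matrix(em, file.path(opts$out_dir, "expression_full"))
    emf <- filter_mirnas(em, cfg$fail_frac_max, cfg$detect_frac_min)
    write_expr_matrix(emf, file.path(opts$out_dir, "expression_filtered"))
  } else if (cmd %in% c("de", "detect", "assoc", "deps", "composite",
                        "filter")) {
    stopifnot(!is.null(opts$phenotypes))
    phenos <- read_phenotypes(opts$phenotypes)
    emf <- read_expr_matrix(file.path(opts$out_dir, "expression_filtered"))
    if (cmd == "de") {
      utils::write.csv(run_contrasts(emf, phenos, alpha = cfg$alpha,
                                     fc_policy = cfg$fc_policy),
                       file.path(opts$out_dir, "differential_expression.csv"),
                       row.names = FALSE)
    } else if (cmd == "detect") {
      utils::write.csv(run_detection_contrasts(emf, phenos, alpha = cfg$alpha),
                       file.path(opts$out_dir, "differential_detection.csv"),
                       row.names = FALSE)
    } else if (cmd == "assoc") {
      utils::write.csv(run_associations(emf, phenos),
                       file.path(opts$out_dir, "associations.csv"),
                       row.names = FALSE)
    } else {
      em_full <- read_expr_matrix(file.path(opts$out_dir, "expression_full"))
      idx <- match(em_full$samples, phenos$sample_id)
      primaries <- lapply(build_primaries(phenos),
                          function(b) { b$codes <- b$codes[idx]; b })
      secondaries <- lapply(bin_secondary(phenos),
                            function(b) { b$codes <- b$codes[idx]; b })
      search <- run_search(bin_mirnas(em_full,
                                      censored_policy = cfg$censored_policy),
                           primaries, secondaries, top_k = cfg$top_k,
                           z_min = cfg$z_min, n_min = cfg$n_min)
      if (cmd == "deps") {
        write_search(search, file.path(opts$out_dir, "dependency_lists"))
      } else {
        cs <- lapply(names(primaries),
                     function(pn) composite_scores(search, pn))
        names(cs) <- names(primaries)
        if (cmd == "composite") {
          for (pn in names(cs))
            utils::write.csv(cs[[pn]],
                             file.path(opts$out_dir,
                                       paste0("composite_", pn, ".csv")),
                             row.names = FALSE)
        } else {
          filtered <- stringent_filter(cs, qc_pass = emf$mirnas,
                                       k_sd = cfg$stringent_k_sd)
          utils::write.csv(data.frame(mirna_id = filtered),
                           file.path(opts$out_dir,
                                     "stringent_candidates.csv"),
                           row.names = FALSE)
        }
      }
    }
  } else {
    stop("unknown subcommand: ", cmd)
  }
  invisible(0L)
}
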