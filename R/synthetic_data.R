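#' Configuration for the synthetic qPCR array generator
#'
#' Defaults state the world the analysis assumes: three participant groups
#' of 52/18/45, a 377-probe miRNA panel plus three non-miRNA control probes,
#' per-probe baseline Cq in 24-33 cycles and biological SD 0.4-1.5, a
#' card-level sample random effect (SD 0.3) that endogenous-control
#' normalization must remove, mechanistic detection censoring at the Cq-34
#' ceiling, three planted stable endogenous controls, and a 1% overall
#' technical-failure rate realized as a probe-level mixture (a `flaky_frac`
#' share of probes fail in `failure_rate / flaky_frac` of their reactions;
#' real qPCR failures cluster by primer/probe lot, and per-reaction i.i.d.
#' failures would make 100%-presence endogenous-control candidacy
#' unattainable).
#'
#' @param n_comc,n_depc,n_deptbi Group sizes (default 52/18/45).
#' @param n_mirnas Panel size including the planted ECs (default 377).
#' @param n_ecs Planted endogenous controls (default 3).
#' @param baseline_range Per-probe baseline Cq range (default c(24, 33)).
#' @param sd_range Per-probe biological SD range (default c(0.4, 1.5)).
#' @param ec_baseline_range Baseline range for ECs (default c(24, 27)).
#' @param ec_sd EC biological SD (default 0.1, within the <= 0.15 world).
#' @param sample_effect_sd Card-to-card offset SD (default 0.3).
#' @param cq_ceiling Detection ceiling (default 34).
#' @param failure_rate Overall technical-failure rate (default 0.01).
#' @param flaky_frac Fraction of probes carrying the failures (default 0.05).
#' @param level_effects data.frame(mirna_id, group, dcq_shift): the group's
#'   latent Cq (hence delta-Cq) is shifted by `dcq_shift`.
#' @param detection_effects data.frame(mirna_id, group, detect_prob,
#'   base_detect_prob): the probe's latent mean is set so that detection
#'   probability is `base_detect_prob` everywhere and `detect_prob` in
#'   `group`.
#' @param synergy_effects data.frame(mirna_id, strength): the probe's latent
#'   Cq is shifted by `strength` cycles in samples where deployment XOR tbi
#'   is 1 (the DepC group), creating a parity-style purely collective
#'   three-way dependence with the deployment and tbi variables.
#' @param seed RNG seed.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_comc = 52L, n_depc = 18L, n_deptbi = 45L,
                       n_mirnas = 377L, n_ecs = 3L,
                       baseline_range = c(24, 33), sd_range = c(0.4, 1.5),
                       ec_baseline_range = c(24, 27), ec_sd = 0.1,
                       sample_effect_sd = 0.3, cq_ceiling = 34,
                       failure_rate = 0.01, flaky_frac = 0.05,
                       level_effects = NULL, detection_effects = NULL,
                       synergy_effects = NULL, seed = 1L) {
  stopifnot(n_comc >= 2L, n_depc >= 2L, n_deptbi >= 2L, n_ecs >= 2L,
            n_mirnas > n_ecs)
  # a probe may carry only one kind of planted effect
  eff_ids <- c(if (!is.null(level_effects)) level_effects$mirna_id,
               if (!is.null(detection_effects)) detection_effects$mirna_id,
               if (!is.null(synergy_effects)) synergy_effects$mirna_id)
  kinds <- c(rep("level", NROW(level_effects)),
             rep("detection", NROW(detection_effects)),
             rep("synergy", NROW(synergy_effects)))
  if (length(eff_ids)) {
    tab <- rowSums(table(eff_ids, kinds) > 0)
    if (any(tab > 1))
      stop("sim_config: contradictory plantings on ",
           paste(names(tab)[tab > 1], collapse = ", "))
  }
  structure(list(n_comc = n_comc, n_depc = n_depc, n_deptbi = n_deptbi,
                 n_mirnas = n_mirnas, n_ecs = n_ecs,
                 baseline_range = baseline_range, sd_range = sd_range,
                 ec_baseline_range = ec_baseline_range, ec_sd = ec_sd,
                 sample_effect_sd = sample_effect_sd, cq_ceiling = cq_ceiling,
                 failure_rate = failure_rate, flaky_frac = flaky_frac,
                 level_effects = level_effects,
                 detection_effects = detection_effects,
                 synergy_effects = synergy_effects, seed = seed),
            class = "sim_config")
}

.rtrunc_norm <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < lo | x > hi)
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] < lo | x[bad] > hi]
  }
  x
}

.rlnorm_moments <- function(n, m, s) {
  # lognormal with target arithmetic mean m and SD s
  cv2 <- (s / m)^2
  sdlog <- sqrt(log(1 + cv2))
  meanlog <- log(m) - sdlog^2 / 2
  stats::rlnorm(n, meanlog, sdlog)
}

.sim_phenotypes <- function(groups) {
  n <- length(groups)
  gi <- match(groups, c("ComC", "DepC", "DepTBI"))
  pick <- function(v) v[gi]
  age <- .rtrunc_norm(n, pick(c(33.4, 31.8, 34.0)), pick(c(9.3, 7.1, 10.0)),
                      lo = 20, hi = 65)
  bmi <- .rtrunc_norm(n, pick(c(25.1, 26.9, 28.5)), pick(c(3.4, 4.3, 4.4)),
                      lo = 16)
  mmse <- round(pmin(30, .rtrunc_norm(n, pick(c(29.5, 29.1, 28.5)),
                                      pick(c(0.6, 1.1, 1.6)), hi = 30.49)))
  abeta42 <- .rlnorm_moments(n, pick(c(321.4, 309.5, 316.0)),
                             pick(c(54.2, 70.3, 55.8)))
  ttau <- .rlnorm_moments(n, pick(c(42.9, 35.2, 37.5)),
                          pick(c(17.3, 14.1, 13.7)))
  ptau181 <- .rlnorm_moments(n, pick(c(27.8, 28.7, 28.2)),
                             pick(c(9.3, 8.9, 6.4)))
  # e4 carrier frequency and genotyping dropout follow the study structure
  p_e4 <- pick(c(14 / 51, 9 / 17, 10 / 40))
  p_na <- pick(c(1 / 52, 1 / 18, 5 / 45))
  carrier <- stats::runif(n) < p_e4
  homo <- stats::runif(n) < 0.1
  apoe <- ifelse(carrier, ifelse(homo, "e4/e4", "e3/e4"),
                 ifelse(stats::runif(n) < 0.12, "e2/e3", "e3/e3"))
  apoe[stats::runif(n) < p_na] <- NA
  p_yes <- pick(c(2 / 52, 1 / 18, 14 / 45))
  p_unk <- pick(c(0, 0, 1 / 45))
  u <- stats::runif(n)
  smoke <- ifelse(u < p_yes, "yes", ifelse(u < p_yes + p_unk, "unknown", "no"))
  race <- sample(c("White", "Black", "Asian/PI", "AmInd", "Other"), n,
                 replace = TRUE, prob = c(0.72, 0.035, 0.104, 0.026, 0.115))
  n_tbi <- ifelse(groups == "DepTBI",
                  pmax(1, round(stats::rlnorm(n, 2.47, 1.0))), 0)
  years_since_tbi <- ifelse(groups == "DepTBI",
                            .rtrunc_norm(n, 4.7, 2.2, lo = 1.5, hi = 11.5),
                            NA_real_)
  data.frame(sample_id = sprintf("S%03d", seq_len(n)), group = groups,
             age = age, bmi = bmi, mmse = mmse, abeta42 = abeta42,
             ttau = ttau, ptau181 = ptau181, apoe = apoe, smoke = smoke,
             race = race, n_tbi = n_tbi, years_since_tbi = years_since_tbi,
             stringsAsFactors = FALSE)
}

#' Simulate a censored qPCR array study
#'
#' Draws latent per-reaction Cq values as probe baseline + planted group
#' effects + a shared per-sample card offset + probe-level noise; reactions
#' whose latent Cq reaches the ceiling are emitted as censored records with
#' no Cq (so detection and level effects are mechanistically coupled).
#' Technical failures get a sub-threshold amplification score. Phenotypes
#' are drawn per group with the study's location/scale structure. Identical
#' seeds give identical output.
#'
#' @param config A [sim_config()].
#' @return List with `records` (an `amp_records` data.frame), `phenotypes`
#'   (a `pheno_table`), `panel` (a [probe_panel()], three U6-class control
#'   probes included), and `truth` (manifest of every planted quantity).
#' @export
simulate_qpcr <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  groups <- rep(c("ComC", "DepC", "DepTBI"),
                c(config$n_comc, config$n_depc, config$n_deptbi))
  n_s <- length(groups)
  samples <- sprintf("S%03d", seq_len(n_s))

  n_reg <- config$n_mirnas - config$n_ecs
  reg_ids <- sprintf("sim-miR-%03d", seq_len(n_reg))
  ec_ids <- sprintf("sim-EC-%d", seq_len(config$n_ecs))
  mirnas <- c(reg_ids, ec_ids)
  control_ids <- c("U6-snRNA", "RNU44", "RNU48")

  baseline <- c(stats::runif(n_reg, config$baseline_range[1],
                             config$baseline_range[2]),
                stats::runif(config$n_ecs, config$ec_baseline_range[1],
                             config$ec_baseline_range[2]))
  sdv <- c(stats::runif(n_reg, config$sd_range[1], config$sd_range[2]),
           rep(config$ec_sd, config$n_ecs))
  names(baseline) <- names(sdv) <- mirnas

  sample_eff <- stats::rnorm(n_s, 0, config$sample_effect_sd)

  # latent mean matrix, samples x probes
  mu <- matrix(baseline, n_s, length(mirnas), byrow = TRUE,
               dimnames = list(samples, mirnas))
  de <- config$detection_effects
  if (!is.null(de)) {
    for (i in seq_len(nrow(de))) {
      m <- de$mirna_id[i]
      sig <- sqrt(sdv[m]^2 + config$sample_effect_sd^2)
      mu[, m] <- config$cq_ceiling - stats::qnorm(de$base_detect_prob[i]) * sig
      g <- groups == de$group[i]
      mu[g, m] <- config$cq_ceiling - stats::qnorm(de$detect_prob[i]) * sig
    }
  }
  le <- config$level_effects
  if (!is.null(le)) {
    for (i in seq_len(nrow(le))) {
      g <- groups == le$group[i]
      mu[g, le$mirna_id[i]] <- mu[g, le$mirna_id[i]] + le$dcq_shift[i]
    }
  }
  se <- config$synergy_effects
  if (!is.null(se)) {
    parity <- groups == "DepC"  # deployment XOR tbi
    for (i in seq_len(nrow(se)))
      mu[parity, se$mirna_id[i]] <- mu[parity, se$mirna_id[i]] + se$strength[i]
  }

  latent <- mu + sample_eff +
    matrix(stats::rnorm(n_s * length(mirnas)), n_s) *
    matrix(sdv, n_s, length(mirnas), byrow = TRUE)

  # control probes: stable, always detected, exempt from EC candidacy by id
  ctrl_latent <- matrix(rep(c(22, 23, 23.5), each = n_s), n_s) + sample_eff +
    matrix(stats::rnorm(n_s * 3, 0, 0.12), n_s)
  latent <- cbind(latent, ctrl_latent)
  colnames(latent) <- c(mirnas, control_ids)
  all_ids <- colnames(latent)

  flaky <- stats::runif(length(all_ids)) < config$flaky_frac
  names(flaky) <- all_ids
  p_fail <- ifelse(flaky, config$failure_rate / config$flaky_frac, 0)
  fail <- matrix(stats::runif(n_s * length(all_ids)), n_s) <
    matrix(p_fail, n_s, length(all_ids), byrow = TRUE)

  censored <- latent >= config$cq_ceiling
  cq <- ifelse(censored, NA_real_, latent)
  amp_score <- matrix(stats::runif(n_s * length(all_ids), 1.1, 1.9), n_s)
  amp_score[fail] <- stats::runif(sum(fail), 0.2, 0.9)
  cq_conf <- pmin(1, pmax(0, 1 - 0.01 * (latent - 20) +
                            stats::rnorm(n_s * length(all_ids), 0, 0.02)))
  cq_conf[censored] <- stats::runif(sum(censored), 0, 0.5)

  records <- data.frame(
    sample_id = rep(samples, times = length(all_ids)),
    mirna_id = rep(all_ids, each = n_s),
    cq = as.vector(cq),
    amp_score = as.vector(amp_score),
    cq_conf = as.vector(cq_conf),
    stringsAsFactors = FALSE)
  qc <- qc_params(cq_ceiling = config$cq_ceiling)
  panel <- probe_panel(all_ids, withdrawn_ids = character(),
                       control_ids = control_ids)
  records <- amp_records(records, qc = qc, panel = panel)

  phenos <- pheno_table(.sim_phenotypes(groups))

  truth <- list(seed = config$seed, ecs = ec_ids, baseline = baseline,
                sd = sdv, sample_effect = stats::setNames(sample_eff, samples),
                flaky_probes = all_ids[flaky],
                level_effects = le, detection_effects = de,
                synergy_effects = se,
                group_sizes = c(ComC = config$n_comc, DepC = config$n_depc,
                                DepTBI = config$n_deptbi))
  list(records = records, phenotypes = phenos, panel = panel, truth = truth)
}

#' Deterministic worked-example fixture
#'
#' A hand-built 8-sample x 12-probe dataset with hand-computable
#' normalization: three ECs at constant Cq 20 (geometric-mean normalizer
#' exactly 20 in every sample), a target at Cq 25 everywhere (delta-Cq 5), a
#' probe with a noiseless planted 2-fold shift (delta-delta-Cq -1) between
#' DepTBI and ComC, one probe censored in half the samples, and one excluded
#' (failed) reaction.
#'
#' @return List with `records`, `phenotypes`, `panel`, `expected` (a list of
#'   hand-derived values used by tests and the README example).
#' @export
worked_example_fixture <- function() {
  samples <- sprintf("WX%02d", 1:8)
  groups <- c("ComC", "ComC", "ComC", "DepC", "DepC", "DepTBI", "DepTBI",
              "DepTBI")
  ecs <- c("wx-EC-1", "wx-EC-2", "wx-EC-3")
  targets <- sprintf("wx-miR-%02d", 1:9)
  probes <- c(targets, ecs)
  cq <- matrix(NA_real_, 8, 12, dimnames = list(samples, probes))
  cq[, ecs] <- 20
  cq[, "wx-miR-01"] <- 25                       # dCq 5.0 everywhere
  cq[, "wx-miR-02"] <- c(26, 26, 26, 26, 26, 25, 25, 25)  # 2-fold up in DepTBI
  cq[, "wx-miR-03"] <- c(27, 28, 27, 28, 27, 28, 27, 28)
  cq[, "wx-miR-04"] <- c(NA, NA, NA, NA, 33, 33, 32, 32)  # censored in ComC+
  cq[, "wx-miR-05"] <- c(22, 23, 22, 23, 22, 23, 22, 23)
  cq[, "wx-miR-06"] <- c(30, 31, 30, 31, 30, 31, 30, 31)
  cq[, "wx-miR-07"] <- c(24, 24.5, 24, 24.5, 24, 24.5, 24, 24.5)
  cq[, "wx-miR-08"] <- c(NA, 35, NA, 35, NA, 35, NA, 35)  # never detected
  cq[, "wx-miR-09"] <- c(26, 27, 26, 27, 26, 27, 26, 27)
  amp <- matrix(1.5, 8, 12, dimnames = list(samples, probes))
  amp["WX01", "wx-miR-09"] <- 0.5               # one technical failure
  conf <- matrix(0.95, 8, 12, dimnames = list(samples, probes))
  records <- amp_records(data.frame(
    sample_id = rep(samples, times = 12),
    mirna_id = rep(probes, each = 8),
    cq = as.vector(cq), amp_score = as.vector(amp),
    cq_conf = as.vector(conf), stringsAsFactors = FALSE))
  phenos <- pheno_table(data.frame(
    sample_id = samples, group = groups,
    age = c(30, 35, 40, 32, 38, 31, 36, 41),
    bmi = c(24, 25, 26, 27, 26, 28, 29, 30),
    mmse = c(30, 30, 29, 30, 29, 29, 28, 29),
    abeta42 = c(320, 310, 330, 300, 315, 305, 325, 312),
    ttau = c(40, 42, 38, 36, 35, 37, 39, 41),
    ptau181 = c(27, 28, 26, 30, 29, 28, 27, 30),
    apoe = c("e3/e3", "e3/e4", "e3/e3", "e3/e3", "e3/e4", "e4/e4",
             "e3/e3", "e3/e4"),
    smoke = c("no", "no", "yes", "no", "no", "yes", "no", "no"),
    race = c("White", "White", "Asian/PI", "White", "Black", "White",
             "White", "Other"),
    stringsAsFactors = FALSE))
  panel <- probe_panel(probes)
  expected <- list(
    g_s = 20,                                    # EC geometric mean, all samples
    dcq_s1_mir01 = 5.0,
    censor_threshold = 14,                       # 34 - 20
    fc_mir02_deptbi_vs_comc = 2.0,               # ddCq = -1 exactly
    excluded_cells = 1L)
  list(records = records, phenotypes = phenos, panel = panel,
       expected = expected)
}

#' Write the worked-example fixture as CSVs
#' @param dir Output directory.
#' @return Paths of the two CSVs, invisibly.
#' @export
write_fixture <- function(dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fx <- worked_example_fixture()
  p1 <- file.path(dir, "worked_example_amplifications.csv")
  p2 <- file.path(dir, "worked_example_phenotypes.csv")
  write_amplifications(fx$records, p1)
  utils::write.csv(as.data.frame(fx$phenotypes), p2, row.names = FALSE, na = "")
  invisible(c(p1, p2))
}
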