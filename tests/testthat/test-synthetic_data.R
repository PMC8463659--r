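test_that("identical seeds reproduce bit-identical output; seeds matter", {
  cfg <- sim_config(n_comc = 10, n_depc = 5, n_deptbi = 8, n_mirnas = 25,
                    seed = 5)
  a <- simulate_qpcr(cfg)
  b <- simulate_qpcr(cfg)
  expect_identical(as.data.frame(a$records), as.data.frame(b$records))
  expect_identical(as.data.frame(a$phenotypes), as.data.frame(b$phenotypes))
  cfg2 <- cfg; cfg2$seed <- 6
  c_ <- simulate_qpcr(cfg2)
  expect_false(identical(a$records$cq, c_$records$cq))
})

test_that("generator emits the stated world", {
  sim <- simulate_qpcr(sim_config(seed = 2))
  ph <- sim$phenotypes
  expect_equal(as.integer(table(ph$group)[c("ComC", "DepC", "DepTBI")]),
               c(52L, 18L, 45L))
  expect_equal(length(unique(sim$records$mirna_id)), 380)  # 377 + 3 controls
  expect_length(sim$truth$ecs, 3)
  # EC probes are quiet and well below the candidacy Cq bound
  ec_rows <- sim$records[sim$records$mirna_id %in% sim$truth$ecs, ]
  expect_true(all(ec_rows$cq < 30, na.rm = TRUE))
  # flags conserve records
  expect_equal(sum(table(sim$records$flag)), nrow(sim$records))
  # no TBI history outside DepTBI
  expect_true(all(ph$n_tbi[ph$group != "DepTBI"] == 0))
  expect_true(all(ph$n_tbi[ph$group == "DepTBI"] >= 1))
})

test_that("detection rate decreases with baseline Cq by construction", {
  sim <- simulate_qpcr(sim_config(seed = 3))
  rec <- as.data.frame(sim$records)
  det <- tapply(rec$flag == "good", rec$mirna_id, mean)
  ids <- names(sim$truth$baseline)
  r <- cor(sim$truth$baseline[ids], det[ids], method = "spearman")
  expect_lt(r, -0.3)
  # a baseline sweep is monotone nonincreasing in bins, up to the detection
  # plateau (low-Cq probes are all but always detected, so the first bins
  # saturate near 1 and only jitter at the fourth decimal)
  bins <- cut(sim$truth$baseline[ids], c(24, 27, 30, 33))
  by_bin <- tapply(det[ids], bins, mean)
  expect_true(all(diff(by_bin) < 0.005))
  expect_lt(by_bin[[3]], by_bin[[1]] - 0.01)
  # near the ceiling the censoring mechanism bites visibly
  high <- ids[sim$truth$baseline[ids] > 32.5]
  expect_lt(mean(det[high]), 0.95)
})

test_that("the truth manifest records every planted effect", {
  le <- data.frame(mirna_id = "sim-miR-001", group = "DepTBI", dcq_shift = 1)
  de <- data.frame(mirna_id = "sim-miR-002", group = "DepTBI",
                   detect_prob = 0.8, base_detect_prob = 0.2)
  se <- data.frame(mirna_id = "sim-miR-003", strength = 2)
  sim <- simulate_qpcr(sim_config(n_comc = 12, n_depc = 6, n_deptbi = 10,
                                  n_mirnas = 30, seed = 4,
                                  level_effects = le, detection_effects = de,
                                  synergy_effects = se))
  expect_equal(sim$truth$level_effects, le)
  expect_equal(sim$truth$detection_effects, de)
  expect_equal(sim$truth$synergy_effects, se)
  expect_true(all(c("ecs", "baseline", "sd", "sample_effect",
                    "group_sizes") %in% names(sim$truth)))
  # contradictory plantings on one probe are rejected
  expect_error(sim_config(level_effects = le,
                          detection_effects = data.frame(
                            mirna_id = "sim-miR-001", group = "DepC",
                            detect_prob = 0.5, base_detect_prob = 0.5)),
               "contradictory")
})

test_that("a planted detection shift realizes its target rates", {
  de <- data.frame(mirna_id = "sim-miR-001", group = "DepTBI",
                   detect_prob = 0.8, base_detect_prob = 0.2)
  sim <- simulate_qpcr(sim_config(seed = 8, detection_effects = de))
  rec <- as.data.frame(sim$records)
  rec <- rec[rec$mirna_id == "sim-miR-001", ]
  grp <- sim$phenotypes$group[match(rec$sample_id, sim$phenotypes$sample_id)]
  rate_tbi <- mean(rec$flag[grp == "DepTBI"] == "good")
  rate_ref <- mean(rec$flag[grp != "DepTBI"] == "good")
  expect_lt(abs(rate_tbi - 0.8), 0.2)
  expect_lt(abs(rate_ref - 0.2), 0.15)
})

test_that("the worked example fixture matches its hand-computed values", {
  fx <- worked_example_fixture()
  expect_equal(fx$expected$excluded_cells, sum(fx$records$flag == "excluded"))
  em <- normalize_dcq(fx$records, c("wx-EC-1", "wx-EC-2", "wx-EC-3"))
  expect_equal(em$dcq["WX01", "wx-miR-01"], 5.0)
  expect_equal(unname(em$censor_threshold["WX01"]), 14)
  fc <- fold_change(em$dcq[6:8, "wx-miR-02"], em$censored[6:8, "wx-miR-02"],
                    em$dcq[1:3, "wx-miR-02"], em$censored[1:3, "wx-miR-02"])
  expect_equal(fc$fc, 2.0)  # noiseless planted 2-fold shift, recovered exactly
  # deterministic: two builds are identical
  expect_identical(as.data.frame(worked_example_fixture()$records),
                   as.data.frame(fx$records))
})

test_that("shipped fixture CSVs equal the in-code construction", {
  amp_path <- system.file("extdata", "worked_example_amplifications.csv",
                          package = "qpcrcens")
  expect_true(nzchar(amp_path))
  rec <- read_amplifications(amp_path)
  fx <- worked_example_fixture()
  ord <- function(r) {
    r <- as.data.frame(r)[order(r$sample_id, r$mirna_id), ]
    rownames(r) <- NULL
    r
  }
  expect_equal(ord(rec), ord(fx$records), tolerance = 1e-12)
  ph <- read_phenotypes(system.file("extdata",
                                    "worked_example_phenotypes.csv",
                                    package = "qpcrcens"))
  expect_equal(ph$group, fx$phenotypes$group)
})
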