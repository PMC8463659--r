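test_that("entropy hits the closed-form anchors", {
  expect_equal(entropy_bits(c(1, 1)), 1)          # fair bit
  expect_equal(entropy_bits(c(5, 0, 0)), 0)       # deterministic
  expect_equal(entropy_bits(c(2, 1, 1)), 1.5)     # hand arithmetic
  expect_error(entropy_bits(c(0, 0)), "empty")
})

test_that("mutual information matches the brute-force double sum", {
  # identity on a fair bit: MI = H = 1
  x <- rep(0:1, 50)
  expect_equal(mutual_information(x, x), 1)
  # exact product table: independence, MI = 0
  xi <- rep(0:1, each = 6); yi <- rep(0:2, 4)
  expect_equal(mutual_information(xi, yi), 0, tolerance = 1e-12)
  set.seed(31)
  for (i in 1:30) {
    x <- sample(0:2, 40, replace = TRUE)
    y <- sample(0:1, 40, replace = TRUE)
    expect_close(mutual_information(x, y), oracle_mi(x, y))
  }
})

test_that("MI obeys the information inequalities on exact tables", {
  set.seed(32)
  for (i in 1:25) {
    x <- sample(0:2, 60, replace = TRUE)
    y <- sample(0:2, 60, replace = TRUE)
    mi <- mutual_information(x, y)
    expect_gte(mi, -1e-12)
    expect_equal(mi, mutual_information(y, x), tolerance = 1e-12)
    expect_lte(mi, min(entropy_bits(table(x)), entropy_bits(table(y))) + 1e-12)
    expect_equal(mutual_information(x, x), entropy_bits(table(x)),
                 tolerance = 1e-12)
  }
})

test_that("the XOR triple is purely synergistic: delta_bar = -1 bit exactly", {
  # exact joint distribution: m,p independent fair bits, s = xor(m,p)
  m <- rep(0:1, each = 2); p <- rep(0:1, 2); s <- bitwXor(m, p)
  m <- rep(m, 25); p <- rep(p, 25); s <- rep(s, 25)
  expect_equal(mutual_information(m, p), 0, tolerance = 1e-12)
  expect_equal(mutual_information(m, s), 0, tolerance = 1e-12)
  expect_equal(mutual_information(p, s), 0, tolerance = 1e-12)
  d <- symmetric_delta(m, p, s)
  expect_equal(d$i3, -1, tolerance = 1e-12)
  expect_equal(d$delta_m, -1, tolerance = 1e-12)
  expect_equal(d$delta_p, -1, tolerance = 1e-12)
  expect_equal(d$delta_s, -1, tolerance = 1e-12)
  expect_equal(d$delta_bar, -1, tolerance = 1e-12)
})

test_that("independence of any variable zeroes the symmetric delta", {
  # s independent of (m,p): exact factorized triple over all combinations
  grid <- expand.grid(m = 0:1, p = 0:1, s = 0:1)
  d <- symmetric_delta(grid$m, grid$p, grid$s)
  expect_equal(d$delta_bar, 0, tolerance = 1e-12)
  # correlated (m,p) but s still independent
  grid2 <- expand.grid(mp = 0:1, s = 0:2)
  d2 <- symmetric_delta(grid2$mp, grid2$mp, grid2$s)
  expect_equal(d2$delta_bar, 0, tolerance = 1e-12)
})

test_that("delta components match the entropy-sum oracle and are symmetric", {
  set.seed(41)
  for (i in 1:30) {
    m <- sample(0:1, 50, replace = TRUE)
    p <- sample(0:1, 50, replace = TRUE)
    s <- sample(0:1, 50, replace = TRUE)
    d <- symmetric_delta(m, p, s)
    o <- oracle_delta(m, p, s)
    expect_close(d$i3, o$i3)
    expect_close(d$delta_m, o$delta_m)
    expect_close(d$delta_bar, o$delta_bar)
    # delta_bar invariant under permutations of (m, p, s)
    for (perm in list(list(p, m, s), list(s, p, m), list(p, s, m))) {
      dp <- symmetric_delta(perm[[1]], perm[[2]], perm[[3]])
      expect_close(dp$delta_bar, d$delta_bar)
    }
  }
})

test_that("tertile binning recovers the distribution's equal-mass factor", {
  set.seed(51)
  # standard normal: tertile boundary at 0.4307 SD
  b <- bin_tertile(rnorm(3000))
  expect_lt(abs(b$f - qnorm(2 / 3)), 0.05)
  expect_true(all(abs(table(b$codes) - 1000) < 150))
  # uniform(0,1): boundary at 1/3 from the mean in units of sd = 1/sqrt(12)
  bu <- bin_tertile(runif(3000))
  expect_lt(abs(bu$f - (1 / 6) / (1 / sqrt(12))), 0.07)
  # boundary values fall in the lower bin
  v <- c(1, 1, 1, 2, 2, 2, 3, 3, 3)
  bt <- bin_tertile(v)
  expect_equal(bt$codes[v == 1], rep(0L, 3))
  expect_error(bin_tertile(rep(1, 10)), "zero variance")
  expect_error(bin_tertile(1:5), "at least 6")
})

test_that("secondary binning follows the documented schemes", {
  ph <- make_phenos(rep(c("ComC", "DepC", "DepTBI"), each = 4),
                    age = c(25, 30, 35, 40, 45, 28, 33, 38, 43, 27, 31, 36),
                    bmi = c(22, 24, 26, 28, 30, 23, 25, 27, 29, 24, 26, 31),
                    ttau = c(30, 40, 50, 35, 45, 30, 50, 40, 35, 45, 30, 50),
                    apoe = c("e3/e3", "e3/e4", "e4/e4", NA, "e2/e3", "e3/e3",
                             "e3/e4", "e3/e3", "e3/e3", "e3/e4", "e3/e3",
                             "e3/e3"),
                    smoke = rep(c("no", "yes", "no"), 4),
                    race = c("White", "White", "White", "Black", "Asian",
                             "AmInd", "Other", "White", "White", "Asian",
                             "White", "White"))
  sec <- bin_secondary(ph)
  expect_equal(sec$age$n_bins, 3L)
  expect_equal(sec$age$scheme, "tertile-musigma")
  # mean split: 0 below mean, 1 at or above
  b3 <- bin_mean_split(c(30, 40, 50))
  expect_equal(b3$codes, c(0L, 1L, 1L))
  # apoe4 is carrier status; NA preserved
  expect_equal(sec$apoe4$codes[1:4], c(0L, 1L, 1L, NA))
  # five races merge to 3 bins, most frequent keeping their own code
  expect_equal(sec$race$n_bins, 3L)
  expect_equal(sec$race$levels[1], "White")
  expect_equal(sec$race$levels[3], "other")
  ph_bad <- ph; ph_bad$smoke[1] <- "sometimes"
  expect_error(bin_secondary(ph_bad), "sometimes")
})

test_that("primary variables recode groups as documented", {
  ph <- make_phenos(c("ComC", "DepC", "DepTBI"))
  pr <- build_primaries(ph)
  expect_equal(pr$deployment$codes, c(0L, 1L, 1L))
  expect_equal(pr$tbi$codes, c(0L, 0L, 1L))
  expect_equal(pr$exp_grp$codes, c(0L, 1L, 2L))
})

test_that("miRNA binning handles censoring and degenerate probes", {
  set.seed(61)
  dcq <- cbind(clean = rnorm(30, 5, 1),
               half = c(rnorm(15, 5, 1), rep(9, 15)),
               sparse = rep(9, 30))
  cen <- matrix(FALSE, 30, 3, dimnames = list(NULL, colnames(dcq)))
  cen[16:30, "half"] <- TRUE
  cen[, "sparse"] <- TRUE
  em <- make_em(dcq, censored = cen)
  bm <- bin_mirnas(em)
  expect_equal(sort(unique(bm$clean$codes)), 0:2)
  # censored cells land in the lowest-expression (highest-dCq) bin
  expect_true(all(bm$half$codes[16:30] == bm$half$n_bins - 1L))
  # all-censored probe falls back to the detected/censored coding
  expect_equal(bm$sparse$scheme, "detected-split")
  expect_true(all(bm$sparse$codes == 1L))
  # drop policy leaves censored cells missing
  bm2 <- bin_mirnas(em, censored_policy = "drop")
  expect_true(all(is.na(bm2$half$codes[16:30])))
})

test_that("the search emits 43 lists with calibrated z-scores", {
  set.seed(71)
  sim <- simulate_qpcr(sim_config(n_comc = 20, n_depc = 10, n_deptbi = 16,
                                  n_mirnas = 40, seed = 71))
  em <- suppressWarnings(normalize_dcq(sim$records, sim$truth$ecs,
                                       mirnas = analyzable_ids(sim$panel)))
  bm <- bin_mirnas(em)
  idx <- match(em$samples, sim$phenotypes$sample_id)
  pr <- lapply(build_primaries(sim$phenotypes),
               function(b) { b$codes <- b$codes[idx]; b })
  sec <- lapply(bin_secondary(sim$phenotypes),
                function(b) { b$codes <- b$codes[idx]; b })
  search <- run_search(bm, pr, sec)
  expect_length(search, 3 + 3 * 13 + 1)
  for (id in names(search)) {
    df <- search[[id]]
    z <- df$z[!is.na(df$z)]
    expect_equal(mean(z), 0, tolerance = 1e-10)
    expect_equal(sd(z), 1, tolerance = 1e-10)
    ranked <- df$rank[!is.na(df$rank)]
    expect_lte(length(ranked), 20L)
    expect_true(all(df$z[!is.na(df$rank)] > 1))
  }
  # MI lists carry nonnegative raw scores, delta lists nonpositive-or-mixed
  expect_true(all(search[["MI:tbi"]]$raw >= 0))
})

test_that("composite scores are the stated weighted sum of z components", {
  fake_list <- function(z, measure = "delta") {
    data.frame(mirna_id = "m1", measure = measure, raw = z, z = z,
               rank = NA_integer_, n = 50, stringsAsFactors = FALSE)
  }
  search <- structure(list(
    "MI:tbi" = fake_list(2, "MI"),
    "delta:tbi:ptau_ttau" = fake_list(1),
    "delta:tbi:abeta_ttau" = fake_list(0.5),
    "delta:tbi:abeta_ptau" = fake_list(-2),
    "delta:tbi:apoe4" = fake_list(1),
    "delta:tbi:age" = fake_list(0),
    "delta:tbi:bmi" = fake_list(0),
    "delta:tbi:smoke" = fake_list(0)), class = "dep_search")
  cs <- composite_scores(search, "tbi")
  # ratio term takes the max (1), not the sum, of the three ratio lists
  expect_equal(cs$value, 2 + 0.5 * (1 + 1))
  expect_equal(cs$z_ratio_max, 1)
  # linearity in components with weights 1, 1/2, 1/2, 1/3, 1/3, 1/3
  search$`delta:tbi:age` <- fake_list(3)
  search$`delta:tbi:bmi` <- fake_list(-1.5)
  cs2 <- composite_scores(search, "tbi")
  expect_equal(cs2$value, 2 + 0.5 * (1 + 1) + (3 - 1.5) / 3)
  # all-zero components give zero
  search0 <- structure(lapply(search, function(df) { df$z <- 0; df }),
                       class = "dep_search")
  expect_equal(composite_scores(search0, "tbi")$value, 0)
})

test_that("stringent filtering keeps only the extreme tail", {
  mk <- function(values) {
    data.frame(mirna_id = sprintf("m%03d", seq_along(values)),
               primary = "tbi", value = values, stringsAsFactors = FALSE)
  }
  # all-equal scores: no tail, empty selection
  expect_length(stringent_filter(list(mk(rep(1, 50)))), 0)
  # a 10-SD outlier is exactly what survives
  set.seed(81)
  v <- rnorm(100); v[7] <- 10
  expect_equal(stringent_filter(list(mk(v))), "m007")
  # intersection with QC-passing probes
  expect_length(stringent_filter(list(mk(v)), qc_pass = "m001"), 0)
})
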