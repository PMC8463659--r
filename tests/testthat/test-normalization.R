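make_records <- function(cq_mat, amp = 1.5, conf = 0.95) {
  samples <- rownames(cq_mat); probes <- colnames(cq_mat)
  amp_records(data.frame(
    sample_id = rep(samples, times = length(probes)),
    mirna_id = rep(probes, each = length(samples)),
    cq = as.vector(cq_mat), amp_score = amp, cq_conf = conf,
    stringsAsFactors = FALSE))
}

test_that("EC candidacy enforces strict boundaries in every sample", {
  cq <- matrix(25, 4, 3, dimnames = list(paste0("s", 1:4), c("a", "b", "c")))
  cq["s2", "b"] <- 30.0   # strict < 30: b is out
  rec <- make_records(cq)
  expect_error(select_ec_candidates(rec), "insufficient")
  cq <- cbind(cq, d = 26, e = 27)
  expect_equal(select_ec_candidates(make_records(cq)),
               c("a", "c", "d", "e"))
  # all perfect: all returned
  cq2 <- matrix(24, 3, 4, dimnames = list(paste0("s", 1:3), letters[1:4]))
  expect_equal(select_ec_candidates(make_records(cq2)), letters[1:4])
  # control probes are not eligible
  panel <- probe_panel(colnames(cq), control_ids = "a")
  expect_equal(select_ec_candidates(make_records(cq), panel),
               c("c", "d", "e"))
})

test_that("stability M matches the brute-force pairwise-SD oracle", {
  set.seed(11)
  for (rep in 1:20) {
    tab <- matrix(rnorm(5 * 8, 25, 1), 8, 5,
                  dimnames = list(NULL, paste0("g", 1:5)))
    rk <- stability_rank(tab)
    m_oracle <- oracle_genorm_m(tab)
    expect_equal(rk$M[names(m_oracle)], m_oracle, tolerance = 1e-10)
  }
})

test_that("a noisy gene ranks last; co-stable genes have the lowest M", {
  set.seed(3)
  base <- rnorm(6, 25, 0.5)             # shared per-sample shift
  tab <- cbind(g1 = base + 20,          # identical up to constant offsets
               g2 = base + 21,
               g3 = base + 22 + rnorm(6, 0, 0.05),
               g4 = base + rnorm(6, 0, 3))  # noisy
  rk <- stability_rank(tab)
  expect_equal(rk$candidates[4], "g4")
  # two genes identical up to a per-sample common shift: pairwise SD zero
  tab2 <- cbind(a = base, b = base + 1,
                c = base + rnorm(6, 0, 0.5), d = base + rnorm(6, 0, 0.5))
  m <- stability_rank(tab2)$M
  expect_lt(m[["a"]], min(m[["c"]], m[["d"]]))
  expect_equal(unname(m[["a"]]), unname(m[["b"]]))
})

test_that("stability ranking is invariant to per-sample constant shifts", {
  set.seed(21)
  tab <- matrix(rnorm(6 * 10, 26, 1), 10, 6,
                dimnames = list(NULL, paste0("g", 1:6)))
  shift <- rnorm(10, 0, 2)
  rk1 <- stability_rank(tab)
  rk2 <- stability_rank(tab + shift)
  expect_equal(rk1$candidates, rk2$candidates)
  expect_equal(rk1$M, rk2$M, tolerance = 1e-10)
  expect_equal(rk1$V, rk2$V, tolerance = 1e-10)
})

test_that("pairwise variation stopping selects a compact stable set", {
  set.seed(5)
  base <- rnorm(40, 25, 0.4)
  tab <- cbind(e1 = base + rnorm(40, 0, 0.05),
               e2 = base + 1 + rnorm(40, 0, 0.05),
               e3 = base + 2 + rnorm(40, 0, 0.05),
               n1 = base + rnorm(40, 0, 1.5),
               n2 = base + rnorm(40, 0, 1.5))
  rk <- stability_rank(tab)
  expect_true(all(rk$selected_ecs %in% c("e1", "e2", "e3")))
  expect_gte(length(rk$selected_ecs), 2L)
  # the V sequence has one entry per k = 2..n-1
  expect_equal(names(rk$V), paste0("V", 2:4))
})

test_that("delta-Cq normalization follows the EC geometric mean", {
  samples <- paste0("s", 1:2)
  cq <- matrix(c(18, 19, 20, 20, 22.5, 21, 24, 25, NA, 33),
               nrow = 2, dimnames = list(samples,
                                         c("e1", "e2", "e3", "t1", "t2")))
  rec <- make_records(cq)
  em <- normalize_dcq(rec, c("e1", "e2", "e3"))
  g1 <- (18 * 20 * 22.5)^(1 / 3)
  expect_equal(em$dcq["s1", "t1"], 24 - g1)
  expect_equal(em$censor_threshold[["s1"]], 34 - g1)
  # censored cell carries the sample threshold
  expect_true(em$censored["s1", "t2"])
  expect_equal(em$dcq["s1", "t2"], 34 - g1)
  # equal ECs: geometric mean equals the common value
  g2 <- (19 * 20 * 21)^(1 / 3)
  expect_equal(em$dcq["s2", "t1"], 25 - g2)
})

test_that("samples missing an EC are dropped with a warning", {
  cq <- matrix(c(20, 20, 20, NA, 25, 26), nrow = 2,
               dimnames = list(c("s1", "s2"), c("e1", "e2", "t1")))
  rec <- make_records(cq)
  expect_warning(em <- normalize_dcq(rec, c("e1", "e2")), "s2")
  expect_equal(em$samples, "s1")
  expect_equal(em$dcq["s1", "t1"], 5)
})

test_that("miRNA filtering applies > and >= at exact boundaries", {
  n <- 100
  excl <- matrix(FALSE, n, 3, dimnames = list(NULL, c("a", "b", "c")))
  cen <- matrix(FALSE, n, 3, dimnames = dimnames(excl))
  excl[1:21, "a"] <- TRUE             # 21% failed: dropped
  excl[1:20, "b"] <- TRUE             # exactly 20%: kept
  cen[1:90, "c"] <- TRUE              # exactly 10% detected: kept
  dcq <- matrix(5, n, 3, dimnames = dimnames(excl))
  em <- make_em(dcq, censored = cen, excluded = excl)
  kept <- filter_mirnas(em)$mirnas
  expect_equal(kept, c("b", "c"))
  expect_true(all(kept %in% em$mirnas))  # output subset of input
  # censored cells count toward neither failure nor detection
  cen2 <- cen; cen2[1:91, "c"] <- TRUE   # 9% detected: dropped
  expect_equal(filter_mirnas(make_em(dcq, cen2, excl))$mirnas, "b")
})

test_that("expression matrix CSV round-trip preserves values and masks", {
  fx <- worked_example_fixture()
  em <- suppressWarnings(normalize_dcq(fx$records,
                                       c("wx-EC-1", "wx-EC-2", "wx-EC-3")))
  pref <- withr::local_tempfile()
  write_expr_matrix(em, pref)
  em2 <- read_expr_matrix(pref)
  expect_equal(em2$dcq, em$dcq, tolerance = 1e-12)
  expect_equal(em2$censored, em$censored)
  expect_equal(em2$excluded, em$excluded)
  expect_equal(unname(em2$censor_threshold), unname(em$censor_threshold))
})
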