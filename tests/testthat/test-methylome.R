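test_that("oxBS subtraction arithmetic, clipping and masking", {
  cts <- count_rows("chr1", 100, "ctrl", 1L, bs_meth = 30, bs_total = 60,
                    oxbs_meth = 15, oxbs_total = 50)
  b <- compute_betas(cts, min_coverage = 10)
  expect_equal(b$beta_bs, 0.5)
  expect_equal(b$beta_5mc, 0.3)
  expect_equal(b$beta_5hmc, 0.2)
  expect_false(b$clipped)
  expect_false(b$masked)

  clipped <- compute_betas(
    count_rows("chr1", 200, "ctrl", 1L, 10, 50, 20, 50), min_coverage = 10)
  expect_equal(clipped$beta_5hmc, 0)
  expect_true(clipped$clipped)

  low <- compute_betas(
    count_rows("chr1", 300, "ctrl", 1L, 3, 5, 2, 5), min_coverage = 10)
  expect_true(low$masked)
  expect_error(compute_betas(count_rows("chr1", 1, "c", 1L, 60, 50, 1, 50)),
               "meth > total")
  expect_error(compute_betas(dplyr::select(cts, -"total")), "missing columns")
})

test_that("beta of pooled counts equals mean beta for equal totals", {
  cts <- dplyr::bind_rows(
    count_rows("chr1", 1, "ctrl", 1L, 20, 50, 10, 50),
    count_rows("chr1", 1, "ctrl", 2L, 30, 50, 20, 50)
  )
  b <- compute_betas(cts, min_coverage = 10)
  pooled_beta <- sum(c(20, 30)) / sum(c(50, 50))
  expect_equal(mean(b$beta_bs), pooled_beta)
})

test_that("welch calls match stats::t.test and the threshold rule", {
  # clear effect: control 0.20/0.22 vs treated 0.50/0.52
  cts <- site_counts(100, c(0.20, 0.22), c(0.50, 0.52))
  dm <- call_dmps(cts, "control", "treated", mark = "5mC", test = "welch")
  expect_equal(dm$delta_beta, 0.30, tolerance = 1e-12)
  oracle <- stats::t.test(c(0.50, 0.52), c(0.20, 0.22))
  expect_equal(dm$p_value, oracle$p.value, tolerance = 1e-9)
  expect_lt(dm$p_value, 0.05)
  expect_identical(dm$call, "hyper")

  # significant but tiny effect: below the delta threshold -> none
  small <- site_counts(200, c(0.40, 0.42), c(0.44, 0.46))
  dm2 <- call_dmps(small, "control", "treated", mark = "5mC", test = "welch")
  expect_equal(dm2$delta_beta, 0.04, tolerance = 1e-12)
  expect_identical(dm2$call, "none")

  # identical groups: no difference, no call
  same <- site_counts(300, c(0.35, 0.35), c(0.35, 0.35))
  dm3 <- call_dmps(same, "control", "treated", mark = "5mC", test = "welch")
  expect_equal(dm3$delta_beta, 0)
  expect_equal(dm3$p_value, 1)
  expect_identical(dm3$call, "none")

  # hypo direction is symmetric
  hypo <- site_counts(400, c(0.50, 0.52), c(0.20, 0.22))
  dm4 <- call_dmps(hypo, "control", "treated", mark = "5mC", test = "welch")
  expect_identical(dm4$call, "hypo")
})

test_that("pooled Fisher calls match stats::fisher.test", {
  cts <- dplyr::bind_rows(
    count_rows("chr1", 10, "control", 1L, 20, 100, 20, 100),
    count_rows("chr1", 10, "control", 2L, 24, 100, 24, 100),
    count_rows("chr1", 10, "treated", 1L, 52, 100, 52, 100),
    count_rows("chr1", 10, "treated", 2L, 48, 100, 48, 100)
  )
  dm <- call_dmps(cts, "control", "treated", mark = "5mC",
                  test = "fisher_pooled")
  oracle <- stats::fisher.test(matrix(c(44, 156, 100, 100), 2))$p.value
  expect_equal(dm$p_value, oracle, tolerance = 1e-12)
  expect_equal(dm$beta_control, 0.22)
  expect_equal(dm$beta_treated, 0.50)
  expect_identical(dm$call, "hyper")
  # usable with a single replicate per condition
  one_rep <- dplyr::bind_rows(
    count_rows("chr1", 20, "control", 1L, 10, 100, 10, 100),
    count_rows("chr1", 20, "treated", 1L, 60, 100, 60, 100)
  )
  dm1 <- call_dmps(one_rep, "control", "treated", mark = "5mC",
                   test = "fisher_pooled")
  expect_identical(dm1$call, "hyper")
})

test_that("the moderated test finds planted effects and spares null sites", {
  sim <- synth_oxrrbs(n_sites = 300, effect_fraction_hyper = 0.1,
                      effect_fraction_hypo = 0, seed = 21)
  dm <- call_dmps(sim$counts, "control", "treated", mark = "5mC")
  truth <- dplyr::filter(sim$truth, mark == "5mC")
  joined <- dplyr::inner_join(dm, truth, by = c("chrom", "pos"))
  strong <- dplyr::filter(joined, effect == "hyper", applied_delta >= 0.295)
  expect_gt(mean(strong$call == "hyper"), 0.9)
  null_sites <- dplyr::filter(joined, effect == "none")
  expect_lt(mean(null_sites$call != "none"), 0.1)
})

test_that("5hmC calling works on the subtraction scale", {
  # treated gains 5hmC: BS rises, oxBS unchanged
  mk <- function(cond, rep, bs_m) {
    count_rows("chr1", 50, cond, rep, bs_m, 100, 20, 100)
  }
  cts <- dplyr::bind_rows(mk("control", 1L, 30), mk("control", 2L, 32),
                          mk("treated", 1L, 62), mk("treated", 2L, 60))
  dm <- call_dmps(cts, "control", "treated", mark = "5hmC", test = "welch")
  expect_equal(dm$delta_beta, 0.30, tolerance = 1e-9)
  expect_identical(dm$call, "hyper")
  # while 5mC at the same site is untouched
  dm_m <- call_dmps(cts, "control", "treated", mark = "5mC", test = "welch")
  expect_identical(dm_m$call, "none")
})

test_that("promoter methylation versus expression correlation", {
  betas <- tibble::tibble(gene = paste0("g", 1:50),
                          beta = seq(0.02, 0.98, length.out = 50))
  perfect <- tibble::tibble(gene = betas$gene, expression = exp(-betas$beta))
  r <- methylation_expression_correlation(betas, perfect)
  expect_equal(r$rho, -1)

  shuffled <- withr::with_seed(5, {
    tibble::tibble(gene = sample(betas$gene), expression = exp(-betas$beta))
  })
  r2 <- methylation_expression_correlation(betas, shuffled)
  expect_lt(abs(r2$rho), 0.3)
  expect_gt(r2$p_value, 0.05)

  expect_error(
    methylation_expression_correlation(betas[1:5, ], perfect[1:5, ]),
    "at least 10")
})
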