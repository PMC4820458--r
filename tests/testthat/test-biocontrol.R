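test_that("MOI dosing is the product of MOI and host density", {
  expect_equal(moi_dose(0.1, 1e4), 1e3)   # the cheese-model inoculum
  expect_equal(moi_dose(1, 1e4), 1e4)
  expect_equal(moi_dose(10, 2.5e3), 2.5e4)
  expect_error(moi_dose(0, 1e4), class = "phagerflp_input_error")
  expect_error(moi_dose(0.1, -1), class = "phagerflp_input_error")
})

test_that("percent reduction matches the published cheese figures", {
  expect_equal(round(percent_reduction(3.13, 0.46)), 85)
  expect_equal(percent_reduction(5, 5), 0)
  expect_equal(percent_reduction(3.05e9, 4.56e8), 85.04918, tolerance = 1e-6)
  expect_equal(percent_reduction(10, 0), 100)
  expect_lt(percent_reduction(10, 15), 0)
  expect_error(percent_reduction(0, 1), class = "phagerflp_input_error")
  expect_error(percent_reduction(1, -1), class = "phagerflp_input_error")
})

test_that("a generously rounded published reduction is flagged", {
  # broth counts compute to 85.0%, not the 90% quoted alongside them
  expect_warning(
    out <- reduction_consistency(3.05e9, 4.56e8, reported_percent = 90),
    class = "phagerflp_reduction_discrepancy"
  )
  expect_false(out$consistent)
  expect_equal(round(out$computed_percent, 1), 85.0)
  ok <- reduction_consistency(3.13, 0.46, reported_percent = 85)
  expect_true(ok$consistent)
})

test_that("tyramine mM converts to mg/kg via the molar mass", {
  expect_equal(round(tyramine_mm_to_mgkg(3.13), 1), 429.4)
  expect_equal(tyramine_mm_to_mgkg(0), 0)
  expect_equal(round(tyramine_mm_to_mgkg(1), 1), 137.2)
  expect_error(tyramine_mm_to_mgkg(-0.1), class = "phagerflp_input_error")
})

test_that("the packaged host-range panel summarises to 10 of 27 strains", {
  hr <- read_host_range(system.file("extdata", "host_range_q69.tsv",
                                    package = "phagerflp"))
  smry <- host_range_summary(hr)
  overall <- smry[smry$origin == "overall", ]
  expect_equal(overall$n_susceptible, 10L)
  expect_equal(overall$n_total, 27L)
  expect_equal(overall$percent, 37.0)
  # susceptible strains are of dairy, human and type-strain origin only
  expect_equal(smry$n_susceptible[smry$origin == "meat"], 0L)
  expect_equal(smry$n_susceptible[smry$origin == "clinical"], 0L)
  expect_equal(smry$n_susceptible[smry$origin == "dairy"], 6L)
  expect_equal(smry$n_susceptible[smry$origin == "human"], 3L)
})

test_that("host-range edge cases behave", {
  rec <- tibble::tibble(strain = c("s1", "s2"), origin = "dairy",
                        susceptible = c(FALSE, FALSE))
  out <- host_range_summary(rec)
  expect_equal(out$percent[out$origin == "overall"], 0)
  one <- host_range_summary(tibble::tibble(strain = "s", origin = "dairy",
                                           susceptible = TRUE))
  expect_equal(one$percent[one$origin == "overall"], 100)
  dup <- tibble::tibble(strain = c("s", "s"), origin = "dairy",
                        susceptible = c(TRUE, FALSE))
  expect_error(host_range_summary(dup), class = "phagerflp_input_error")
})

test_that("qPCR quantification inverts the standard curve", {
  curve <- standard_curve(slope = -3.32, intercept = 40)
  expect_equal(qpcr_cells(40, curve), 1)
  expect_equal(qpcr_cells(40 - 3.32, curve), 10)
  expect_equal(qpcr_cells(25, curve), 10^(15 / 3.32), tolerance = 1e-12)
  expect_equal(round(qpcr_cells(25, curve) / 1e4, 2), 3.30)
  # exact inverse of the forward map Ct(N) = intercept + slope*log10(N)
  withr::with_seed(12, {
    N <- 10^runif(20, 0, 9)
    ct <- curve$intercept + curve$slope * log10(N)
    expect_equal(qpcr_cells(ct, curve), N, tolerance = 1e-9)
  })
  expect_error(standard_curve(slope = 0), class = "phagerflp_input_error")
  expect_error(standard_curve(slope = 3.32), class = "phagerflp_input_error")
})

test_that("the pooled t-test matches the textbook formula and stats::t.test", {
  res <- two_sample_t(c(2.1, 2.0, 1.9), c(3.1, 3.0, 2.9))
  expect_equal(res$t, -12.24745, tolerance = 1e-5)  # hand-computed pooled t
  expect_equal(res$df, 4)
  expect_true(res$significant)

  same <- two_sample_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p_value, 1)
  expect_false(same$significant)

  withr::with_seed(23, {
    for (rep in 1:20) {
      a <- rnorm(3, 5, 1)
      b <- rnorm(4, 6, 2)
      mine <- two_sample_t(a, b)
      ref <- stats::t.test(a, b, var.equal = TRUE)
      expect_equal(mine$t, unname(ref$statistic), tolerance = 1e-10)
      expect_equal(mine$df, unname(ref$parameter), tolerance = 1e-10)
      expect_equal(mine$p_value, ref$p.value, tolerance = 1e-10)
      # p is symmetric under group swap
      expect_equal(two_sample_t(b, a)$p_value, mine$p_value, tolerance = 1e-12)
      # Welch variant against its reference
      minew <- two_sample_t(a, b, var_equal = FALSE)
      refw <- stats::t.test(a, b)
      expect_equal(minew$t, unname(refw$statistic), tolerance = 1e-10)
      expect_equal(minew$df, unname(refw$parameter), tolerance = 1e-10)
    }
  })

  expect_error(two_sample_t(c(1, 1, 1), c(1, 1, 1)), class = "phagerflp_input_error")
  expect_error(two_sample_t(1, c(1, 2)), class = "phagerflp_input_error")
})
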