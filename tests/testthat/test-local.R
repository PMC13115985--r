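test_that("Silverman's rule and its guards", {
  withr::with_seed(10, v <- rnorm(279, 5, 2.5))
  v <- pmin(pmax(v, 0), 10)
  h <- select_bandwidth(v)
  expect_equal(h, 1.06 * sd(v) * 279^(-0.2))
  # frozen value for the reference case sd = 2.5, n = 279
  expect_equal(1.06 * 2.5 * 279^(-0.2), 0.85929, tolerance = 1e-4)
  expect_error(select_bandwidth(rep(4, 50)), "homogeneous")
})

test_that("cv bandwidth selection stays inside the candidate set", {
  co <- simulate_cohort(
    cohort_config(n = 60, prevalence = 0.5,
                  vas_dist = list(p_zero = 0.1, shape1 = 1, shape2 = 1,
                                  continuous = TRUE)),
    seed = 12)
  panel <- as_test_panel(co)
  cands <- c(1, 2, 4)
  h <- select_bandwidth(co$vas, panel, method = "cv", candidates = cands,
                        seed = 1)
  expect_true(as.numeric(h) %in% cands)
  expect_length(attr(h, "cv_loglik"), 3)
  expect_error(select_bandwidth(co$vas[1:10], panel[1:10, ], method = "cv"),
               "n >= 30")
})

test_that("an infinite bandwidth reproduces the homogeneous fit", {
  co <- simulate_cohort(scenario_preset("overall", n = 400), seed = 13)
  panel <- as_test_panel(co)
  hom <- fit_lca(panel, seed = 2, n_restarts = 5)
  loc <- local_fit(panel, co$vas, v0 = 5, bandwidth = 1e6, seed = 2,
                   n_restarts = 5)
  expect_equal(loc$params$prevalence, hom$params$prevalence,
               tolerance = 1e-6)
  expect_equal(loc$params$se, hom$params$se, tolerance = 1e-6)
  expect_equal(loc$params$sp, hom$params$sp, tolerance = 1e-6)
})

test_that("a point mass at v0 reduces to the homogeneous fit on that subset", {
  co <- simulate_cohort(scenario_preset("overall", n = 300), seed = 14)
  co$vas <- rep(4, nrow(co))
  panel <- as_test_panel(co)
  hom <- fit_lca(panel, seed = 3, n_restarts = 5)
  loc <- local_fit(panel, co$vas, v0 = 4, bandwidth = 0.5, seed = 3,
                   n_restarts = 5)
  expect_equal(loc$params$se, hom$params$se, tolerance = 1e-6)
  expect_equal(loc$eff_n, 300)
})

test_that("the locally weighted log-likelihood is monotone along EM", {
  co <- simulate_cohort(scenario_preset("overall", n = 500), seed = 15)
  panel <- as_test_panel(co)
  for (v0 in c(2, 5, 8)) {
    loc <- local_fit(panel, co$vas, v0 = v0, bandwidth = 1.5, seed = 4,
                     n_restarts = 3)
    expect_true(all(diff(loc$trace) >= -1e-8), label = paste("v0", v0))
  }
})

test_that("a linearly varying CEC sensitivity is recovered locally", {
  cfg <- cohort_config(
    n = 4000, prevalence = 0.5,
    test_params = list(
      laparoscopy = c(se = 0.88, sp = 1.00),
      CEC = list(se = function(vas, phase) 0.5 + 0.04 * vas,
                 sp = function(vas, phase) rep(0.81, length(vas))),
      CA125 = c(se = 0.37, sp = 0.754)),
    vas_dist = list(p_zero = 0.05, shape1 = 1, shape2 = 1,
                    continuous = TRUE))
  co <- simulate_cohort(cfg, seed = 16)
  panel <- as_test_panel(co)
  for (v0 in c(2, 5, 8)) {
    loc <- local_fit(panel, co$vas, v0 = v0, bandwidth = 1.2, seed = 5)
    expect_lt(abs(loc$params$se[["CEC"]] - (0.5 + 0.04 * v0)), 0.07)
  }
})

test_that("constant generating specificity yields a near-flat curve", {
  cfg <- cohort_config(
    n = 4000, prevalence = 0.5,
    vas_dist = list(p_zero = 0.05, shape1 = 1, shape2 = 1,
                    continuous = TRUE))
  co <- simulate_cohort(cfg, seed = 17)
  curve <- fit_curve(co, grid = seq(1, 9, by = 1), bandwidth = 1.5,
                     B = 0, seed = 6)
  sp_cec <- curve$estimate[curve$parameter == "specificity" &
                             curve$test == "CEC" & !curve$flagged]
  expect_lt(max(sp_cec) - min(sp_cec), 0.1)
})

test_that("curves carry the grid, bands, flags, and phase stratification", {
  co <- simulate_cohort(scenario_preset("overall", n = 600), seed = 18)
  co$vas <- pmin(co$vas, 8)  # leave VAS > 8 unpopulated

  curve <- fit_curve(co, stratum = "secretory", grid = seq(0, 10, by = 0.25),
                     bandwidth = 1.5, kernel = "epanechnikov", B = 0,
                     seed = 7)
  expect_s3_class(curve, "cec_curve")
  expect_equal(length(unique(curve$vas)), 41)
  expect_true(all(curve$stratum == "secretory"))
  # grid points far beyond the data are flagged, not silently estimated
  expect_true(any(curve$flagged[curve$vas == 10]))

  # flat truth: bootstrap bands cover the generating constants
  small <- simulate_cohort(scenario_preset("overall", n = 500), seed = 19)
  bc <- fit_curve(small, grid = c(2, 5, 8), bandwidth = 2.5, B = 100,
                  seed = 8)
  ok <- !bc$flagged & bc$parameter == "sensitivity" & bc$test == "CEC"
  expect_true(all(bc$lo[ok] <= bc$hi[ok]))
  expect_true(all(bc$lo[ok] - 1e-9 <= bc$estimate[ok] &
                    bc$estimate[ok] <= bc$hi[ok] + 1e-9))
  covered <- bc$lo[ok] <= 0.58 & 0.58 <= bc$hi[ok]
  expect_true(all(covered))
})

test_that("the pooled-phase scenario recovers its constant curve level", {
  cfg <- scenario_preset("by_phase", stratum = "prolif_menstrual", n = 2000)
  co <- simulate_cohort(cfg, seed = 20)
  curve <- fit_curve(co, stratum = "prolif_menstrual",
                     grid = seq(1, 9, by = 2), bandwidth = 2, B = 0,
                     seed = 9)
  se_cec <- curve$estimate[curve$parameter == "sensitivity" &
                             curve$test == "CEC" & !curve$flagged]
  sp_cec <- curve$estimate[curve$parameter == "specificity" &
                             curve$test == "CEC" & !curve$flagged]
  expect_lt(abs(mean(se_cec) - 0.84), 0.05)
  expect_lt(abs(mean(sp_cec) - 0.83), 0.05)
})
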