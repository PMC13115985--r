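test_that("degenerate posteriors make imputation equal hard cross-tabulation", {
  rp <- random_panel(200, seed = 30)
  panel <- cbind(rp$panel, truth = rp$truth)
  gamma <- as.numeric(rp$truth)
  acc <- impute_accuracy(rp$panel, gamma, M = 10, seed = 1)
  naive <- naive_accuracy(panel, reference = "truth")
  for (k in naive$test) {
    expect_equal(acc$sensitivity[acc$test == k],
                 naive$sensitivity[naive$test == k])
    expect_equal(acc$specificity[acc$test == k],
                 naive$specificity[naive$test == k])
  }
  # every draw identical: repeating with another seed changes nothing
  acc2 <- impute_accuracy(rp$panel, gamma, M = 10, seed = 99)
  expect_equal(acc, acc2, ignore_attr = TRUE)
})

test_that("a flat posterior drives imputed accuracy to the marginal rates", {
  # with gamma == pi independent of the data, imputed status is unrelated
  # to the tests, so E[Se_k] is just the marginal positivity rate
  rp <- random_panel(2000, seed = 31, prevalence = 0.4)
  gamma <- rep(0.4, 2000)
  acc <- impute_accuracy(rp$panel, gamma, M = 200, seed = 2)
  for (k in seq_len(3)) {
    marg <- mean(rp$panel[, k])
    expect_lt(abs(acc$sensitivity[k] - marg), 0.02)
    expect_lt(abs(acc$specificity[k] - (1 - marg)), 0.02)
  }
})

test_that("imputation point estimates stabilise in M", {
  co <- simulate_cohort(scenario_preset("overall", n = 500), seed = 32)
  panel <- as_test_panel(co)
  fit <- fit_lca(panel, seed = 3, n_restarts = 5)
  a50 <- impute_accuracy(panel, fit$responsibilities, M = 50, seed = 4)
  a500 <- impute_accuracy(panel, fit$responsibilities, M = 500, seed = 5)
  expect_lt(max(abs(a50$sensitivity - a500$sensitivity)), 0.01)
  expect_lt(max(abs(a50$specificity - a500$specificity)), 0.01)
  expect_error(impute_accuracy(panel, fit$responsibilities, M = 1, seed = 1),
               "at least 2")
})

test_that("bootstrap intervals: determinism, ordering, degenerate cases", {
  d <- tibble::tibble(x = rnorm(100))
  const <- bootstrap_ci(d, function(df) c(k = 1.0), B = 200, seed = 5)
  expect_equal(const$lower, 1)
  expect_equal(const$upper, 1)

  ci1 <- bootstrap_ci(d, function(df) c(m = mean(df$x)), B = 200, seed = 6)
  ci2 <- bootstrap_ci(d, function(df) c(m = mean(df$x)), B = 200, seed = 6)
  expect_identical(ci1, ci2)
  expect_lte(ci1$lower, ci1$upper)

  # failing replicates are dropped up to 10%, then fatal
  flaky <- function(df) if (runif(1) < 0.5) stop("boom") else c(m = mean(df$x))
  expect_error(withr::with_seed(7, bootstrap_ci(d, flaky, B = 200, seed = 8)),
               "10%")
})

test_that("percentile bootstrap of a sample mean attains nominal coverage", {
  n <- 200
  hits <- withr::with_seed(40, {
    vapply(seq_len(200), function(r) {
      x <- tibble::tibble(y = as.numeric(runif(n) < 0.5))
      ci <- suppressMessages(
        bootstrap_ci(x, function(df) c(m = mean(df$y)), B = 1000,
                     seed = 10000 + r))
      ci$lower <= 0.5 && 0.5 <= ci$upper
    }, logical(1))
  })
  expect_gte(mean(hits), 0.91)
  expect_lte(mean(hits), 0.99)
})

test_that("accuracy_report assembles the stratified table with intervals", {
  co <- simulate_cohort(scenario_preset("overall", n = 400), seed = 33)
  tab <- suppressMessages(
    accuracy_report(co, NULL, M = 20, B = 100, seed = 9))
  expect_s3_class(tab, "accuracy_table")
  expect_equal(nrow(tab), 3)
  expect_true(all(c("laparoscopy", "CEC", "CA125") %in% tab$test))
  ok <- !is.na(tab$sensitivity)
  expect_true(all(tab$sens_lo[ok] - 1e-9 <= tab$sensitivity[ok] &
                    tab$sensitivity[ok] <= tab$sens_hi[ok] + 1e-9))
  expect_true(all(tab$spec_lo[ok] - 1e-9 <= tab$specificity[ok] &
                    tab$specificity[ok] <= tab$spec_hi[ok] + 1e-9))
  # the structurally fixed laparoscopy specificity pins its interval at 1
  lap <- tab[tab$test == "laparoscopy", ]
  expect_equal(c(lap$specificity, lap$spec_lo, lap$spec_hi), c(1, 1, 1),
               tolerance = 1e-9)

  # formatted rendering in the conventional style
  txt <- format_accuracy(tab)
  expect_match(txt$specificity[txt$test == "laparoscopy"],
               "^1\\.00 \\(1\\.00, 1\\.00\\)$")

  # an undersized stratum is flagged rather than estimated
  tiny <- co[1:5, ]
  expect_warning(tab2 <- accuracy_report(tiny, NULL, M = 10, B = 100,
                                         seed = 10),
                 "flagged")
  expect_true(all(tab2$flagged))
})

test_that("posterior_from_curve evaluates patients at their own VAS", {
  co <- simulate_cohort(scenario_preset("overall", n = 800), seed = 34)
  panel <- as_test_panel(co)
  curve <- fit_curve(co, grid = c(0, 2, 4, 6, 8, 10), bandwidth = 3,
                     B = 0, seed = 11)
  gamma <- posterior_from_curve(curve, panel, co$vas)
  expect_true(all(gamma >= 0 & gamma <= 1))
  # posteriors must broadly track the latent truth
  expect_gt(mean(gamma[co$true_status]), mean(gamma[!co$true_status]))
})
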