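uniform_params <- function(K = 3, tests = paste0("test", 1:K)) {
  lca_params(0.5, setNames(rep(0.5, K), tests), setNames(rep(0.5, K), tests))
}

test_that("the log-likelihood matches direct mixture enumeration", {
  # uniform tests: every 3-test pattern has probability 1/8
  rp <- random_panel(10, seed = 1)
  ll <- lca_loglik(rp$panel, uniform_params())
  expect_equal(as.numeric(ll), 10 * log(0.125))

  # degenerate: an all-negative patient under pi = 0, perfect specificity
  panel1 <- matrix(0L, 1, 3, dimnames = list(NULL, paste0("test", 1:3)))
  p_deg <- lca_params(0, setNames(runif(3), paste0("test", 1:3)),
                      setNames(rep(1, 3), paste0("test", 1:3)))
  expect_equal(as.numeric(lca_loglik(panel1, p_deg)), 0)

  # random panels (with missingness) against the brute-force oracle
  for (s in 1:5) {
    rp <- random_panel(20, seed = s, miss = 0.15)
    p <- withr::with_seed(100 + s, {
      lca_params(runif(1), setNames(runif(3), colnames(rp$panel)),
                 setNames(runif(3), colnames(rp$panel)))
    })
    expect_equal(as.numeric(lca_loglik(rp$panel, p)),
                 oracle_loglik(rp$panel, p$prevalence, p$se, p$sp))
  }
})

test_that("the E-step is the Bayes posterior, with constraint consequences", {
  tests <- paste0("test", 1:3)
  # uninformative tests (Se = 1 - Sp): posterior equals the prior
  p_unif <- lca_params(0.3, setNames(rep(0.7, 3), tests),
                       setNames(rep(0.3, 3), tests))
  rp <- random_panel(15, seed = 2)
  expect_equal(lca_e_step(rp$panel, p_unif), rep(0.3, 15))

  # positive on a test with Sp = 1 implies disease with certainty
  p_lap <- lca_params(0.4, setNames(c(0.8, 0.6, 0.5), tests),
                      setNames(c(1.0, 0.8, 0.7), tests))
  gamma <- lca_e_step(rp$panel, p_lap)
  expect_true(all(gamma[rp$panel[, 1] == 1] == 1))

  # 8-patient fixture against the enumeration oracle
  rp8 <- random_panel(8, seed = 3, miss = 0.2)
  p <- lca_params(0.45, setNames(c(0.9, 0.7, 0.6), tests),
                  setNames(c(0.95, 0.8, 0.75), tests))
  expect_equal(lca_e_step(rp8$panel, p),
               oracle_posterior(rp8$panel, p$prevalence, p$se, p$sp))
})

test_that("the M-step reproduces weighted-average updates and constraints", {
  rp <- random_panel(30, seed = 4, miss = 0.1)
  gamma1 <- rep(1, 30)
  up <- lca_m_step(rp$panel, gamma1 - 1e-9) # avoid the empty healthy class
  expect_equal(up$prevalence, 1, tolerance = 1e-6)
  for (k in 1:3) {
    y <- rp$panel[, k]
    expect_equal(up$se[[k]], mean(y, na.rm = TRUE), tolerance = 1e-6)
  }

  withr::with_seed(5, gamma <- runif(30))
  up2 <- lca_m_step(rp$panel, gamma)
  oracle <- oracle_m_step(rp$panel, gamma)
  expect_equal(up2$prevalence, oracle$prevalence)
  expect_equal(unname(up2$se), oracle$se)
  expect_equal(unname(up2$sp), oracle$sp)

  cons <- lca_constraints(fixed_sp = c(test1 = 1), anchor = "test1")
  up3 <- lca_m_step(rp$panel, gamma, constraints = cons)
  expect_identical(up3$sp[["test1"]], 1)

  expect_error(lca_m_step(rp$panel, rep(0, 30)), class = "cecdx_empty_class")
})

test_that("EM separates perfectly concordant tests", {
  withr::with_seed(6, d <- rbinom(300, 1, 0.5))
  panel <- cbind(test1 = d, test2 = d, test3 = d)
  fit <- fit_lca(panel, constraints = lca_constraints(anchor = "test1"),
                 seed = 1)
  expect_equal(fit$params$prevalence, mean(d), tolerance = 0.01)
  expect_true(all(fit$params$se > 0.99) && all(fit$params$sp > 0.99))
})

test_that("the EM log-likelihood trace never decreases (100 random fixtures)", {
  for (s in 1:100) {
    rp <- random_panel(25, seed = 200 + s, prevalence = 0.3 + 0.4 * (s %% 2),
                       miss = ifelse(s %% 3 == 0, 0.1, 0))
    fit <- fit_lca(rp$panel, constraints = lca_constraints(anchor = "test1"),
                   n_restarts = 2, seed = s, max_iter = 200)
    expect_true(all(diff(fit$trace) >= -1e-8), label = paste("seed", s))
  }
})

test_that("EM attains at least the best point of a coarse lattice oracle", {
  for (s in 1:3) {
    rp <- random_panel(40 + 10 * s, seed = 300 + s)
    fit <- fit_lca(rp$panel, constraints = lca_constraints(anchor = "test1"),
                   n_restarts = 10, seed = s)
    expect_gte(fit$loglik, oracle_grid_max(rp$panel) - 1e-6)
  }
})

test_that("a perfect pseudo-test collapses EM to naive accuracy against truth", {
  rp <- random_panel(400, seed = 7)
  panel <- cbind(rp$panel, truth = rp$truth)
  cons <- lca_constraints(fixed_se = c(truth = 1), fixed_sp = c(truth = 1),
                          anchor = "truth")
  fit <- fit_lca(panel, constraints = cons, seed = 1, n_restarts = 3)
  naive <- naive_accuracy(panel, reference = "truth")
  for (k in naive$test) {
    expect_equal(fit$params$se[[k]], naive$sensitivity[naive$test == k],
                 tolerance = 1e-6)
    expect_equal(fit$params$sp[[k]], naive$specificity[naive$test == k],
                 tolerance = 1e-6)
  }
})

test_that("fixed parameters survive the whole fit bit-exactly", {
  co <- simulate_cohort(scenario_preset("overall", n = 300), seed = 8)
  panel <- as_test_panel(co)
  fit <- fit_lca(panel, seed = 2, n_restarts = 5)
  expect_identical(fit$params$sp[["laparoscopy"]], 1)
  # anchor resolution: laparoscopy is never anti-informative
  expect_gte(fit$params$se[["laparoscopy"]] + fit$params$sp[["laparoscopy"]], 1)
})

test_that("identifiability and input guards fire", {
  rp <- random_panel(50, K = 2, seed = 9)
  expect_warning(fit_lca(rp$panel, constraints = lca_constraints(anchor = "test1"),
                         n_restarts = 2, seed = 1),
                 "not identifiable")
  expect_error(fit_lca(rp$panel), "mandatory")
})

test_that("naive accuracy reproduces printed cross-tabulated counts", {
  expect_warning(
    res0 <- naive_accuracy(cbind(a = rep(1L, 4), b = c(1L, 0L, 1L, 1L)), "a"),
    "constant")

  ref <- c(rep(1L, 10), rep(0L, 10))
  same <- naive_accuracy(cbind(ref = ref, t = ref), "ref")
  expect_equal(c(same$sensitivity, same$specificity), c(1, 1))
  opp <- naive_accuracy(cbind(ref = ref, t = 1L - ref), "ref")
  expect_equal(c(opp$sensitivity, opp$specificity), c(0, 0))

  # printed-count fixture: 55/86 positive among diseased, 36/146 among controls
  ref2 <- c(rep(1L, 86), rep(0L, 146))
  cec <- c(rep(1L, 55), rep(0L, 31), rep(1L, 36), rep(0L, 110))
  acc <- naive_accuracy(cbind(ref = ref2, CEC = cec), "ref")
  expect_equal(round(acc$sensitivity, 3), 0.640)
  expect_equal(round(acc$specificity, 3), 0.753)
})
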