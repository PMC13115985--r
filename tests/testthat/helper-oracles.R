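# Independent oracle implementations, deliberately naive: plain loops and
# direct enumeration, sharing no code with the package internals.

# Mixture likelihood of one response pattern, computed term by term.
oracle_pattern_prob <- function(y, prevalence, se, sp) {
  se <- unname(se)
  sp <- unname(sp)
  p1 <- unname(prevalence)
  p0 <- 1 - p1
  for (k in seq_along(y)) {
    if (is.na(y[k])) next
    if (y[k] == 1) {
      p1 <- p1 * se[k]
      p0 <- p0 * (1 - sp[k])
    } else {
      p1 <- p1 * (1 - se[k])
      p0 <- p0 * sp[k]
    }
  }
  c(p1 = p1, p0 = p0)
}

oracle_loglik <- function(panel, prevalence, se, sp) {
  ll <- 0
  for (i in seq_len(nrow(panel))) {
    p <- oracle_pattern_prob(panel[i, ], prevalence, se, sp)
    ll <- ll + log(p["p1"] + p["p0"])
  }
  unname(ll)
}

oracle_posterior <- function(panel, prevalence, se, sp) {
  sapply(seq_len(nrow(panel)), function(i) {
    p <- oracle_pattern_prob(panel[i, ], prevalence, se, sp)
    unname(p["p1"] / (p["p1"] + p["p0"]))
  })
}

# Weighted-average M-step oracle.
oracle_m_step <- function(panel, gamma) {
  K <- ncol(panel)
  se <- sp <- numeric(K)
  for (k in seq_len(K)) {
    y <- panel[, k]
    obs <- !is.na(y)
    se[k] <- sum(gamma[obs] * y[obs]) / sum(gamma[obs])
    sp[k] <- sum((1 - gamma[obs]) * (1 - y[obs])) / sum(1 - gamma[obs])
  }
  list(prevalence = mean(gamma), se = se, sp = sp)
}

# Best log-likelihood over a coarse lattice in which all tests share one
# (se, sp) pair -- a subset of the model's parameter space, so its maximum
# lower-bounds the true maximum likelihood.
oracle_grid_max <- function(panel, step = 0.05) {
  vals <- seq(0, 1, by = step)
  best <- -Inf
  for (prev in vals) {
    for (se in vals) {
      for (sp in vals) {
        ll <- oracle_loglik(panel, prev, rep(se, ncol(panel)),
                            rep(sp, ncol(panel)))
        if (ll > best) best <- ll
      }
    }
  }
  best
}

# Random small test panel straight from the two-class model.
random_panel <- function(n, K = 3, prevalence = 0.5, se = NULL, sp = NULL,
                         seed, miss = 0) {
  withr::with_seed(seed, {
    se <- se %||% runif(K, 0.6, 0.95)
    sp <- sp %||% runif(K, 0.6, 0.95)
    d <- rbinom(n, 1, prevalence)
    panel <- sapply(seq_len(K), function(k) {
      p <- ifelse(d == 1, se[k], 1 - sp[k])
      as.integer(runif(n) < p)
    })
    if (miss > 0) panel[runif(length(panel)) < miss] <- NA
    colnames(panel) <- paste0("test", seq_len(K))
    list(panel = panel, truth = d, se = se, sp = sp)
  })
}

`%||%` <- function(x, y) if (is.null(x)) y else x
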