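# Disproportionality statistics: ROR, PRR, BCPNN IC, MGPS/EBGM, FDR
# adjustment, tiering, label comparison.

random_tables <- function(n, seed = 1, lambda = c(5, 50, 100, 5000)) {
  set.seed(seed)
  data.frame(a = rpois(n, lambda[1]) + 1, b = rpois(n, lambda[2]) + 1,
             c = rpois(n, lambda[3]) + 1, d = rpois(n, lambda[4]) + 1)
}

test_that("ROR point estimates and Haldane correction are exact", {
  r <- ror_signal(5, 5, 5, 5)
  expect_equal(r$ror, 1)
  expect_false(r$ror_flag)
  expect_equal(ror_signal(6, 10, 100, 10000)$ror, 60)
  # zero cell: 0.5 added to all four cells -> 3.5*1000.5/(0.5*10.5)
  rz <- ror_signal(3, 0, 10, 1000)
  expect_true(rz$corrected)
  expect_equal(rz$ror, 3.5 * 1000.5 / (0.5 * 10.5))
  # interval ordering invariant
  expect_true(all(rz$ror_lower <= rz$ror & rz$ror <= rz$ror_upper))
})

test_that("PRR estimate, chi-square and case-minimum rule are exact", {
  p <- prr_signal(10, 90, 10, 890)
  expect_equal(p$prr, (10 / 100) / (10 / 900))
  # equal proportions on both margins
  expect_equal(prr_signal(5, 45, 20, 180)$prr, 1)
  expect_false(prr_signal(5, 45, 20, 180)$prr_flag)
  # a = 2 never flags regardless of the estimate
  big <- prr_signal(2, 8, 1, 989)
  expect_gt(big$prr, 2)
  expect_false(big$prr_flag)
})

test_that("ROR and PRR equal brute-force ratio evaluation on random tables", {
  tabs <- random_tables(1000, seed = 7)
  rr <- ror_signal(tabs$a, tabs$b, tabs$c, tabs$d)
  pr <- prr_signal(tabs$a, tabs$b, tabs$c, tabs$d)
  for (i in seq_len(nrow(tabs))) {
    with(tabs[i, ], {
      expect_lt(abs(rr$ror[i] - (a * d) / (b * c)) / rr$ror[i], 1e-12)
      expect_lt(abs(pr$prr[i] - (a / (a + b)) / (c / (c + d))) / pr$prr[i],
                1e-12)
    })
  }
  # when the focal event share is small and ROR > 1, ROR >= PRR
  small <- random_tables(500, seed = 8, lambda = c(3, 200, 50, 5000))
  rr <- ror_signal(small$a, small$b, small$c, small$d)
  pr <- prr_signal(small$a, small$b, small$c, small$d)
  up <- rr$ror > 1
  expect_true(all(rr$ror[up] >= pr$prr[up]))
})

test_that("information component matches its closed form", {
  # a = E gives IC = 0 exactly
  ic <- bcpnn_ic(10, 90, 90, 810)  # E = 100*100/1000 = 10
  expect_equal(ic$ic, 0)
  # a = 0, E = 10 -> log2(0.5/10.5)
  ic0 <- bcpnn_ic(0, 100, 91, 719)  # E = 100*91/910 = 10
  expect_equal(ic0$ic, log2(0.5 / 10.5), tolerance = 1e-12)
  expect_equal(ic0$ic, -4.392, tolerance = 1e-3)
  # the credible-bound penalty is strictly positive
  tabs <- random_tables(200, seed = 9)
  icr <- bcpnn_ic(tabs$a, tabs$b, tabs$c, tabs$d)
  expect_true(all(icr$ic025 < icr$ic))
})

test_that("MGPS prior recovers a null database and is order invariant", {
  set.seed(51)
  E <- runif(600, 0.5, 60)
  a <- rpois(600, E)  # lambda = 1 everywhere
  expect_warning(prior <- fit_mgps_prior(a, E), NA)
  pm <- prior$mixture_weight * prior$alpha1 / prior$beta1 +
    (1 - prior$mixture_weight) * prior$alpha2 / prior$beta2
  expect_gte(pm, 0.8)
  expect_lte(pm, 1.25)
  # permuting the cells leaves the fit unchanged
  perm <- sample(600)
  prior2 <- fit_mgps_prior(a[perm], E[perm])
  expect_equal(prior2$log_marginal, prior$log_marginal, tolerance = 1e-6)
  expect_equal(prior2$alpha1, prior$alpha1, tolerance = 1e-4)
  # optimization improves on the default start
  default_ll <- sum(log(
    (1 / 3) * dnbinom(a, size = 0.2, prob = 0.1 / (0.1 + E)) +
      (2 / 3) * dnbinom(a, size = 2, prob = 4 / (4 + E))))
  expect_gte(prior$log_marginal, default_ll)
})

test_that("EBGM shrinks toward the prior and matches numeric integration", {
  set.seed(52)
  E <- runif(200, 1, 50)
  a <- rpois(200, E)
  prior <- fit_mgps_prior(a, E)
  # zero count under a prior centred near 1 -> EBGM < 1
  z <- ebgm_signal(0, 10, prior)
  expect_lt(z$ebgm, 1)
  # strong signal shrinks between 1 and the raw ratio
  s <- ebgm_signal(200, 20, prior)
  expect_gt(s$ebgm, 1)
  expect_lt(s$ebgm, 10)
  # quantile below the geometric mean across a grid
  grid <- ebgm_signal(c(0, 1, 3, 10, 50, 120), c(2, 2, 5, 9, 40, 20), prior)
  expect_true(all(grid$ebgm05 <= grid$ebgm))
  # numeric-integration oracle for the posterior mean of log2(lambda) and
  # for the 5th percentile
  for (i in 1:3) {
    ai <- c(4, 30, 0)[i]; Ei <- c(2, 10, 6)[i]
    f1 <- dnbinom(ai, size = prior$alpha1,
                  prob = prior$beta1 / (prior$beta1 + Ei))
    f2 <- dnbinom(ai, size = prior$alpha2,
                  prob = prior$beta2 / (prior$beta2 + Ei))
    w1 <- prior$mixture_weight * f1
    w2 <- (1 - prior$mixture_weight) * f2
    Q <- w1 / (w1 + w2)
    # a fitted component can be a near-delta spike, so each component is
    # integrated over its own quantile-adapted range
    comp_mean_log <- function(shape, rate) {
      lo <- qgamma(1e-14, shape, rate = rate)
      hi <- qgamma(1 - 1e-14, shape, rate = rate)
      integrate(function(x) log(x) * dgamma(x, shape, rate = rate), lo, hi,
                rel.tol = 1e-10, subdivisions = 800L)$value
    }
    comp_cdf <- function(x, shape, rate) {
      lo <- qgamma(1e-14, shape, rate = rate)
      if (x <= lo) return(0)
      hi <- min(x, qgamma(1 - 1e-14, shape, rate = rate))
      if (hi <= lo) return(0)
      p <- integrate(function(y) dgamma(y, shape, rate = rate), lo, hi,
                     rel.tol = 1e-10, subdivisions = 800L)$value
      min(p + (if (x > hi) 1e-14 else 0), 1)
    }
    m <- Q * comp_mean_log(prior$alpha1 + ai, prior$beta1 + Ei) +
      (1 - Q) * comp_mean_log(prior$alpha2 + ai, prior$beta2 + Ei)
    got <- ebgm_signal(ai, Ei, prior)
    expect_equal(got$ebgm, exp(m), tolerance = 1e-6)
    cdf05 <- Q * comp_cdf(got$ebgm05, prior$alpha1 + ai, prior$beta1 + Ei) +
      (1 - Q) * comp_cdf(got$ebgm05, prior$alpha2 + ai, prior$beta2 + Ei)
    expect_equal(cdf05, 0.05, tolerance = 1e-4)
  }
})

test_that("FDR adjustment reproduces the worked example and is monotone", {
  expect_equal(adjust_fdr(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  expect_equal(adjust_fdr(rep(0.2, 5)), rep(0.2, 5))
  set.seed(53)
  p <- runif(50)
  adj <- adjust_fdr(p)
  expect_true(all(adj >= p))
  o <- order(p)
  expect_true(all(diff(adj[o]) >= -1e-15))
  expect_equal(adjust_fdr(c(0.01, 0.5), "bonferroni"), c(0.02, 1))
  expect_error(adjust_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("signals are tiered by the cross-validation rule", {
  expect_equal(classify_signal(TRUE, TRUE, TRUE, TRUE), "cross_validated")
  expect_equal(classify_signal(TRUE, FALSE, FALSE, FALSE),
               "hypothesis_generating")
  expect_equal(classify_signal(TRUE, TRUE, FALSE, TRUE),
               "hypothesis_generating")
  expect_equal(classify_signal(FALSE, FALSE, FALSE, FALSE), "negative")
})

test_that("label comparison is case-insensitive and reports unlisted PTs", {
  sig <- data.table::data.table(
    label = c("NAUSEA", "FACIAL PARALYSIS", "RASH"),
    tier = c("cross_validated", "cross_validated", "negative"))
  out <- compare_to_label(sig, c("nausea", "rash"))
  expect_equal(out$label, "FACIAL PARALYSIS")
  expect_warning(compare_to_label(sig, character()), "unlisted")
  empty <- compare_to_label(sig[0], c("nausea"))
  expect_equal(nrow(empty), 0L)
})

test_that("signal_metrics assembles consistent per-PT rows", {
  cfg <- synthetic_config(n_reports = 10000, seed = 61)
  rep <- replicate_tables(cfg, seed = 61)
  sig <- signal_metrics(rep$tables)
  expect_equal(nrow(sig), nrow(rep$tables))
  expect_true(all(sig$ror_lower <= sig$ror & sig$ror <= sig$ror_upper))
  expect_true(all(sig$ic025 <= sig$ic))
  expect_true(all(sig$ebgm05 <= sig$ebgm))
  fam <- !is.na(sig$p_adjusted)
  expect_true(all(sig$p_adjusted[fam] >= sig$p_value[fam]))
  expect_true(all(sig$tier %in%
                    c("cross_validated", "hypothesis_generating", "negative")))
})
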