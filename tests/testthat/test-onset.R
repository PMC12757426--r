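# Time-to-onset: interval construction, summaries, Weibull fitting,
# cumulative curves, log-rank comparison.

test_that("TTO intervals are computed with the stated exclusions", {
  ther <- data.table::data.table(
    primary_id = c("1", "2", "3", "4", "5", "5"),
    start_date = c("20240101", "20240101", "20240105", "", "20240110",
                   "20240103"))
  ev <- data.table::data.table(
    primary_id = c("1", "2", "3", "4", "5"),
    event_date = c("20240108", "20231231", "20240105", "20240110", "20240111"))
  tto <- compute_tto(ther, ev)
  # report 1: 7 days; report 2: negative, excluded; report 3: same day ->
  # 0, included; report 4: missing start; report 5: earliest of two starts
  expect_equal(tto$tto_days[tto$primary_id == "1"], 7L)
  expect_false("2" %in% tto$primary_id)
  expect_equal(tto$tto_days[tto$primary_id == "3"], 0L)
  expect_equal(tto$tto_days[tto$primary_id == "5"], 8L)
  excl <- attr(tto, "exclusions")
  expect_equal(unname(excl["negative"]), 1L)
  expect_equal(unname(excl["missing_start"]), 1L)
  # accounting: records in = used + excluded
  expect_equal(nrow(tto) + sum(excl), 5L)
  # partial dates were flagged missing upstream of arithmetic
  ther2 <- data.table::data.table(primary_id = "9", start_date = "202401")
  ev2 <- data.table::data.table(primary_id = "9", event_date = "20240110")
  expect_equal(unname(attr(compute_tto(ther2, ev2),
                           "exclusions")["missing_start"]), 1L)
})

test_that("TTO summaries use the linear-interpolation quartiles", {
  s <- summarize_tto(c(2, 7, 23))
  expect_equal(s$median, 7)
  expect_equal(summarize_tto(rep(5, 9))[c("median", "q1", "q3")],
               list(median = 5, q1 = 5, q3 = 5))
  expect_error(summarize_tto(numeric()), "no time-to-onset")
  # Monte-Carlo: 113 draws from the reference early-failure Weibull have a
  # median near alpha*(log 2)^(1/beta) ~ 9.3. The binomial order-statistic
  # oracle gives the band: P(median <= x) = P(Bin(113, F(x)) >= 57), so
  # [4, 16] has ~97% coverage.
  band_coverage <- pbinom(56, 113, pweibull(4, 0.49, 19.73)) -
    pbinom(56, 113, pweibull(16, 0.49, 19.73))
  expect_gte(band_coverage, 0.95)
  set.seed(81)
  hit <- 0
  for (r in 1:60) {
    m <- summarize_tto(round(rweibull(113, 0.49, 19.73)))$median
    if (m >= 4 && m <= 16) hit <- hit + 1
  }
  expect_gte(hit / 60, 0.9)
})

test_that("Weibull fit beats random restarts and matches a grid oracle", {
  set.seed(82)
  x <- rweibull(100, shape = 0.7, scale = 15)
  fit <- weibull_fit(x)
  # local-optimum guard: fitted likelihood >= 50 random restarts
  for (i in 1:50) {
    expect_gte(fit$log_likelihood + 1e-6,
               weibull_loglik(x, runif(1, 0.2, 3), runif(1, 1, 60)))
  }
  # dense 200 x 200 grid oracle within one grid cell
  g <- oracle_weibull_grid(x, c(0.3, 1.5), c(5, 40))
  expect_lt(abs(fit$shape_beta - g$shape), g$d_shape * 1.5)
  expect_lt(abs(fit$scale_alpha - g$scale), g$d_scale * 1.5)
})

test_that("failure types follow the shape-parameter interval rule", {
  set.seed(83)
  # decreasing hazard: shape CI entirely below 1 -> early failure
  early <- weibull_fit(rweibull(2000, 0.49, 19.73))
  expect_lt(early$shape_ci[2], 1)
  expect_equal(early$failure_type, "early_failure")
  # increasing hazard
  late <- weibull_fit(rweibull(2000, 2.2, 20))
  expect_equal(late$failure_type, "wear_out")
  # constant hazard: the interval covers 1 in most replicates
  hits <- 0
  for (r in 1:100) {
    f <- weibull_fit(rexp(500, 1 / 15))
    if (f$shape_ci[1] <= 1 && f$shape_ci[2] >= 1) hits <- hits + 1
  }
  expect_gte(hits / 100, 0.9)
  expect_error(weibull_fit(rep(3, 20)), "distinct")
  expect_warning(weibull_fit(c(1, 2, 4, 9)), "fewer than 10")
})

test_that("day-zero events are offset for fitting only", {
  set.seed(84)
  days <- round(rweibull(800, 0.6, 10))
  expect_true(any(days == 0))
  f_auto <- weibull_fit(days, offset = "auto")
  expect_equal(f_auto$offset_used, 0.5)
  f_none <- weibull_fit(days + 1, offset = "none")
  expect_equal(f_none$offset_used, 0)
  # bootstrap interval is seeded and ordered
  set.seed(85)
  fb <- weibull_fit(days, ci = "bootstrap", n_boot = 100)
  expect_lt(fb$shape_ci[1], fb$shape_ci[2])
})

test_that("cumulative onset curves are proper ECDFs", {
  one <- data.table::data.table(primary_id = "1", tto_days = 7L)
  c1 <- cumulative_onset(one)
  expect_equal(c1$day, 7L)
  expect_equal(c1$cum_frac, 1)
  set.seed(86)
  rec <- data.table::data.table(
    primary_id = as.character(1:300),
    tto_days = round(rweibull(300, 0.5, 20)),
    sex = sample(c("female", "male"), 300, TRUE))
  cur <- cumulative_onset(rec, by = "sex")
  for (g in unique(cur$group)) {
    cc <- cur[cur$group == g, ]
    expect_true(all(diff(cc$cum_frac) > 0))
    expect_equal(max(cc$cum_frac), 1)
    expect_equal(max(cc$day), max(rec$tto_days[rec$sex == g]))
    # group medians agree with summarize_tto
    expect_equal(attr(cur, "summaries")[[g]]$median,
                 summarize_tto(rec$tto_days[rec$sex == g])$median)
  }
})

test_that("the log-rank test matches a hand oracle and detects separation", {
  # identical samples -> statistic 0, p 1
  same <- logrank_tto(c(1, 3, 5, 1, 3, 5), rep(c("f", "m"), each = 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  # six-observation worked fixture against the textbook computation
  t6 <- c(1, 3, 5, 2, 4, 6)
  g6 <- rep(c("A", "B"), each = 3)
  got <- logrank_tto(t6, g6)
  expect_equal(got$statistic, oracle_logrank(t6, g6), tolerance = 1e-10)
  expect_error(logrank_tto(c(1, 2), c("A", "A")), "two non-empty")
  # power: medians 6 vs 14 at n = 200 per arm separate most of the time
  set.seed(87)
  sig <- 0
  for (r in 1:50) {
    f <- rweibull(200, 1.2, 6 / log(2)^(1 / 1.2))
    m <- rweibull(200, 1.2, 14 / log(2)^(1 / 1.2))
    p <- logrank_tto(c(f, m), rep(c("F", "M"), each = 200))$p_value
    if (p < 0.05) sig <- sig + 1
  }
  expect_gte(sig / 50, 0.8)
})
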