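# Independent oracles used across test files. Each deliberately takes a
# different computational route from the implementation it checks.

# Two-sided Fisher p by explicit enumeration: hypergeometric probabilities
# from binomial coefficients (lchoose), summing those not exceeding the
# observed table's probability (same 1e-7 relative tie guard as the
# stated convention).
oracle_fisher_enum <- function(a, b, c, d) {
  m <- a + b; n2 <- c + d; k <- a + c; N <- m + n2
  xs <- max(0, k - n2):min(k, m)
  logp <- lchoose(m, xs) + lchoose(n2, k - xs) - lchoose(N, k)
  p <- exp(logp)
  obs <- exp(lchoose(m, a) + lchoose(n2, c) - lchoose(N, k))
  min(sum(p[p <= obs * (1 + 1e-7)]), 1)
}

# Textbook log-rank statistic: observed-minus-expected group-1 events at
# each distinct event time, hypergeometric variance, chi-square on 1 df.
oracle_logrank <- function(times, group) {
  g <- as.integer(factor(group))
  ts <- sort(unique(times))
  OE <- 0; V <- 0
  for (t in ts) {
    at_risk <- times >= t
    n <- sum(at_risk); n1 <- sum(at_risk & g == 1)
    d <- sum(times == t); d1 <- sum(times == t & g == 1)
    OE <- OE + d1 - d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  OE^2 / V
}

# Dense grid-search Weibull maximum likelihood (shape x scale grid).
oracle_weibull_grid <- function(x, shape_lim, scale_lim, n_grid = 200) {
  shapes <- seq(shape_lim[1], shape_lim[2], length.out = n_grid)
  scales <- seq(scale_lim[1], scale_lim[2], length.out = n_grid)
  ll <- function(sh, sc) sum(dweibull(x, sh, sc, log = TRUE))
  best <- c(NA, NA, -Inf)
  for (sh in shapes) {
    lls <- vapply(scales, function(sc) ll(sh, sc), numeric(1))
    i <- which.max(lls)
    if (lls[i] > best[3]) best <- c(sh, scales[i], lls[i])
  }
  list(shape = best[1], scale = best[2], loglik = best[3],
       d_shape = diff(shape_lim) / (n_grid - 1),
       d_scale = diff(scale_lim) / (n_grid - 1))
}

# Weibull log-likelihood for the restart guard.
weibull_loglik <- function(x, shape, scale) {
  sum(dweibull(x, shape, scale, log = TRUE))
}
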