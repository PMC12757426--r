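# The four disproportionality statistics and signal classification.
#
# ROR and PRR are frequentist screening statistics with the conventional
# pharmacovigilance positivity thresholds. The BCPNN information component
# uses the closed-form shrinkage estimate with the Noren credible-bound
# approximation. MGPS is DuMouchel's empirical Bayes gamma-Poisson
# shrinker: a two-component gamma mixture prior on the relative reporting
# rate, fitted by marginal maximum likelihood over all drug-event cells.

haldane <- function(a, b, c, d) {
  corrected <- a == 0 | b == 0 | c == 0 | d == 0
  k <- ifelse(corrected, 0.5, 0)
  list(a = a + k, b = b + k, c = c + k, d = d + k, corrected = corrected)
}

#' Reporting odds ratio
#'
#' `ROR = (a d) / (b c)` with a Woolf (log-scale Wald) 95% confidence
#' interval. Any zero cell triggers the Haldane correction (0.5 added to
#' all four cells) and the row is marked `corrected`. The default
#' positivity rule flags a PT when the point estimate is at least
#' `ror_min` (3) and the CI lower bound exceeds `ci_lower_min` (1); the
#' conventional alternative rule (`rule = "cases"`) replaces the
#' point-estimate condition with a minimum of `min_cases` reports.
#'
#' @param a,b,c,d integer vectors of 2x2 cell counts (focal-with-event,
#'   focal-without, other-with, other-without).
#' @param ror_min,ci_lower_min,min_cases positivity thresholds.
#' @param rule `"estimate"` (default) or `"cases"`.
#' @param conf confidence level.
#' @return `data.table` with `ror`, `ror_lower`, `ror_upper`, `corrected`,
#'   `ror_flag`.
#' @export
ror_signal <- function(a, b, c, d, ror_min = 3, ci_lower_min = 1,
                       min_cases = 3, rule = c("estimate", "cases"),
                       conf = 0.95) {
  rule <- match.arg(rule)
  stopifnot(all(a >= 0), all(b >= 0), all(c >= 0), all(d >= 0))
  h <- haldane(a, b, c, d)
  est <- (h$a * h$d) / (h$b * h$c)
  z <- qnorm(1 - (1 - conf) / 2)
  se <- sqrt(1 / h$a + 1 / h$b + 1 / h$c + 1 / h$d)
  lower <- exp(log(est) - z * se)
  upper <- exp(log(est) + z * se)
  flag <- if (rule == "estimate") {
    est >= ror_min & lower > ci_lower_min
  } else {
    a >= min_cases & lower > ci_lower_min
  }
  data.table::data.table(ror = est, ror_lower = lower, ror_upper = upper,
                         corrected = h$corrected, ror_flag = flag)
}

#' Proportional reporting ratio
#'
#' `PRR = [a/(a+b)] / [c/(c+d)]` with the uncorrected Pearson chi-square
#' statistic of the same table (1 df, two-sided p). The positivity rule is
#' `PRR >= prr_min`, `chi2 >= chi2_min`, and at least `min_cases` focal
#' reports of the event. Zero cells are Haldane-corrected for both the
#' estimate and the statistic and marked.
#'
#' @inheritParams ror_signal
#' @param prr_min,chi2_min,min_cases positivity thresholds.
#' @return `data.table` with `prr`, `chi2`, `p_value`, `corrected`,
#'   `prr_flag`.
#' @export
prr_signal <- function(a, b, c, d, prr_min = 2, chi2_min = 4, min_cases = 3) {
  stopifnot(all(a + b > 0), all(c + d > 0))
  h <- haldane(a, b, c, d)
  est <- (h$a / (h$a + h$b)) / (h$c / (h$c + h$d))
  N <- h$a + h$b + h$c + h$d
  chi2 <- N * (h$a * h$d - h$b * h$c)^2 /
    ((h$a + h$b) * (h$c + h$d) * (h$a + h$c) * (h$b + h$d))
  p <- pchisq(chi2, df = 1, lower.tail = FALSE)
  flag <- est >= prr_min & chi2 >= chi2_min & a >= min_cases
  data.table::data.table(prr = est, chi2 = chi2, p_value = p,
                         corrected = h$corrected, prr_flag = flag)
}

#' BCPNN information component (closed form)
#'
#' Shrinkage information component
#' `IC = log2((a + 0.5) / (E + 0.5))` with expected count
#' `E = (a+b)(a+c)/N`, and the Noren approximation to the lower 95%
#' credible bound
#' `IC025 = IC - 3.3 (a+0.5)^{-1/2} - 2 (a+0.5)^{-3/2}`.
#' A PT is flagged when `IC025 > 0`. With `ic_mode = "ic_from_ebgm"` the
#' point estimate is taken as `log2(EBGM)` (some published signal tables
#' print the information component on that convention); the credible bound
#' keeps the closed-form penalty.
#'
#' @inheritParams ror_signal
#' @param ic_mode `"closed_form"` (default) or `"ic_from_ebgm"`.
#' @param ebgm EBGM point estimates, required for `"ic_from_ebgm"`.
#' @return `data.table` with `ic`, `ic025`, `ic_flag`.
#' @export
bcpnn_ic <- function(a, b, c, d, ic_mode = c("closed_form", "ic_from_ebgm"),
                     ebgm = NULL) {
  ic_mode <- match.arg(ic_mode)
  N <- a + b + c + d
  stopifnot(all(N > 0))
  E <- (a + b) * (a + c) / N
  ic <- log2((a + 0.5) / (E + 0.5))
  if (ic_mode == "ic_from_ebgm") {
    if (is.null(ebgm)) stop("ic_from_ebgm mode needs EBGM estimates")
    ic <- log2(ebgm)
  }
  ic025 <- ic - 3.3 * (a + 0.5)^(-0.5) - 2 * (a + 0.5)^(-1.5)
  data.table::data.table(ic = ic, ic025 = ic025, ic_flag = ic025 > 0)
}

# Log marginal likelihood of observed counts under the two-component
# negative-binomial mixture induced by lambda ~ P Gamma(a1, b1) +
# (1-P) Gamma(a2, b2) and a | lambda ~ Poisson(lambda E).
mgps_loglik <- function(theta, a, E) {
  a1 <- exp(theta[1]); b1 <- exp(theta[2])
  a2 <- exp(theta[3]); b2 <- exp(theta[4])
  P <- stats::plogis(theta[5])
  l1 <- dnbinom(a, size = a1, prob = b1 / (b1 + E), log = TRUE)
  l2 <- dnbinom(a, size = a2, prob = b2 / (b2 + E), log = TRUE)
  m <- pmax(l1, l2)
  sum(m + log(P * exp(l1 - m) + (1 - P) * exp(l2 - m)))
}

#' Fit the MGPS gamma-mixture prior
#'
#' Maximizes the marginal likelihood of the observed a-cells over all
#' drug-event combinations under DuMouchel's two-component gamma mixture
#' prior on the relative reporting rate. Optimization is multi-start
#' bounded quasi-Newton (L-BFGS-B on log/logit-transformed parameters)
#' from the DuMouchel default start `(0.2, 0.1, 2.0, 4.0, 1/3)` plus
#' perturbed restarts.
#'
#' @param a observed focal-with-event counts, one per drug-event cell.
#' @param E expected counts under independence, `(a+b)(a+c)/N`.
#' @param extra_starts number of additional perturbed starts.
#' @return object of class `mgps_prior`: `alpha1`, `beta1`, `alpha2`,
#'   `beta2`, `mixture_weight`, `log_marginal`, `convergence`.
#' @export
fit_mgps_prior <- function(a, E, extra_starts = 6) {
  stopifnot(length(a) == length(E), all(E > 0), all(a >= 0))
  if (length(a) < 50) {
    warning("fewer than 50 drug-event cells; MGPS prior may be unstable")
  }
  default <- c(log(0.2), log(0.1), log(2), log(4), stats::qlogis(1 / 3))
  starts <- list(default)
  set <- c(0.5, 2, 0.25, 4, 1, 0.1)
  for (i in seq_len(extra_starts)) {
    starts[[i + 1]] <- default + c(log(set[(i %% 6) + 1]), 0.5 * (-1)^i,
                                   0.3 * i %% 2, -0.3, 0.2 * (-1)^i)
  }
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      optim(s, function(th) -mgps_loglik(th, a, E), method = "L-BFGS-B",
            lower = c(rep(log(1e-6), 4), -12), upper = c(rep(log(1e6), 4), 12),
            control = list(maxit = 500)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) stop("MGPS prior fit failed from every start")
  if (best$convergence != 0) {
    # L-BFGS-B occasionally aborts its line search at a stationary point;
    # accept the iterate when the gradient is numerically flat
    gr <- tryCatch(max(abs(numeric_grad(
      function(th) -mgps_loglik(th, a, E), best$par))), error = function(e) NA)
    if (!is.finite(gr) || gr > 1e-2 * max(1, abs(best$value))) {
      stop("MGPS prior fit did not converge; best nll = ",
           signif(best$value, 8), ", max |grad| = ", signif(gr, 4))
    }
    best$convergence <- 0L
  }
  th <- best$par
  structure(list(alpha1 = exp(th[1]), beta1 = exp(th[2]),
                 alpha2 = exp(th[3]), beta2 = exp(th[4]),
                 mixture_weight = stats::plogis(th[5]),
                 log_marginal = -best$value,
                 n_cells = length(a), convergence = best$convergence),
            class = "mgps_prior")
}

numeric_grad <- function(f, x, eps = 1e-6) {
  vapply(seq_along(x), function(i) {
    h <- eps * max(1, abs(x[i]))
    xp <- x; xp[i] <- x[i] + h
    xm <- x; xm[i] <- x[i] - h
    (f(xp) - f(xm)) / (2 * h)
  }, numeric(1))
}

#' @export
print.mgps_prior <- function(x, ...) {
  cat("MGPS gamma-mixture prior (", x$n_cells, " cells)\n", sep = "")
  cat(sprintf("  P = %.3f, Gamma(%.4g, %.4g) / Gamma(%.4g, %.4g)\n",
              x$mixture_weight, x$alpha1, x$beta1, x$alpha2, x$beta2))
  cat(sprintf("  prior mean = %.3f, log marginal = %.2f\n",
              x$mixture_weight * x$alpha1 / x$beta1 +
                (1 - x$mixture_weight) * x$alpha2 / x$beta2,
              x$log_marginal))
  invisible(x)
}

# Prior mean of the relative reporting rate.
mgps_prior_mean <- function(prior) {
  prior$mixture_weight * prior$alpha1 / prior$beta1 +
    (1 - prior$mixture_weight) * prior$alpha2 / prior$beta2
}

#' Build the full drug-event cell family for the MGPS prior
#'
#' The empirical Bayes prior is meant to be fitted across a null-dominated
#' family of drug-event combinations — every drug in the database crossed
#' with every observed PT — not just the focal drug's cells. For each
#' (drug, PT) pair this returns the observed report count `a` and the
#' expected count under independence `E = n_drug x n_pt / N` (zero-count
#' pairs included).
#'
#' @param case_ids all deduplicated report ids.
#' @param reactions report-level reaction table (`primary_id`, `pt`).
#' @param drugs report-level drug table (`primary_id`, `drug_name`; every
#'   role participates, the DuMouchel convention).
#' @return `data.table` with `drug_name`, `pt`, `a`, `E`.
#' @export
mgps_cells <- function(case_ids, reactions, drugs) {
  ids <- unique(as.character(case_ids))
  N <- length(ids)
  rd <- unique(data.table::as.data.table(drugs)[
    primary_id %in% ids, .(primary_id = as.character(primary_id), drug_name)])
  rp <- unique(data.table::as.data.table(reactions)[
    primary_id %in% ids, .(primary_id = as.character(primary_id), pt)])
  n_drug <- rd[, .(n_d = .N), by = drug_name]
  n_pt <- rp[, .(n_p = .N), by = pt]
  obs <- merge(rd, rp, by = "primary_id",
               allow.cartesian = TRUE)[, .(a = .N), by = .(drug_name, pt)]
  grid <- data.table::CJ(drug_name = n_drug$drug_name, pt = n_pt$pt)
  grid <- merge(grid, obs, by = c("drug_name", "pt"), all.x = TRUE)
  grid[is.na(a), a := 0L]
  grid <- merge(grid, n_drug, by = "drug_name")
  grid <- merge(grid, n_pt, by = "pt")
  grid[, E := n_d * n_p / N]
  data.table::setorder(grid, drug_name, pt)
  grid[, .(drug_name, pt, a, E)]
}

#' Empirical Bayes geometric mean (EBGM)
#'
#' Posterior summaries under a fitted MGPS prior. Given a cell with count
#' `a` and expected count `E`, the posterior on the relative reporting
#' rate is a gamma mixture with components `Gamma(alpha1 + a, beta1 + E)`
#' and `Gamma(alpha2 + a, beta2 + E)` and weights updated by the component
#' marginal likelihoods. `EBGM = 2^{E[log2 lambda | a]}` and `EBGM05` is
#' the 5th posterior percentile, solved by bisection to
#' `|CDF - 0.05| < 1e-8`. The positivity rule is `EBGM05 > ebgm05_min`
#' (default 2); the companion condition `EBGM > 0` holds for every cell
#' and is recorded as vacuous.
#'
#' @param a,E cell counts and expected counts.
#' @param prior a fitted [fit_mgps_prior()] object.
#' @param ebgm05_min positivity threshold on the 5th percentile.
#' @return `data.table` with `ebgm`, `ebgm05`, `ebgm_flag`.
#' @export
ebgm_signal <- function(a, E, prior, ebgm05_min = 2) {
  stopifnot(inherits(prior, "mgps_prior"), length(a) == length(E))
  l1 <- dnbinom(a, size = prior$alpha1,
                prob = prior$beta1 / (prior$beta1 + E), log = TRUE)
  l2 <- dnbinom(a, size = prior$alpha2,
                prob = prior$beta2 / (prior$beta2 + E), log = TRUE)
  lw1 <- log(prior$mixture_weight) + l1
  lw2 <- log(1 - prior$mixture_weight) + l2
  m <- pmax(lw1, lw2)
  Q <- exp(lw1 - m) / (exp(lw1 - m) + exp(lw2 - m))
  s1 <- prior$alpha1 + a; r1 <- prior$beta1 + E
  s2 <- prior$alpha2 + a; r2 <- prior$beta2 + E
  elog <- Q * (digamma(s1) - log(r1)) + (1 - Q) * (digamma(s2) - log(r2))
  ebgm <- exp(elog)
  ebgm05 <- vapply(seq_along(a), function(i) {
    mixture_gamma_quantile(0.05, Q[i], s1[i], r1[i], s2[i], r2[i])
  }, numeric(1))
  data.table::data.table(ebgm = ebgm, ebgm05 = ebgm05,
                         ebgm_flag = ebgm05 > ebgm05_min)
}

# Quantile of Q Gamma(s1, r1) + (1-Q) Gamma(s2, r2) by bisection on the
# mixture CDF, to |CDF - p| < 1e-8.
mixture_gamma_quantile <- function(p, Q, s1, r1, s2, r2) {
  cdf <- function(x) Q * pgamma(x, s1, rate = r1) +
    (1 - Q) * pgamma(x, s2, rate = r2)
  lo <- 0
  hi <- max(stats::qgamma(p, s1, rate = r1), stats::qgamma(p, s2, rate = r2),
            1e-8) * 2 + 1
  while (cdf(hi) < p) hi <- hi * 2
  if (!is.finite(hi)) stop("EBGM05 quantile bracketing failed: hi = ", hi)
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    f <- cdf(mid)
    if (abs(f - p) < 1e-8) return(mid)
    if (f < p) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Multiple-testing adjustment
#'
#' Benjamini-Hochberg step-up (default) or Bonferroni correction.
#'
#' @param p numeric p-values in `[0, 1]`.
#' @param method `"BH"` or `"bonferroni"`.
#' @return adjusted p-values in the original order.
#' @export
adjust_fdr <- function(p, method = c("BH", "bonferroni")) {
  method <- match.arg(method)
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  p.adjust(p, method = method)
}

#' Classify a signal into evidence tiers
#'
#' `cross_validated` when all four algorithm flags fire (the conjunction
#' rule behind a "positive by four algorithms" table);
#' `hypothesis_generating` when at least one flag fires but not all four
#' (one family alone, or partial cross-family agreement); `negative`
#' otherwise.
#'
#' @param ror_flag,prr_flag,ic_flag,ebgm_flag logical vectors.
#' @return character vector of tiers.
#' @export
classify_signal <- function(ror_flag, prr_flag, ic_flag, ebgm_flag) {
  all4 <- ror_flag & prr_flag & ic_flag & ebgm_flag
  any1 <- ror_flag | prr_flag | ic_flag | ebgm_flag
  ifelse(all4, "cross_validated",
         ifelse(any1, "hypothesis_generating", "negative"))
}

#' Flag signals absent from the drug label
#'
#' @param signals a signal table with columns `label` (PT) and `tier`.
#' @param labeled_pts character vector of PTs on the product label
#'   (case-insensitive exact matching).
#' @return the positive-tier rows whose PT is not on the label.
#' @export
compare_to_label <- function(signals, labeled_pts) {
  dt <- data.table::as.data.table(signals)
  if (length(labeled_pts) == 0L) {
    warning("empty label list: every positive signal reported as unlisted")
  }
  pos <- dt[tier != "negative"]
  pos[!toupper(label) %in% toupper(labeled_pts)]
}

#' Compute the full signal table for a set of contingency tables
#'
#' Runs all four disproportionality algorithms, fits (or reuses) the MGPS
#' prior across the cells, classifies tiers, and applies the
#' multiple-testing adjustment to the PRR chi-square p-values across the
#' family of PTs with at least `fdr_min_cases` focal reports.
#'
#' @param tables a [build_pt_tables()] result.
#' @param prior optional pre-fitted [fit_mgps_prior()]; fitted from
#'   `tables` when `NULL`.
#' @param fdr_method `"BH"` (default) or `"bonferroni"`.
#' @param fdr_min_cases minimum a-cell for membership in the adjusted
#'   family (others get `NA`).
#' @param ic_mode passed to [bcpnn_ic()].
#' @param ... threshold overrides passed to [ror_signal()], [prr_signal()],
#'   [ebgm_signal()].
#' @return `data.table` (one row per label) with counts, all four
#'   estimates/intervals/flags, `tier`, `p_adjusted`; the prior is attached
#'   as attribute `mgps_prior`.
#' @export
signal_metrics <- function(tables, prior = NULL,
                           fdr_method = c("BH", "bonferroni"),
                           fdr_min_cases = 3,
                           ic_mode = c("closed_form", "ic_from_ebgm"), ...) {
  fdr_method <- match.arg(fdr_method)
  ic_mode <- match.arg(ic_mode)
  dt <- data.table::as.data.table(tables)
  dots <- list(...)
  call_with <- function(fun, args, allowed) {
    do.call(fun, c(args, dots[intersect(names(dots), allowed)]))
  }
  a <- as.numeric(dt$a); b <- as.numeric(dt$b)
  c <- as.numeric(dt$c); d <- as.numeric(dt$d)
  N <- a + b + c + d
  E <- (a + b) * (a + c) / N
  rr <- call_with(ror_signal, list(a, b, c, d),
                  c("ror_min", "ci_lower_min", "min_cases", "rule"))
  pr <- call_with(prr_signal, list(a, b, c, d),
                  c("prr_min", "chi2_min", "min_cases"))
  if (is.null(prior)) prior <- fit_mgps_prior(a, E)
  eb <- call_with(ebgm_signal, list(a, E, prior), "ebgm05_min")
  icdt <- bcpnn_ic(a, b, c, d, ic_mode = ic_mode, ebgm = eb$ebgm)
  out <- data.table::data.table(label = dt$label, n_cases = a, expected = E)
  out <- cbind(out, rr, pr[, !"corrected"], icdt, eb)
  data.table::set(out, j = "tier",
                  value = classify_signal(rr$ror_flag, pr$prr_flag,
                                          icdt$ic_flag, eb$ebgm_flag))
  fam <- out$n_cases >= fdr_min_cases
  out[, p_adjusted := NA_real_]
  if (any(fam)) {
    data.table::set(out, which(fam), "p_adjusted",
                    adjust_fdr(out$p_value[fam], fdr_method))
  }
  data.table::setattr(out, "mgps_prior", prior)
  out[]
}
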