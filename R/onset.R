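# Time-to-onset analysis: interval construction with exclusion accounting,
# quartile summaries, two-parameter Weibull maximum likelihood with
# failure-type classification, cumulative onset curves, and the two-group
# log-rank comparison (all observations are events; spontaneous reports
# carry no at-risk denominator, so there is no censoring).

#' Compute time-to-onset records
#'
#' `tto = event date - earliest focal-drug start date`, in whole days, per
#' report. Records with a missing start date, missing event date, or an
#' event before the start are excluded and tallied by reason; day 0
#' (same-day onset) is included. Partial dates must already be flagged
#' missing upstream.
#'
#' @param therapies `data.table` with `primary_id`, `start_date` (8-digit
#'   strings; several rows per report allowed — the earliest start is the
#'   origin).
#' @param events `data.table` with `primary_id`, `event_date`.
#' @param cases optional case table contributing a `sex` column.
#' @return `data.table` (class `onset_records`) with `primary_id`,
#'   `tto_days` and (if available) `sex`; attribute `exclusions` is the
#'   named tally, and `records_in = nrow(out) + sum(exclusions)` always.
#' @export
compute_tto <- function(therapies, events, cases = NULL) {
  th <- data.table::as.data.table(therapies)
  ev <- data.table::as.data.table(events)
  th <- th[, .(primary_id = as.character(primary_id),
               start = parse_faers_date_full(start_date))]
  th <- th[, .(start = if (all(is.na(start))) as.Date(NA) else
    min(start, na.rm = TRUE)), by = primary_id]
  ev <- ev[, .(primary_id = as.character(primary_id),
               event = parse_faers_date_full(event_date))]
  ev <- unique(ev, by = "primary_id")
  dt <- merge(ev, th, by = "primary_id", all.x = TRUE, sort = TRUE)
  n_in <- nrow(dt)
  miss_start <- is.na(dt$start)
  miss_event <- !miss_start & is.na(dt$event)
  neg <- !miss_start & !miss_event & dt$event < dt$start
  keep <- !(miss_start | miss_event | neg)
  out <- dt[keep, .(primary_id,
                    tto_days = as.integer(event - start))]
  if (!is.null(cases)) {
    cs <- data.table::as.data.table(cases)[, .(
      primary_id = as.character(primary_id), sex)]
    out <- merge(out, cs, by = "primary_id", all.x = TRUE, sort = TRUE)
  }
  excl <- c(missing_start = sum(miss_start), missing_event = sum(miss_event),
            negative = sum(neg))
  stopifnot(n_in == nrow(out) + sum(excl))
  data.table::setattr(out, "exclusions", excl)
  data.table::setattr(out, "class", c("onset_records", class(out)))
  out[]
}

#' Summarize time-to-onset
#'
#' Median and quartiles by the linear-interpolation convention
#' (`quantile` type 7).
#'
#' @param tto_days numeric vector of onset days (n >= 1).
#' @return list with `n`, `median`, `q1`, `q3`.
#' @export
summarize_tto <- function(tto_days) {
  tto_days <- tto_days[!is.na(tto_days)]
  if (!length(tto_days)) stop("no time-to-onset records to summarize")
  q <- unname(quantile(tto_days, c(0.25, 0.5, 0.75), type = 7))
  list(n = length(tto_days), median = q[2], q1 = q[1], q3 = q[3])
}

#' Fit a two-parameter Weibull to onset intervals
#'
#' Maximum-likelihood scale (alpha, days) and shape (beta, dimensionless)
#' with 95% Wald intervals computed on the log-parameter scale from the
#' observed information and reported on the natural scale (a seeded
#' nonparametric bootstrap is available instead). Because Weibull support
#' is positive and spontaneous-report dates have day resolution, day-0
#' events are legal; with `offset = "auto"` (default) all values are
#' shifted by +0.5 day for fitting only when any zero is present.
#' The failure type follows the CI rule: `early_failure` when the shape CI
#' lies entirely below 1 (decreasing hazard), `wear_out` entirely above 1,
#' `random_failure` otherwise.
#'
#' @param tto_days onset intervals in days (n >= 10 recommended; fewer
#'   draws a warning, identical values an error).
#' @param offset `"auto"`, `"none"`, or `"half_day"` (always shift).
#' @param ci `"wald"` (default) or `"bootstrap"`.
#' @param n_boot bootstrap resamples.
#' @param conf confidence level.
#' @return object of class `weibull_fit`: `scale_alpha`, `shape_beta`,
#'   `scale_ci`, `shape_ci`, `n`, `failure_type`, `log_likelihood`,
#'   `offset_used`.
#' @export
weibull_fit <- function(tto_days, offset = c("auto", "none", "half_day"),
                        ci = c("wald", "bootstrap"), n_boot = 1000,
                        conf = 0.95) {
  offset <- match.arg(offset)
  ci <- match.arg(ci)
  x <- as.numeric(tto_days[!is.na(tto_days)])
  if (length(unique(x)) < 2) {
    stop("Weibull fit needs at least two distinct onset values")
  }
  if (length(x) < 10) warning("fewer than 10 onset records; fit attempted")
  shift <- switch(offset,
                  none = 0,
                  half_day = 0.5,
                  auto = if (any(x <= 0)) 0.5 else 0)
  y <- x + shift
  fit <- survival::survreg(survival::Surv(y) ~ 1, dist = "weibull")
  # survreg parameterization: log(alpha) = intercept, beta = 1/scale
  mu <- unname(coef(fit)[1])
  logsig <- log(fit$scale)
  V <- vcov(fit)                       # covariance of (mu, log sigma)
  alpha <- exp(mu)
  beta <- exp(-logsig)
  z <- qnorm(1 - (1 - conf) / 2)
  if (ci == "wald") {
    se_mu <- sqrt(V[1, 1])
    se_ls <- sqrt(V[2, 2])
    scale_ci <- exp(mu + c(-1, 1) * z * se_mu)
    shape_ci <- exp(-logsig + c(-1, 1) * z * se_ls)
  } else {
    n <- length(y)
    bs <- vapply(seq_len(n_boot), function(i) {
      yy <- sample(y, n, replace = TRUE)
      f <- tryCatch(survival::survreg(survival::Surv(yy) ~ 1,
                                      dist = "weibull"),
                    error = function(e) NULL)
      if (is.null(f)) c(NA_real_, NA_real_) else
        c(exp(unname(coef(f)[1])), 1 / f$scale)
    }, numeric(2))
    qs <- c((1 - conf) / 2, 1 - (1 - conf) / 2)
    scale_ci <- unname(quantile(bs[1, ], qs, na.rm = TRUE))
    shape_ci <- unname(quantile(bs[2, ], qs, na.rm = TRUE))
  }
  type <- if (shape_ci[2] < 1) "early_failure" else
    if (shape_ci[1] > 1) "wear_out" else "random_failure"
  structure(list(scale_alpha = alpha, shape_beta = beta,
                 scale_ci = scale_ci, shape_ci = shape_ci,
                 n = length(y), failure_type = type,
                 log_likelihood = as.numeric(logLik(fit)),
                 offset_used = shift, ci_method = ci),
            class = "weibull_fit")
}

#' @export
print.weibull_fit <- function(x, ...) {
  cat("Weibull onset model (n = ", x$n, ")\n", sep = "")
  cat(sprintf("  scale alpha = %.2f d (%.2f-%.2f)\n", x$scale_alpha,
              x$scale_ci[1], x$scale_ci[2]))
  cat(sprintf("  shape beta  = %.2f   (%.2f-%.2f)\n", x$shape_beta,
              x$shape_ci[1], x$shape_ci[2]))
  cat("  failure type:", gsub("_", " ", x$failure_type), "\n")
  invisible(x)
}

#' Cumulative onset curve(s)
#'
#' Empirical cumulative fraction of events by day since drug start — every
#' record is an event, so this is the ECDF evaluated at the distinct
#' observed days, optionally per group.
#'
#' @param records an [compute_tto()] result (needs `tto_days`, and the
#'   grouping column when `by` is given).
#' @param by optional grouping column name (e.g. `"sex"`).
#' @return `data.table` with `group` (`"all"` when ungrouped), `day`,
#'   `cum_frac`; attribute `summaries` holds per-group [summarize_tto()]
#'   output.
#' @export
cumulative_onset <- function(records, by = NULL) {
  dt <- data.table::as.data.table(records)
  grp <- if (is.null(by)) rep("all", nrow(dt)) else as.character(dt[[by]])
  out <- list(); sums <- list()
  for (g in sort(unique(grp))) {
    days <- sort(dt$tto_days[grp == g])
    if (!length(days)) next
    ud <- unique(days)
    cf <- cumsum(tabulate(match(days, ud))) / length(days)
    out[[g]] <- data.table::data.table(group = g, day = ud, cum_frac = cf)
    sums[[g]] <- summarize_tto(days)
  }
  res <- data.table::rbindlist(out)
  data.table::setattr(res, "summaries", sums)
  res[]
}

#' Log-rank test between two onset groups
#'
#' Standard log-rank statistic over the pooled distinct event times, all
#' observations treated as events, p on 1 df.
#'
#' @param tto_days onset days.
#' @param group two-level grouping vector.
#' @return list with `statistic`, `p_value`, `n` per group.
#' @export
logrank_tto <- function(tto_days, group) {
  keep <- !is.na(tto_days) & !is.na(group)
  tto_days <- tto_days[keep]; group <- as.character(group[keep])
  tabs <- table(group)
  if (length(tabs) != 2 || any(tabs < 1)) {
    stop("log-rank comparison needs two non-empty groups")
  }
  sd <- survival::survdiff(survival::Surv(tto_days,
                                          rep(1, length(tto_days))) ~ group)
  stat <- sd$chisq
  list(statistic = stat,
       p_value = pchisq(stat, df = 1, lower.tail = FALSE),
       n = as.vector(tabs))
}
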