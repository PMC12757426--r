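# Serious vs non-serious comparison per PT. The group denominators are
# PT-occurrence totals (all reaction rows in each group), not case counts:
# that is the margin convention that reproduces published per-term
# statistics. Test selection follows the classical expected-count rule
# (Fisher's exact test when any expected cell is below 5, Yates-corrected
# chi-square otherwise).

#' Build a serious/non-serious 2x2 table for one PT
#'
#' Cells are (events, total - events) per group, where the totals are the
#' PT-occurrence margins of the serious and non-serious groups.
#'
#' @param pt PT label.
#' @param serious_events,nonserious_events event counts per group.
#' @param serious_total,nonserious_total PT-occurrence margins per group.
#' @return list of class `severity_table` with `pt`, cells `a`, `b`
#'   (serious with/without), `c`, `d` (non-serious with/without), and
#'   `degenerate` (no events in either group).
#' @export
severity_table <- function(pt, serious_events, serious_total,
                           nonserious_events, nonserious_total) {
  if (serious_events > serious_total || nonserious_events > nonserious_total) {
    stop("event count exceeds group total for PT ", pt)
  }
  stopifnot(serious_events >= 0, nonserious_events >= 0)
  structure(list(pt = pt,
                 a = as.numeric(serious_events),
                 b = as.numeric(serious_total - serious_events),
                 c = as.numeric(nonserious_events),
                 d = as.numeric(nonserious_total - nonserious_events),
                 degenerate = serious_events + nonserious_events == 0),
            class = "severity_table")
}

#' Choose chi-square or Fisher's exact test for a 2x2 table
#'
#' Fisher's exact test iff the smallest expected cell count
#' `row_i x col_j / N` is below `threshold` (default 5); the
#' continuity-corrected chi-square test otherwise.
#'
#' @param tab a [severity_table()] (or any list with `a`, `b`, `c`, `d`).
#' @param threshold minimum expected cell count for the chi-square test.
#' @return `"chi_square"` or `"fisher_exact"`.
#' @export
select_test <- function(tab, threshold = 5) {
  a <- tab$a; b <- tab$b; c <- tab$c; d <- tab$d
  N <- a + b + c + d
  expected <- outer(c(a + b, c + d), c(a + c, b + d)) / N
  if (min(expected) < threshold) "fisher_exact" else "chi_square"
}

#' Continuity-corrected chi-square test for a 2x2 table
#'
#' Yates statistic
#' `N (|ad - bc| - N/2)^2 / [(a+b)(c+d)(a+c)(b+d)]`, clamped at 0 when
#' `|ad - bc| <= N/2`, with a two-sided p-value on 1 df. Set
#' `correct = FALSE` for the uncorrected Pearson statistic.
#'
#' @param tab table as in [select_test()].
#' @param correct apply the Yates continuity correction (default).
#' @return list with `statistic`, `p_value`.
#' @export
chi_square_yates <- function(tab, correct = TRUE) {
  a <- as.numeric(tab$a); b <- as.numeric(tab$b)
  c <- as.numeric(tab$c); d <- as.numeric(tab$d)
  N <- a + b + c + d
  if ((a + b) == 0 || (c + d) == 0 || (a + c) == 0 || (b + d) == 0) {
    stop("degenerate table: zero margin")
  }
  num <- abs(a * d - b * c)
  if (correct) num <- max(num - N / 2, 0)
  stat <- N * num^2 / ((a + b) * (c + d) * (a + c) * (b + d))
  list(statistic = stat, p_value = pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Fisher's exact test for a 2x2 table (two-sided, sum of small p)
#'
#' Two-sided p-value by summation of hypergeometric probabilities not
#' exceeding the observed table's probability (with the customary
#' `1 + 1e-7` relative guard against floating-point ties); the mid-p
#' variant is not used.
#'
#' @param tab table as in [select_test()].
#' @return list with `p_value`.
#' @export
fisher_exact <- function(tab) {
  a <- tab$a; b <- tab$b; c <- tab$c; d <- tab$d
  m <- a + b          # serious margin
  k <- a + c          # event margin
  N <- a + b + c + d
  support <- max(0, k - (c + d)):min(k, m)
  dens <- dhyper(support, m, N - m, k)
  obs <- dhyper(a, m, N - m, k)
  p <- sum(dens[dens <= obs * (1 + 1e-7)])
  list(p_value = min(p, 1))
}

#' Serious vs non-serious comparison across PTs
#'
#' Builds the per-PT 2x2 tables against the group PT-occurrence margins,
#' chooses chi-square or Fisher per the expected-count rule, and computes
#' the two-sided p-values.
#'
#' @param counts `data.frame` with columns `pt`, `serious_events`,
#'   `nonserious_events`.
#' @param serious_total,nonserious_total PT-occurrence margins.
#' @param correct continuity correction for the chi-square branch.
#' @return `data.table` with per-PT percentages, `test_used`, `statistic`
#'   (NA for Fisher), `p_value`, and the significance bucket printed in
#'   severity tables (`"<0.001"`, `"<0.01"`, `"<0.05"`, `"ns"`).
#' @export
severity_analysis <- function(counts, serious_total, nonserious_total,
                              correct = TRUE) {
  dt <- data.table::as.data.table(counts)
  stopifnot(all(c("pt", "serious_events", "nonserious_events") %in% names(dt)))
  res <- lapply(seq_len(nrow(dt)), function(i) {
    tab <- severity_table(dt$pt[i], dt$serious_events[i], serious_total,
                          dt$nonserious_events[i], nonserious_total)
    if (tab$degenerate) {
      return(data.table::data.table(test_used = NA_character_,
                                    statistic = NA_real_,
                                    p_value = NA_real_, degenerate = TRUE))
    }
    test <- select_test(tab)
    if (test == "chi_square") {
      r <- chi_square_yates(tab, correct = correct)
      data.table::data.table(test_used = "chi_square",
                             statistic = r$statistic, p_value = r$p_value,
                             degenerate = FALSE)
    } else {
      r <- fisher_exact(tab)
      data.table::data.table(test_used = "fisher_exact",
                             statistic = NA_real_, p_value = r$p_value,
                             degenerate = FALSE)
    }
  })
  out <- cbind(dt, data.table::rbindlist(res))
  out[, `:=`(
    serious_pct = 100 * serious_events / serious_total,
    nonserious_pct = 100 * nonserious_events / nonserious_total,
    p_bucket = ifelse(is.na(p_value), NA_character_,
                      ifelse(p_value < 0.001, "<0.001",
                             ifelse(p_value < 0.01, "<0.01",
                                    ifelse(p_value < 0.05, "<0.05", "ns"))))
  )]
  out[]
}
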