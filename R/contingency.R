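# 2x2 contingency tables for disproportionality analysis: focal drug vs
# all other reports, per PT and per SOC, overall and within strata. The
# counting unit is always the unique report.

#' Build per-PT 2x2 contingency tables
#'
#' For every PT observed anywhere in the database, counts
#' `a` = focal reports with the event, `b` = focal without, `c` = non-focal
#' with, `d` = non-focal without. Margin identities (`a+b` = focal reports,
#' `a+c` = reports with the event, `N` = all reports) hold exactly and are
#' asserted on every build.
#'
#' @param case_ids character vector of all (deduplicated) report ids in the
#'   database (or stratum).
#' @param reactions `data.table` with `primary_id`, `pt`, already
#'   de-duplicated within report; rows whose `primary_id` is not in
#'   `case_ids` are ignored.
#' @param focal_ids report ids with the focal drug as primary suspect;
#'   must be a subset of `case_ids`.
#' @param stratum optional label recorded on the result.
#' @return `data.table` (class `contingency_set`) with `label`, `a`, `b`,
#'   `c`, `d`; attributes `N`, `n_focal`, `stratum`.
#' @export
build_pt_tables <- function(case_ids, reactions, focal_ids, stratum = NA_character_) {
  case_ids <- unique(as.character(case_ids))
  focal_ids <- unique(as.character(focal_ids))
  if (length(setdiff(focal_ids, case_ids))) {
    stop("focal_ids must be a subset of case_ids")
  }
  reac <- data.table::as.data.table(reactions)[primary_id %in% case_ids]
  reac <- unique(reac[, .(primary_id = as.character(primary_id), pt)])
  N <- length(case_ids)
  nf <- length(focal_ids)
  tab <- reac[, .(a = sum(primary_id %in% focal_ids), n_total = .N), by = pt]
  out <- data.table::data.table(
    label = tab$pt,
    a = tab$a,
    b = nf - tab$a,
    c = tab$n_total - tab$a,
    d = N - nf - (tab$n_total - tab$a)
  )
  data.table::setorder(out, label)
  check_margins(out, N, nf)
  data.table::setattr(out, "N", N)
  data.table::setattr(out, "n_focal", nf)
  data.table::setattr(out, "stratum", stratum)
  data.table::setattr(out, "class",
                      c("contingency_set", class(out)))
  out[]
}

check_margins <- function(tables, N, n_focal) {
  stopifnot(all(tables$a >= 0), all(tables$b >= 0),
            all(tables$c >= 0), all(tables$d >= 0),
            all(tables$a + tables$b == n_focal),
            all(tables$a + tables$b + tables$c + tables$d == N))
  invisible(TRUE)
}

#' Build per-SOC 2x2 contingency tables
#'
#' Maps reaction PTs to System Organ Classes and counts each report once
#' per SOC even when several of its PTs share that SOC. PTs without a
#' mapping are collected under `"UNMAPPED"` and tallied.
#'
#' @inheritParams build_pt_tables
#' @param pt_soc_map `data.frame` with columns `pt`, `soc`
#'   (case-insensitive PT matching).
#' @return `contingency_set` keyed by SOC; attribute `n_unmapped_pts`.
#' @export
build_soc_tables <- function(case_ids, reactions, focal_ids, pt_soc_map,
                             stratum = NA_character_) {
  map <- data.table::as.data.table(pt_soc_map)
  stopifnot(all(c("pt", "soc") %in% names(map)))
  reac <- data.table::as.data.table(reactions)
  soc <- map$soc[match(toupper(reac$pt), toupper(map$pt))]
  n_unmapped <- length(unique(reac$pt[is.na(soc)]))
  soc[is.na(soc)] <- "UNMAPPED"
  soc_reac <- unique(data.table::data.table(
    primary_id = as.character(reac$primary_id), pt = soc))
  out <- build_pt_tables(case_ids, soc_reac, focal_ids, stratum = stratum)
  data.table::setattr(out, "n_unmapped_pts", n_unmapped)
  out
}

#' Partition reports into strata
#'
#' Splits a case table by sex or signal-scheme age band. Missing values
#' form an explicit `"missing"` stratum, which callers exclude from signal
#' statistics.
#'
#' @param cases standardized case table with `primary_id` and the stratum
#'   variable (`sex`, or `age_years` for age bands).
#' @param by `"sex"` or `"age_band"`.
#' @return named list of character vectors of `primary_id`s; the union is
#'   all reports. Empty strata are kept (with a warning).
#' @export
stratify_cases <- function(cases, by = c("sex", "age_band")) {
  by <- match.arg(by)
  dt <- data.table::as.data.table(cases)
  key <- if (by == "sex") {
    k <- dt$sex
    k[is.na(k)] <- "missing"
    k[k == "unknown"] <- "missing"
    k
  } else {
    age_band(dt$age_years, "signal")
  }
  levels <- if (by == "sex") c("female", "male", "missing") else
    c("<18", "18-64.9", ">=65", "missing")
  out <- lapply(levels, function(l) as.character(dt$primary_id[key == l]))
  names(out) <- levels
  empty <- names(out)[vapply(out, length, 0L) == 0L & names(out) != "missing"]
  if (length(empty)) warning("empty stratum: ", paste(empty, collapse = ", "))
  out
}

#' Read a PT-to-SOC mapping table
#'
#' @param path two-column TSV with header `pt<TAB>soc`.
#' @return `data.table` with `pt`, `soc`.
#' @export
read_pt_soc_map <- function(path) {
  map <- data.table::fread(path, sep = "\t", header = TRUE,
                           colClasses = "character")
  data.table::setnames(map, tolower(names(map)))
  stopifnot(all(c("pt", "soc") %in% names(map)))
  map[, .(pt, soc)]
}
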