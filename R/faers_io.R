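# Ingestion of FAERS-style quarterly ASCII tables: parsing, field
# standardization, report deduplication, primary-suspect selection, and the
# conditional weight-imputation rule.

FAERS_TABLES <- c("DEMO", "DRUG", "REAC", "OUTC", "THER", "INDI", "RPSR")

# FAERS outcome codes that make a report "serious"; OT (other) alone does not.
SERIOUS_OUTCOME_CODES <- c("DE", "LT", "HO", "DS", "CA", "RI")

OUTCOME_LABELS <- c(
  DE = "death", LT = "life_threatening", HO = "hospitalization",
  DS = "disability", CA = "congenital_anomaly", RI = "required_intervention",
  OT = "other"
)

ROLE_CODES <- c(
  PS = "primary_suspect", SS = "secondary_suspect",
  C = "concomitant", I = "interacting"
)

REPORTER_CODES <- c(
  CN = "consumer", MD = "physician", HP = "health professional",
  PH = "pharmacist", LW = "lawyer", OT = "other"
)

#' Parse one quarter of FAERS-style ASCII tables
#'
#' Reads the seven core tables (DEMO, DRUG, REAC, OUTC, THER, INDI, RPSR)
#' from `'$'`-delimited text files with a single header line — the FAERS
#' quarterly ASCII convention. All columns are read as character; typing
#' happens in [standardize_bundle()]. Unknown columns are preserved but
#' ignored downstream.
#'
#' @param paths named character vector or list of file paths; names must be
#'   among `DEMO, DRUG, REAC, OUTC, THER, INDI, RPSR` (case-insensitive).
#'   Missing tables are allowed and come back as empty.
#' @param sep field delimiter; `"$"` (default) for FAERS ASCII, `","` for
#'   CSV fixtures.
#' @param quiet suppress the per-table row-count message.
#' @return a named list of `data.table`s (class `faers_bundle`), one per
#'   table, each with lower-cased column names.
#' @details Every file must contain a `PRIMARYID` column; a missing
#'   mandatory column is a hard error naming the file and column. An empty
#'   file yields an empty table with a warning.
#' @export
parse_quarter <- function(paths, sep = "$", quiet = FALSE) {
  nm <- toupper(names(paths))
  if (is.null(nm) || any(!nzchar(nm))) {
    stop("'paths' must be named by table (DEMO, DRUG, REAC, ...)")
  }
  bad <- setdiff(nm, FAERS_TABLES)
  if (length(bad)) stop("unknown table name(s): ", paste(bad, collapse = ", "))
  out <- vector("list", length(FAERS_TABLES))
  names(out) <- FAERS_TABLES
  for (tab in FAERS_TABLES) {
    i <- match(tab, nm)
    if (is.na(i)) {
      out[[tab]] <- data.table::data.table(primaryid = character())
      next
    }
    path <- paths[[i]]
    if (!file.exists(path)) stop("file not found for table ", tab, ": ", path)
    dt <- tryCatch(
      data.table::fread(path, sep = sep, colClasses = "character",
                        quote = "", header = TRUE, fill = TRUE),
      error = function(e) NULL
    )
    if (is.null(dt) || nrow(dt) == 0L) {
      hdr <- readLines(path, n = 1L)
      if (!length(hdr) || !nzchar(hdr)) {
        warning("empty file for table ", tab, ": ", path)
        out[[tab]] <- data.table::data.table(primaryid = character())
        next
      }
      cols <- tolower(strsplit(hdr, sep, fixed = TRUE)[[1]])
      dt <- data.table::as.data.table(
        setNames(rep(list(character()), length(cols)), cols))
    }
    data.table::setnames(dt, tolower(names(dt)))
    if (!"primaryid" %in% names(dt)) {
      stop("mandatory column PRIMARYID missing in ", tab, " file: ", path)
    }
    if (!quiet) message(tab, ": ", nrow(dt), " rows")
    out[[tab]] <- dt
  }
  structure(out, class = c("faers_bundle", "list"))
}

# Age unit codes -> years. Decades are 10 years; weeks use the mean
# Gregorian year of 365.25 d = 52.1775 wk; hours use 8766 h.
AGE_TO_YEARS <- c(DEC = 10, YR = 1, MON = 1 / 12, WK = 1 / 52.1775,
                  DY = 1 / 365.25, HR = 1 / 8766)
WT_TO_KG <- c(KG = 1, LBS = 0.45359237, GMS = 1 / 1000)

convert_units <- function(value, code, factors, what) {
  v <- suppressWarnings(as.numeric(value))
  code <- toupper(trimws(as.character(code)))
  f <- factors[code]
  unknown <- !is.na(v) & !is.na(code) & nzchar(code) & is.na(f)
  if (any(unknown)) {
    tally <- table(code[unknown])
    warning("unknown ", what, " unit code(s), values set missing: ",
            paste(sprintf("%s (%d)", names(tally), tally), collapse = ", "))
  }
  out <- v * unname(f)
  # a value with no unit code is taken at face value only for age in years
  out
}

#' Standardize a parsed FAERS bundle
#'
#' Applies field typing and the cleaning rules for spontaneous-report
#' tables: age converted to years (DEC/YR/MON/WK/DY/HR codes), weight to
#' kilograms (KG/LBS/GMS), drug names normalized (uppercase, characters
#' outside `[A-Z0-9 ]` removed, whitespace collapsed), FAERS role and
#' outcome codes mapped to labels, reaction rows de-duplicated within
#' report (one row per report x PT), and out-of-bound ages/weights set
#' missing.
#'
#' @param bundle result of [parse_quarter()] (or the in-memory equivalent
#'   from [generate_reports()]).
#' @param age_bounds,weight_bounds plausibility bounds; values outside are
#'   set missing and counted in the cleaning log.
#' @return a named list (class `faers_std`) with elements `cases` (one row
#'   per PRIMARYID: demographics, outcomes, seriousness), `drugs`,
#'   `reactions`, `therapies`, and attribute `cleaning_log`.
#' @details Seriousness is `TRUE` iff the report carries at least one
#'   outcome code among `DE, LT, HO, DS, CA, RI`; `OT` alone is
#'   non-serious. Standardization never turns a missing input into a
#'   non-missing value.
#' @export
standardize_bundle <- function(bundle,
                               age_bounds = c(0, 120),
                               weight_bounds = c(1, 500)) {
  stopifnot(inherits(bundle, "faers_bundle") || is.list(bundle))
  log <- list()
  demo <- data.table::as.data.table(bundle$DEMO)

  getcol <- function(dt, col) {
    if (col %in% names(dt)) dt[[col]] else rep(NA_character_, nrow(dt))
  }

  age <- convert_units(getcol(demo, "age"), getcol(demo, "age_cod"),
                       AGE_TO_YEARS, "age")
  # bare numeric age without a unit code: treated as years
  rawage <- suppressWarnings(as.numeric(getcol(demo, "age")))
  nocode <- is.na(age) & !is.na(rawage) &
    (is.na(getcol(demo, "age_cod")) | !nzchar(trimws(getcol(demo, "age_cod"))))
  age[nocode] <- rawage[nocode]
  oob <- !is.na(age) & (age < age_bounds[1] | age > age_bounds[2])
  log$age_out_of_bounds <- sum(oob)
  age[oob] <- NA_real_

  wt <- convert_units(getcol(demo, "wt"), getcol(demo, "wt_cod"),
                      WT_TO_KG, "weight")
  oob <- !is.na(wt) & (wt < weight_bounds[1] | wt > weight_bounds[2])
  log$weight_out_of_bounds <- sum(oob)
  wt[oob] <- NA_real_

  sexcode <- toupper(trimws(getcol(demo, "sex")))
  sex <- ifelse(sexcode == "F", "female",
                ifelse(sexcode == "M", "male", "unknown"))

  occp <- toupper(trimws(getcol(demo, "occp_cod")))
  reporter <- unname(REPORTER_CODES[occp])
  reporter[is.na(reporter)] <- "unknown"

  outc <- data.table::as.data.table(bundle$OUTC)
  if (nrow(outc)) {
    oc <- data.table::data.table(
      primary_id = as.character(getcol(outc, "primaryid")),
      lab = unname(OUTCOME_LABELS[toupper(trimws(getcol(outc, "outc_cod")))]))
    oc[, serious := lab %in%
         unname(OUTCOME_LABELS[SERIOUS_OUTCOME_CODES])]
    oc <- unique(oc[!is.na(lab)], by = c("primary_id", "lab"))
    data.table::setorder(oc, primary_id, lab)
    single <- !(duplicated(oc$primary_id) |
                  duplicated(oc$primary_id, fromLast = TRUE))
    agg_multi <- oc[!single][, .(outcomes = paste(lab, collapse = ";"),
                                 serious = any(serious)), by = primary_id]
    agg_single <- oc[single, .(primary_id, outcomes = lab, serious)]
    outc_agg <- rbind(agg_single, agg_multi)
  } else {
    outc_agg <- data.table::data.table(primary_id = character(),
                                       outcomes = character(),
                                       serious = logical())
  }

  fda_raw <- getcol(demo, "fda_dt")
  cases <- data.table::data.table(
    primary_id = as.character(getcol(demo, "primaryid")),
    case_id = as.character(getcol(demo, "caseid")),
    fda_date = pad_faers_date(fda_raw),
    event_date = getcol(demo, "event_dt"),
    sex = sex,
    age_years = age,
    weight_kg = wt,
    country = trimws(getcol(demo, "reporter_country")),
    reporter_type = reporter,
    quarter = trimws(getcol(demo, "quarter"))
  )
  cases <- merge(cases, outc_agg, by = "primary_id", all.x = TRUE, sort = FALSE)
  cases[is.na(serious), serious := FALSE]
  cases[is.na(outcomes), outcomes := ""]

  drug <- data.table::as.data.table(bundle$DRUG)
  drugs <- data.table::data.table(
    primary_id = as.character(getcol(drug, "primaryid")),
    drug_name = normalize_drug_name(getcol(drug, "drugname")),
    role = unname(ROLE_CODES[toupper(trimws(getcol(drug, "role_cod")))]),
    drug_seq = as.character(getcol(drug, "drug_seq"))
  )

  reac <- data.table::as.data.table(bundle$REAC)
  reactions <- data.table::data.table(
    primary_id = as.character(getcol(reac, "primaryid")),
    pt = trimws(getcol(reac, "pt"))
  )
  reactions <- reactions[!is.na(pt) & nzchar(pt)]
  n_before <- nrow(reactions)
  # one reaction row per (report, PT): disproportionality counts reports
  reactions <- unique(reactions, by = c("primary_id", "pt"))
  log$duplicate_pt_rows_collapsed <- n_before - nrow(reactions)

  ther <- data.table::as.data.table(bundle$THER)
  therapies <- data.table::data.table(
    primary_id = as.character(getcol(ther, "primaryid")),
    drug_seq = as.character(getcol(ther, "dsg_drug_seq")),
    start_date = getcol(ther, "start_dt")
  )

  structure(list(cases = cases, drugs = drugs, reactions = reactions,
                 therapies = therapies),
            cleaning_log = log, class = c("faers_std", "list"))
}

#' Deduplicate spontaneous reports
#'
#' FAERS cases accumulate follow-up versions under one CASEID. For each
#' `case_id` only the record with the latest `fda_date` is retained; among
#' ties on (`case_id`, `fda_date`) the record with the largest numeric
#' `primary_id` wins. Records with a missing `case_id` cannot be grouped
#' and are each retained (and flagged). Output is sorted by `case_id` so
#' the operation is deterministic and idempotent.
#'
#' @param cases a `data.table` with at least `primary_id`, `case_id`,
#'   `fda_date` (8-digit string; partial dates must already be zero-padded).
#' @return the surviving rows, sorted by `case_id`; attributes `n_removed`
#'   (duplicates dropped) and `n_missing_case_id`.
#' @export
deduplicate_cases <- function(cases) {
  dt <- data.table::as.data.table(cases)
  stopifnot(all(c("primary_id", "case_id", "fda_date") %in% names(dt)))
  n_in <- nrow(dt)
  miss <- is.na(dt$case_id) | !nzchar(dt$case_id)
  dt_miss <- dt[miss]
  dt_ok <- dt[!miss]
  if (nrow(dt_ok)) {
    pid_num <- suppressWarnings(as.numeric(dt_ok$primary_id))
    ord <- order(dt_ok$case_id, dt_ok$fda_date, pid_num,
                 decreasing = c(FALSE, TRUE, TRUE), method = "radix")
    dt_ok <- dt_ok[ord][, head(.SD, 1L), by = case_id]
    data.table::setcolorder(dt_ok, names(dt))
  }
  out <- rbind(dt_ok, dt_miss)
  out <- out[order(out$case_id, na.last = TRUE)]
  data.table::setattr(out, "n_removed", n_in - nrow(out))
  data.table::setattr(out, "n_missing_case_id", sum(miss))
  out[]
}

#' Select reports with a target drug as primary suspect
#'
#' @param drugs standardized drug table (`primary_id`, `drug_name`, `role`).
#' @param target character vector of normalized target drug names
#'   (e.g. `"VONOPRAZAN"`); must be non-empty.
#' @param match `"token"` (default) treats a drug name as matching when any
#'   whitespace token equals a target name, so salt forms like
#'   `"VONOPRAZAN FUMARATE"` are captured; `"exact"` requires the whole
#'   normalized name to equal a target.
#' @return character vector of `primary_id`s with at least one
#'   primary-suspect row matching the target.
#' @export
select_primary_suspect <- function(drugs, target, match = c("token", "exact")) {
  match <- match.arg(match)
  if (length(target) == 0L || all(!nzchar(target))) {
    stop("target drug name set must be non-empty")
  }
  target <- normalize_drug_name(target)
  dt <- data.table::as.data.table(drugs)
  ps <- dt[role == "primary_suspect"]
  if (!nrow(ps)) return(character())
  hit <- if (match == "exact") {
    ps$drug_name %in% target
  } else {
    vapply(strsplit(ps$drug_name, " ", fixed = TRUE),
           function(tok) any(tok %in% target), logical(1))
  }
  sort(unique(ps$primary_id[hit]))
}

#' Assign age bands
#'
#' Two band schemes: `"signal"` (`<18`, `[18, 65)`, `>=65`) used for
#' stratified disproportionality, and `"descriptive"` (`<18`, `[18, 65)`,
#' `[65, 85)`, `>=85`) used for baseline tables. The upper bound printed as
#' "64.9" is read as age strictly below 65.
#'
#' @param age_years numeric vector of ages (NA allowed).
#' @param scheme `"signal"` or `"descriptive"`.
#' @return character vector of band labels (`"missing"` for NA).
#' @export
age_band <- function(age_years, scheme = c("signal", "descriptive")) {
  scheme <- match.arg(scheme)
  breaks <- if (scheme == "signal") c(-Inf, 18, 65, Inf) else
    c(-Inf, 18, 65, 85, Inf)
  labels <- if (scheme == "signal") c("<18", "18-64.9", ">=65") else
    c("<18", "18-64.9", "65-85", ">=85")
  out <- as.character(cut(age_years, breaks = breaks, labels = labels,
                          right = FALSE))
  out[is.na(out)] <- "missing"
  out
}

#' Conditionally impute missing weights
#'
#' If the fraction of missing weights is below `missing_threshold`
#' (default 10%), each missing weight is replaced by the median of observed
#' weights in the same (sex, descriptive age band) cell; otherwise nothing
#' is imputed and the skip is recorded. Cells with no observed weight stay
#' missing with a warning.
#'
#' @param cases standardized case table with `sex`, `age_years`, `weight_kg`.
#' @param missing_threshold maximum missing fraction at which imputation
#'   still runs.
#' @return `cases` with `weight_kg` possibly filled and a logical
#'   `weight_imputed` column; attribute `imputation` describes what happened.
#' @export
impute_weight <- function(cases, missing_threshold = 0.10) {
  dt <- data.table::copy(data.table::as.data.table(cases))
  dt[, weight_imputed := FALSE]
  miss_rate <- mean(is.na(dt$weight_kg))
  if (is.nan(miss_rate) || miss_rate >= missing_threshold) {
    data.table::setattr(dt, "imputation",
      list(performed = FALSE, missing_rate = miss_rate))
    return(dt[])
  }
  dt[, age_band := age_band(age_years, "descriptive")]
  med <- dt[!is.na(weight_kg),
            .(cell_median = stats::median(weight_kg)),
            by = .(sex, age_band)]
  dt <- merge(dt, med, by = c("sex", "age_band"), all.x = TRUE, sort = FALSE)
  fill <- is.na(dt$weight_kg) & !is.na(dt$cell_median)
  nofill <- is.na(dt$weight_kg) & is.na(dt$cell_median)
  if (any(nofill)) {
    warning(sum(nofill), " missing weight(s) in cells with no observed ",
            "weight were left missing")
  }
  dt[fill, weight_kg := cell_median]
  dt[fill, weight_imputed := TRUE]
  dt[, cell_median := NULL]
  dt[, age_band := NULL]
  data.table::setattr(dt, "imputation",
    list(performed = TRUE, missing_rate = miss_rate, n_imputed = sum(fill)))
  dt[]
}

#' Write a bundle of FAERS-style tables to delimited files
#'
#' @param bundle named list of tables (as from [generate_reports()]).
#' @param dir output directory (created if needed).
#' @param sep field delimiter (`"$"` default).
#' @return invisibly, the named vector of file paths.
#' @export
write_faers_bundle <- function(bundle, dir, sep = "$") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  for (tab in intersect(FAERS_TABLES, toupper(names(bundle)))) {
    path <- file.path(dir, paste0(tolower(tab), ".txt"))
    data.table::fwrite(bundle[[tab]], path, sep = sep, quote = FALSE,
                       eol = "\n")
    paths[tab] <- path
  }
  invisible(paths)
}
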