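# End-to-end orchestration: ingest (or simulate) -> standardize ->
# deduplicate -> primary-suspect filter -> contingency -> four algorithms
# -> tiering -> severity -> strata -> onset -> report bundle, with a
# machine-readable manifest of counts at every stage.

#' Build a run configuration
#'
#' Exactly one of `input_paths` (named FAERS table files) or `synthetic`
#' (a [synthetic_config()]) must be supplied.
#'
#' @param target character vector of target (focal) drug names.
#' @param input_paths named paths for [parse_quarter()], or `NULL`.
#' @param synthetic a [synthetic_config()], or `NULL`.
#' @param output_dir directory for the report bundle.
#' @param seed run seed; every source of randomness (synthetic generation,
#'   bootstrap) flows from it.
#' @param sep input delimiter for file ingestion.
#' @param pt_soc_map path to a PT->SOC TSV; defaults to the bundled
#'   fixture.
#' @param labeled_pts path to a labeled-PT TSV (one PT per line under a
#'   `pt` header); defaults to the bundled synthetic label list.
#' @param thresholds named list of positivity-threshold overrides passed
#'   to [signal_metrics()] (e.g. `ror_min`, `prr_min`, `ebgm05_min`).
#' @param fdr_method `"BH"` or `"bonferroni"`.
#' @param ic_mode [bcpnn_ic()] mode.
#' @param severity_correct Yates correction on/off for the chi-square
#'   branch of the severity comparison.
#' @param severity_min_events minimum total events for a PT to enter the
#'   severity table.
#' @param onset_offset,onset_ci options for [weibull_fit()].
#' @param mgps_prior_source family of drug-event cells the MGPS prior is
#'   fitted on: `"focal_tables"` (default; the focal drug's per-PT tables)
#'   or `"all_drugs"` (every drug crossed with every PT via
#'   [mgps_cells()], the null-dominated family of classical MGPS
#'   practice).
#' @return validated list of class `run_config`.
#' @export
run_config <- function(target = "VONOPRAZAN",
                       input_paths = NULL,
                       synthetic = NULL,
                       output_dir = tempfile("faersignal_run_"),
                       seed = 1L,
                       sep = "$",
                       pt_soc_map = system.file("extdata", "pt_soc_map.tsv",
                                               package = "faersignal"),
                       labeled_pts = system.file(
                         "extdata", "label_pts_synthetic.tsv",
                         package = "faersignal"),
                       thresholds = list(),
                       fdr_method = c("BH", "bonferroni"),
                       ic_mode = c("closed_form", "ic_from_ebgm"),
                       severity_correct = TRUE,
                       severity_min_events = 5,
                       onset_offset = "auto",
                       onset_ci = "wald",
                       mgps_prior_source = c("focal_tables", "all_drugs")) {
  if (is.null(input_paths) == is.null(synthetic)) {
    stop("supply exactly one of 'input_paths' or 'synthetic'")
  }
  bad <- unlist(thresholds)
  if (length(bad) && any(!is.finite(bad) | bad <= 0)) {
    stop("all thresholds must be positive numbers")
  }
  structure(list(target = normalize_drug_name(target),
                 input_paths = input_paths, synthetic = synthetic,
                 output_dir = output_dir, seed = as.integer(seed),
                 sep = sep, pt_soc_map = pt_soc_map,
                 labeled_pts = labeled_pts, thresholds = thresholds,
                 fdr_method = match.arg(fdr_method),
                 ic_mode = match.arg(ic_mode),
                 severity_correct = severity_correct,
                 severity_min_events = severity_min_events,
                 onset_offset = onset_offset, onset_ci = onset_ci,
                 mgps_prior_source = match.arg(mgps_prior_source)),
            class = "run_config")
}

#' Load a run configuration from a YAML file
#'
#' Keys mirror the arguments of [run_config()]; a `synthetic:` block is
#' passed to [synthetic_config()].
#'
#' @param path YAML file.
#' @return a `run_config`.
#' @export
load_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$synthetic)) {
    sy <- y$synthetic
    y$synthetic <- do.call(synthetic_config, sy)
  }
  do.call(run_config, y)
}

#' Tabulate co-medications among focal reports
#'
#' Counts distinct non-target normalized drug names per focal report
#' (a drug repeated on one report counts once), ranked by descending
#' report count with alphabetical tie-break.
#'
#' @param drugs standardized drug table.
#' @param focal_ids focal report ids.
#' @param target normalized target drug names (token match, as in
#'   [select_primary_suspect()]).
#' @return `data.table` with `drug_name`, `n_reports`.
#' @export
tabulate_comedications <- function(drugs, focal_ids, target) {
  dt <- data.table::as.data.table(drugs)
  target <- normalize_drug_name(target)
  dt <- dt[primary_id %in% as.character(focal_ids)]
  is_target <- vapply(strsplit(dt$drug_name, " ", fixed = TRUE),
                      function(tok) any(tok %in% target), logical(1))
  dt <- unique(dt[!is_target, .(primary_id, drug_name)])
  out <- dt[, .(n_reports = .N), by = drug_name]
  data.table::setorder(out, -n_reports, drug_name)
  out[]
}

#' Descriptive baseline table
#'
#' Counts and percentages by sex, descriptive age band, weight band,
#' outcome, country, reporter type, and report year, split by seriousness
#' — the shape of a baseline characteristics table.
#'
#' @param cases deduplicated focal case table.
#' @return `data.table` with `variable`, `level`, `n_serious`,
#'   `n_nonserious`, `n_overall`, `pct_overall` (and per-group
#'   percentages).
#' @export
descriptive_table <- function(cases) {
  dt <- data.table::as.data.table(cases)
  n_all <- nrow(dt); n_ser <- sum(dt$serious); n_non <- n_all - n_ser
  wt_band <- ifelse(is.na(dt$weight_kg), "missing",
                    ifelse(dt$weight_kg < 50, "<50",
                           ifelse(dt$weight_kg < 100, "50-100", ">=100")))
  year <- substr(dt$fda_date, 1, 4)
  year[is.na(year)] <- "missing"
  vars <- list(
    sex = ifelse(dt$sex == "unknown", "missing", dt$sex),
    age_band = age_band(dt$age_years, "descriptive"),
    weight_band = wt_band,
    outcome = ifelse(dt$serious & nzchar(dt$outcomes), dt$outcomes,
                     ifelse(dt$serious, "other_serious", "other")),
    country = ifelse(nzchar(dt$country), dt$country, "missing"),
    reporter_type = dt$reporter_type,
    year = year
  )
  rows <- lapply(names(vars), function(v) {
    lv <- vars[[v]]
    data.table::data.table(variable = v, level = sort(unique(lv)))[
      , .(variable, level,
          n_serious = vapply(level, function(l) sum(lv == l & dt$serious), 0L),
          n_nonserious = vapply(level, function(l) sum(lv == l & !dt$serious), 0L))]
  })
  out <- data.table::rbindlist(rows)
  out[, n_overall := n_serious + n_nonserious]
  out[, pct_overall := round(100 * n_overall / n_all, 1)]
  out[, pct_serious := if (n_ser > 0) round(100 * n_serious / n_ser, 1) else NA_real_]
  out[, pct_nonserious := if (n_non > 0) round(100 * n_nonserious / n_non, 1) else NA_real_]
  data.table::setattr(out, "totals",
                      c(overall = n_all, serious = n_ser, nonserious = n_non))
  out[]
}

write_tsv <- function(x, dir, name) {
  path <- file.path(dir, paste0(name, ".tsv"))
  data.table::fwrite(x, path, sep = "\t", quote = FALSE, eol = "\n", na = "NA")
  path
}

#' Run the full signal-detection pipeline
#'
#' Executes every stage on either ingested FAERS-style files or a
#' synthetic database, and writes a deterministic report bundle:
#' descriptive table, per-PT and per-SOC signal tables (machine precision
#' plus a human-formatted signal table at 2-decimal ratios / 3-decimal
#' chi-square), severity comparison, unlisted-signal list, co-medication
#' ranking, per-sex and per-age-band stratified signal tables, onset
#' summaries with Weibull fit and cumulative curves, the cleaned case
#' table, and a JSON run manifest (config echo, seed, stage counts).
#'
#' @param config a [run_config()].
#' @param quiet suppress progress messages.
#' @return (invisibly) a list with every in-memory artifact plus
#'   `manifest`.
#' @export
run_pipeline <- function(config, quiet = TRUE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  manifest <- list(seed = config$seed, target = config$target,
                   stages = list())

  # -- ingest ---------------------------------------------------------
  stage <- "ingest"
  res <- tryCatch({
    bundle <- if (!is.null(config$synthetic)) {
      generate_reports(config$synthetic, seed = config$seed)
    } else {
      parse_quarter(config$input_paths, sep = config$sep, quiet = quiet)
    }
    std <- standardize_bundle(bundle)
    n_raw <- nrow(std$cases)

    stage <- "deduplicate"
    cases <- deduplicate_cases(std$cases)
    manifest$stages$deduplicate <- list(
      reports_in = n_raw, reports_out = nrow(cases),
      removed = attr(cases, "n_removed"))
    ids <- cases$primary_id
    drugs <- std$drugs[primary_id %in% ids]
    reactions <- std$reactions[primary_id %in% ids]
    therapies <- std$therapies[primary_id %in% ids]

    stage <- "select_primary_suspect"
    focal <- select_primary_suspect(drugs, config$target)
    focal <- intersect(focal, ids)
    manifest$stages$primary_suspect <- list(n_focal = length(focal))
    focal_cases <- cases[primary_id %in% focal]
    focal_cases <- impute_weight(focal_cases)

    stage <- "descriptive"
    desc <- descriptive_table(focal_cases)

    stage <- "contingency"
    map <- read_pt_soc_map(config$pt_soc_map)
    pt_tab <- build_pt_tables(ids, reactions, focal)
    soc_tab <- build_soc_tables(ids, reactions, focal, map)

    stage <- "signals"
    prior <- if (identical(config$mgps_prior_source, "all_drugs")) {
      # alternative family: every drug crossed with every PT
      cells <- mgps_cells(ids, reactions, drugs)
      fit_mgps_prior(cells$a, cells$E)
    } else {
      E <- (pt_tab$a + pt_tab$b) * (pt_tab$a + pt_tab$c) /
        (pt_tab$a + pt_tab$b + pt_tab$c + pt_tab$d)
      fit_mgps_prior(pt_tab$a, E)
    }
    sig_args <- c(list(pt_tab, prior = prior, fdr_method = config$fdr_method,
                       ic_mode = config$ic_mode), config$thresholds)
    sig <- do.call(signal_metrics, sig_args)
    soc_sig <- do.call(signal_metrics,
                       c(list(soc_tab, prior = prior,
                              fdr_method = config$fdr_method,
                              ic_mode = config$ic_mode), config$thresholds))
    sig <- merge(sig, map, by.x = "label", by.y = "pt", all.x = TRUE,
                 sort = TRUE)
    labeled <- data.table::fread(config$labeled_pts, sep = "\t",
                                 header = TRUE)[[1]]
    unlisted <- compare_to_label(sig, labeled)
    manifest$stages$signals <- list(
      n_pts = nrow(sig),
      n_cross_validated = sum(sig$tier == "cross_validated"),
      n_hypothesis = sum(sig$tier == "hypothesis_generating"),
      n_unlisted = nrow(unlisted))

    stage <- "severity"
    ser_ids <- focal_cases$primary_id[focal_cases$serious]
    freac <- reactions[primary_id %in% focal]
    ser_n <- nrow(freac[primary_id %in% ser_ids])
    non_n <- nrow(freac) - ser_n
    cnt <- freac[, .(serious_events = sum(primary_id %in% ser_ids),
                     nonserious_events = sum(!primary_id %in% ser_ids)),
                 by = .(pt)]
    cnt <- cnt[serious_events + nonserious_events >= config$severity_min_events]
    data.table::setorder(cnt, pt)
    sev <- if (nrow(cnt) && ser_n > 0 && non_n > 0) {
      severity_analysis(cnt, ser_n, non_n, correct = config$severity_correct)
    } else data.table::data.table()

    stage <- "comedications"
    comed <- tabulate_comedications(drugs, focal, config$target)

    stage <- "stratified"
    strata <- list()
    for (by in c("sex", "age_band")) {
      parts <- stratify_cases(cases, by)
      for (nm in setdiff(names(parts), "missing")) {
        sids <- parts[[nm]]
        sfoc <- intersect(focal, sids)
        if (length(sids) < 2 || length(sfoc) == 0) next
        st <- build_pt_tables(sids, reactions[primary_id %in% sids], sfoc,
                              stratum = nm)
        ssig <- do.call(signal_metrics,
                        c(list(st, prior = prior,
                               fdr_method = config$fdr_method,
                               ic_mode = config$ic_mode), config$thresholds))
        ssig[, `:=`(stratum_by = by, stratum = nm)]
        strata[[paste(by, nm, sep = ":")]] <- ssig
      }
    }
    strat <- data.table::rbindlist(strata, fill = TRUE)

    stage <- "onset"
    fth <- therapies[primary_id %in% focal]
    fev <- focal_cases[, .(primary_id, event_date)]
    tto <- compute_tto(fth, fev, cases = focal_cases)
    onset_out <- NULL
    if (nrow(tto) >= 10 && length(unique(tto$tto_days)) >= 2) {
      wb <- weibull_fit(tto$tto_days, offset = config$onset_offset,
                        ci = config$onset_ci)
      curves <- cumulative_onset(tto, by = "sex")
      smry <- summarize_tto(tto$tto_days)
      lr <- tryCatch(
        logrank_tto(tto$tto_days[tto$sex %in% c("female", "male")],
                    tto$sex[tto$sex %in% c("female", "male")]),
        error = function(e) NULL)
      onset_out <- list(records = tto, fit = wb, curves = curves,
                        summary = smry, logrank = lr)
      manifest$stages$onset <- list(
        records_in = nrow(tto) + sum(attr(tto, "exclusions")),
        evaluable = nrow(tto),
        exclusions = as.list(attr(tto, "exclusions")))
    }

    list(cases = cases, focal_cases = focal_cases, focal = focal,
         reactions = reactions, drugs = drugs, desc = desc,
         pt_tables = pt_tab, soc_tables = soc_tab, signals = sig,
         soc_signals = soc_sig, unlisted = unlisted, severity = sev,
         comedications = comed, stratified = strat, onset = onset_out,
         prior = prior)
  }, error = function(e) {
    manifest$failed_stage <- stage
    manifest$error <- conditionMessage(e)
    jsonlite::write_json(manifest,
                         file.path(config$output_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    stop("pipeline failed at stage '", stage, "': ",
         conditionMessage(e), call. = FALSE)
  })

  # -- write the bundle ----------------------------------------------
  out <- config$output_dir
  write_tsv(res$cases, out, "cleaned_cases")
  write_tsv(res$desc, out, "descriptive_table")
  write_tsv(res$signals, out, "signal_table_pt")
  write_tsv(res$soc_signals, out, "signal_table_soc")
  write_tsv(format_signal_table(res$signals), out, "signal_table_formatted")
  write_tsv(res$unlisted, out, "unlisted_signals")
  if (nrow(res$severity)) write_tsv(res$severity, out, "severity_table")
  write_tsv(res$comedications, out, "comedications")
  if (nrow(res$stratified)) write_tsv(res$stratified, out,
                                      "stratified_signals")
  if (!is.null(res$onset)) {
    fitdt <- with(res$onset$fit, data.table::data.table(
      n = n, median_iqr = sprintf("%g (%g-%g)", res$onset$summary$median,
                                  res$onset$summary$q1, res$onset$summary$q3),
      scale_alpha = scale_alpha, scale_lower = scale_ci[1],
      scale_upper = scale_ci[2], shape_beta = shape_beta,
      shape_lower = shape_ci[1], shape_upper = shape_ci[2],
      failure_type = failure_type))
    write_tsv(fitdt, out, "onset_weibull")
    write_tsv(res$onset$curves, out, "onset_curves")
  }
  manifest$config <- config_echo(config)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  res$manifest <- manifest
  invisible(res)
}

# Human-formatted signal table: 2 decimals for ratios, 3 for chi-square.
format_signal_table <- function(sig) {
  dt <- data.table::as.data.table(sig)
  out <- data.table::data.table(
    soc = if ("soc" %in% names(dt)) dt$soc else NA_character_,
    pt = dt$label, cases = dt$n_cases,
    ror_ci = sprintf("%.2f (%.2f-%.2f)", dt$ror, dt$ror_lower, dt$ror_upper),
    prr_chi2 = sprintf("%.2f (%.3f)", dt$prr, dt$chi2),
    ebgm_ebgm05 = sprintf("%.2f (%.2f)", dt$ebgm, dt$ebgm05),
    ic_ic025 = sprintf("%.2f (%.2f)", dt$ic, dt$ic025),
    p_adjusted = ifelse(is.na(dt$p_adjusted), "",
                        sprintf("%.3g", dt$p_adjusted)),
    tier = dt$tier)
  data.table::setorder(out, -cases, pt)
  out[]
}

# Config as echoed into the manifest. The output directory is dropped so
# that runs into different directories stay byte-identical.
config_echo <- function(config) {
  e <- unclass(config)
  e$output_dir <- NULL
  if (!is.null(e$synthetic)) {
    s <- unclass(e$synthetic)
    s$background_pts <- NULL
    s$planted_signals <- as.list(e$synthetic$planted_signals[, .(
      pt, relative_reporting_ratio)])
    e$synthetic <- s
  }
  e$input_paths <- if (is.null(e$input_paths)) NULL else
    as.list(e$input_paths)
  e
}

#' Ranked signal views
#'
#' The two conventional orderings of a signal table: by case count and by
#' ROR (descending), each restricted to the top `n`.
#'
#' @param sig a [signal_metrics()] table.
#' @param n number of rows per view.
#' @return list with `by_cases`, `by_ror`.
#' @export
rank_signals <- function(sig, n = 50) {
  dt <- data.table::as.data.table(sig)
  by_cases <- data.table::copy(dt)[order(-n_cases, label)][seq_len(min(n, .N))]
  by_ror <- data.table::copy(dt)[order(-ror, label)][seq_len(min(n, .N))]
  list(by_cases = by_cases, by_ror = by_ror)
}
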