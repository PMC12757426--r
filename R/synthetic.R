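# Synthetic spontaneous-report database with known ground truth: planted
# per-PT reporting-rate elevations over background, demographic strata,
# seriousness outcomes, Weibull-distributed onset intervals, plus injected
# duplicates and partial dates so the cleaning stage is exercised.

default_background_pts <- function() {
  # ~40 background PTs spanning the SOCs of a gastric acid-suppressant
  # safety profile; probabilities chosen so a typical report carries 2-3
  # events (per-report occurrence probability, independent across PTs).
  data.table::data.table(
    pt = c(
      "Nausea", "Diarrhoea", "Headache", "Vomiting", "Abdominal pain",
      "Abdominal pain upper", "Abdominal discomfort", "Abdominal distension",
      "Dyspepsia", "Gastrooesophageal reflux disease", "Constipation",
      "Flatulence", "Dizziness", "Fatigue", "Asthenia", "Rash",
      "Pruritus", "Urticaria", "Insomnia", "Somnolence",
      "Dry mouth", "Decreased appetite", "Weight increased",
      "Weight decreased", "Arthralgia", "Myalgia", "Back pain",
      "Cough", "Dyspnoea", "Oropharyngeal pain", "Palpitations",
      "Hypertension", "Blood pressure decreased", "Oedema peripheral",
      "Pyrexia", "Chest pain", "Malaise", "Anxiety", "Depression",
      "Renal impairment", "Vomiting projectile", "Dysphagia",
      "Eructation", "Haematochezia", "Tremor", "Migraine", "Vertigo",
      "Alopecia", "Hyperhidrosis", "Blood creatinine increased",
      "Hepatic enzyme increased", "Bradycardia", "Tachycardia",
      "Nasopharyngitis", "Urinary tract infection"
    ),
    soc = c(
      "Gastrointestinal Disorders", "Gastrointestinal Disorders",
      "Nervous System Disorders", "Gastrointestinal Disorders",
      "Gastrointestinal Disorders", "Gastrointestinal Disorders",
      "Gastrointestinal Disorders", "Gastrointestinal Disorders",
      "Gastrointestinal Disorders", "Gastrointestinal Disorders",
      "Gastrointestinal Disorders", "Gastrointestinal Disorders",
      "Nervous System Disorders",
      "General Disorders And Administration Site Conditions",
      "General Disorders And Administration Site Conditions",
      "Skin And Subcutaneous Tissue Disorders",
      "Skin And Subcutaneous Tissue Disorders",
      "Skin And Subcutaneous Tissue Disorders",
      "Psychiatric Disorders", "Nervous System Disorders",
      "Gastrointestinal Disorders", "Metabolism And Nutrition Disorders",
      "Investigations", "Investigations",
      "Musculoskeletal And Connective Tissue Disorders",
      "Musculoskeletal And Connective Tissue Disorders",
      "Musculoskeletal And Connective Tissue Disorders",
      "Respiratory, Thoracic And Mediastinal Disorders",
      "Respiratory, Thoracic And Mediastinal Disorders",
      "Respiratory, Thoracic And Mediastinal Disorders",
      "Cardiac Disorders", "Vascular Disorders", "Vascular Disorders",
      "General Disorders And Administration Site Conditions",
      "General Disorders And Administration Site Conditions",
      "General Disorders And Administration Site Conditions",
      "General Disorders And Administration Site Conditions",
      "Psychiatric Disorders", "Psychiatric Disorders",
      "Renal And Urinary Disorders",
      "Gastrointestinal Disorders", "Gastrointestinal Disorders",
      "Gastrointestinal Disorders", "Gastrointestinal Disorders",
      "Nervous System Disorders", "Nervous System Disorders",
      "Nervous System Disorders",
      "Skin And Subcutaneous Tissue Disorders",
      "Skin And Subcutaneous Tissue Disorders",
      "Investigations", "Investigations",
      "Cardiac Disorders", "Cardiac Disorders",
      "Infections And Infestations", "Infections And Infestations"
    ),
    background_probability = c(
      0.12, 0.08, 0.09, 0.06, 0.05, 0.04, 0.03, 0.03,
      0.03, 0.04, 0.03, 0.02, 0.06, 0.08, 0.03, 0.05,
      0.03, 0.02, 0.03, 0.02, 0.02, 0.03, 0.02, 0.02,
      0.04, 0.03, 0.03, 0.04, 0.05, 0.02, 0.02, 0.03,
      0.01, 0.02, 0.04, 0.03, 0.04, 0.03, 0.03, 0.01,
      0.005, 0.02, 0.015, 0.01, 0.02, 0.02, 0.015,
      0.01, 0.015, 0.01, 0.015, 0.008, 0.012, 0.03, 0.025
    )
  )
}

default_planted_signals <- function() {
  # Three planted drug-event associations at relative reporting ratios
  # 2, 5 and 10 over background, echoing the magnitude range of real
  # acid-suppressant signals (common GI symptom, structural GI finding,
  # biochemical marker).
  data.table::data.table(
    pt = c("Abdominal distension", "Gastric polyps", "Blood gastrin increased"),
    soc = c("Gastrointestinal Disorders", "Gastrointestinal Disorders",
            "Investigations"),
    background_probability = c(0.015, 0.008, 0.005),
    relative_reporting_ratio = c(2, 5, 10),
    serious_probability = c(0.30, 0.45, 0.35),
    sex_bias = c(1, 1, 1),
    age_band_bias = c(1, 1, 1)
  )
}

#' Configuration for the synthetic spontaneous-report generator
#'
#' Bundles and validates every knob of the generator. Defaults emulate the
#' structure of a focal-drug pharmacovigilance cohort: the demographic mix
#' (62% female / 29.6% male / 8.4% unknown; age bands 8.1% / 36.6% /
#' 25.3% / 2.8% with 27.2% missing), ~80% missing weight, onset intervals
#' from a Weibull with shape 0.49 and scale 19.73 days (an early-failure
#' hazard), and three planted drug-event associations at relative reporting
#' ratios 2, 5 and 10.
#'
#' @param n_reports total number of unique reports.
#' @param focal_drug_share fraction of reports with the focal drug as
#'   primary suspect.
#' @param background_pts `data.table` with `pt`, `soc`,
#'   `background_probability` (per-report occurrence probability for
#'   non-focal reports).
#' @param planted_signals `data.table` with `pt`, `soc`,
#'   `background_probability`, `relative_reporting_ratio` (> 0),
#'   `serious_probability`, `sex_bias` (multiplier on the occurrence
#'   probability for female focal reports), `age_band_bias` (multiplier for
#'   focal reports aged >= 65).
#' @param onset_shape_beta,onset_scale_alpha Weibull parameters (shape
#'   dimensionless, scale in days) for focal-drug onset intervals.
#' @param sex_mix,age_mix named probability vectors over sexes and
#'   descriptive age bands (must sum to 1 within 1e-9).
#' @param serious_background baseline probability a report is serious when
#'   no planted event is present.
#' @param missing_weight,missing_start_date,missing_event_date per-field
#'   missingness probabilities.
#' @param partial_date_rate fraction of non-missing start/event dates
#'   truncated to YYYYMM (exercises the partial-date rule).
#' @param negative_interval_rate fraction of focal onset records whose
#'   event date is moved before the start date (exercises TTO exclusion).
#' @param duplicate_rate fraction of cases duplicated with an earlier
#'   FDA date and a smaller PRIMARYID (exercises deduplication).
#' @param n_background_drugs size of the background drug-name pool.
#' @param focal_drug normalized focal drug name written to DRUG rows;
#'   a salt-form variant (`paste(focal_drug, "FUMARATE")`) is used for a
#'   share of focal rows.
#' @param seed integer seed; `generate_reports()` is reproducible given it.
#' @return validated `synthetic_config` list.
#' @export
synthetic_config <- function(n_reports = 20000,
                             focal_drug_share = 0.10,
                             background_pts = default_background_pts(),
                             planted_signals = default_planted_signals(),
                             onset_shape_beta = 0.49,
                             onset_scale_alpha = 19.73,
                             sex_mix = c(female = 0.620, male = 0.296,
                                         unknown = 0.084),
                             age_mix = c("<18" = 0.081, "18-64.9" = 0.366,
                                         "65-85" = 0.253, ">=85" = 0.028,
                                         missing = 0.272),
                             serious_background = 0.30,
                             missing_weight = 0.81,
                             missing_start_date = 0.15,
                             missing_event_date = 0.10,
                             partial_date_rate = 0.05,
                             negative_interval_rate = 0.02,
                             duplicate_rate = 0.03,
                             n_background_drugs = 200,
                             focal_drug = "VONOPRAZAN",
                             seed = 20230101) {
  cfg <- list(n_reports = n_reports, focal_drug_share = focal_drug_share,
              background_pts = data.table::as.data.table(background_pts),
              planted_signals = data.table::as.data.table(planted_signals),
              onset_shape_beta = onset_shape_beta,
              onset_scale_alpha = onset_scale_alpha,
              sex_mix = sex_mix, age_mix = age_mix,
              serious_background = serious_background,
              missing_weight = missing_weight,
              missing_start_date = missing_start_date,
              missing_event_date = missing_event_date,
              partial_date_rate = partial_date_rate,
              negative_interval_rate = negative_interval_rate,
              duplicate_rate = duplicate_rate,
              n_background_drugs = n_background_drugs,
              focal_drug = normalize_drug_name(focal_drug),
              seed = seed)
  validate_synthetic_config(cfg)
  structure(cfg, class = "synthetic_config")
}

validate_synthetic_config <- function(cfg) {
  stopifnot(cfg$n_reports >= 0,
            cfg$focal_drug_share >= 0, cfg$focal_drug_share <= 1,
            cfg$onset_shape_beta > 0, cfg$onset_scale_alpha > 0,
            all(cfg$planted_signals$relative_reporting_ratio > 0),
            all(cfg$background_pts$background_probability >= 0),
            all(cfg$background_pts$background_probability <= 1))
  probs <- c(cfg$missing_weight, cfg$missing_start_date,
             cfg$missing_event_date, cfg$partial_date_rate,
             cfg$negative_interval_rate, cfg$duplicate_rate,
             cfg$serious_background,
             cfg$planted_signals$serious_probability)
  stopifnot(all(probs >= 0 & probs <= 1))
  if (abs(sum(cfg$sex_mix) - 1) > 1e-9) stop("sex_mix must sum to 1")
  if (abs(sum(cfg$age_mix) - 1) > 1e-9) stop("age_mix must sum to 1")
  dup <- intersect(cfg$planted_signals$pt, cfg$background_pts$pt)
  # a planted PT overrides its background entry; keep the lists disjoint
  # internally by dropping the background copy at generation time
  invisible(cfg)
}

# Combined PT panel: background PTs not overridden by a planted signal,
# then the planted signals.
pt_panel <- function(cfg) {
  bg <- cfg$background_pts[!pt %in% cfg$planted_signals$pt]
  bg[, `:=`(relative_reporting_ratio = 1, serious_probability = NA_real_,
            sex_bias = 1, age_band_bias = 1)]
  rbind(bg, cfg$planted_signals, fill = TRUE)
}

#' Ground truth for a synthetic configuration
#'
#' One row per PT in the panel: the generating relative reporting ratio,
#' the expected 2x2 cell probabilities under the generative model (ignoring
#' the rare fallback draw that guarantees each report at least one
#' reaction), and the onset distribution parameters.
#'
#' @param config a [synthetic_config()].
#' @return `data.table` with `pt`, `soc`, `ratio`, `p_background`,
#'   `p_a`, `p_b`, `p_c`, `p_d`, `onset_shape`, `onset_scale`.
#' @export
truth_table <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  panel <- pt_panel(config)
  s <- config$focal_drug_share
  p <- panel$background_probability
  r <- panel$relative_reporting_ratio
  pf <- pmin(p * r, 1)
  data.table::data.table(
    pt = panel$pt, soc = panel$soc, ratio = r, p_background = p,
    p_a = s * pf, p_b = s * (1 - pf),
    p_c = (1 - s) * p, p_d = (1 - s) * (1 - p),
    onset_shape = config$onset_shape_beta,
    onset_scale = config$onset_scale_alpha
  )
}

empty_bundle <- function() {
  structure(list(
    DEMO = data.table::data.table(
      primaryid = character(), caseid = character(), fda_dt = character(),
      event_dt = character(), sex = character(), age = character(),
      age_cod = character(), wt = character(), wt_cod = character(),
      reporter_country = character(), occp_cod = character(),
      quarter = character()),
    DRUG = data.table::data.table(
      primaryid = character(), drug_seq = character(),
      role_cod = character(), drugname = character()),
    REAC = data.table::data.table(primaryid = character(), pt = character()),
    OUTC = data.table::data.table(primaryid = character(),
                                  outc_cod = character()),
    THER = data.table::data.table(primaryid = character(),
                                  dsg_drug_seq = character(),
                                  start_dt = character()),
    INDI = data.table::data.table(primaryid = character(),
                                  indi_pt = character()),
    RPSR = data.table::data.table(primaryid = character(),
                                  rpsr_cod = character())
  ), class = c("faers_bundle", "list"))
}

#' Generate a synthetic spontaneous-report database
#'
#' Draws `n_reports` reports: each is focal (target drug as primary
#' suspect) with probability `focal_drug_share`; each PT in the panel
#' occurs independently with probability
#' `background_probability x (ratio if focal and planted, else 1)`, capped
#' at 1 (a warning names any (pt, ratio) pair that had to be capped).
#' Reports that drew no event receive one fallback PT sampled proportional
#' to background probability, since a spontaneous report always carries at
#' least one reaction. Onset intervals for focal reports are Weibull draws
#' rounded to whole days (day 0 legal); start/event/FDA dates are written
#' consistently. Duplicates (same CASEID, earlier FDA_DT, smaller
#' PRIMARYID) and partial dates are injected at the configured rates.
#'
#' @param config a [synthetic_config()].
#' @param seed overrides `config$seed`.
#' @return a `faers_bundle` of in-memory DEMO/DRUG/REAC/OUTC/THER/INDI/RPSR
#'   tables (same schema [parse_quarter()] reads); attribute `n_unique`
#'   gives the intended unique case count.
#' @export
generate_reports <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "synthetic_config"))
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(seed)
  }
  n <- config$n_reports
  if (n == 0L) {
    bundle <- empty_bundle()
    data.table::setattr(bundle, "n_unique", 0L)
    return(bundle)
  }
  panel <- pt_panel(config)
  capped <- panel$background_probability * panel$relative_reporting_ratio > 1
  if (any(capped)) {
    warning("occurrence probability capped at 1 for: ",
            paste(sprintf("%s (ratio %g)", panel$pt[capped],
                          panel$relative_reporting_ratio[capped]),
                  collapse = ", "))
  }

  pid <- as.character(100000000 + seq_len(n))
  cid <- as.character(90000000 + seq_len(n))
  focal <- runif(n) < config$focal_drug_share
  sex <- sample(names(config$sex_mix), n, TRUE, config$sex_mix)
  band <- sample(names(config$age_mix), n, TRUE, config$age_mix)
  age <- rep(NA_real_, n)
  age[band == "<18"] <- runif(sum(band == "<18"), 1, 17.9)
  age[band == "18-64.9"] <- runif(sum(band == "18-64.9"), 18, 64.9)
  age[band == "65-85"] <- runif(sum(band == "65-85"), 65, 84.9)
  age[band == ">=85"] <- runif(sum(band == ">=85"), 85, 99)
  weight <- round(pmax(30, rnorm(n, 72, 15)), 1)
  weight[runif(n) < config$missing_weight] <- NA_real_

  # reaction matrix: report x PT Bernoulli draws
  npt <- nrow(panel)
  pmat <- matrix(rep(panel$background_probability, each = n), n, npt)
  planted <- panel$relative_reporting_ratio != 1
  if (any(planted)) {
    for (j in which(planted)) {
      mult <- rep(1, n)
      mult[focal] <- panel$relative_reporting_ratio[j]
      mult[focal & sex == "female"] <- mult[focal & sex == "female"] *
        panel$sex_bias[j]
      older <- focal & !is.na(age) & age >= 65
      mult[older] <- mult[older] * panel$age_band_bias[j]
      pmat[, j] <- pmin(pmat[, j] * mult, 1)
    }
  }
  occ <- matrix(runif(n * npt), n, npt) < pmat
  none <- rowSums(occ) == 0L
  if (any(none)) {
    fallback <- sample.int(npt, sum(none), TRUE,
                           prob = panel$background_probability)
    occ[cbind(which(none), fallback)] <- TRUE
  }

  reac_idx <- which(occ, arr.ind = TRUE)
  reac <- data.table::data.table(primaryid = pid[reac_idx[, 1]],
                                 pt = panel$pt[reac_idx[, 2]])
  data.table::setorder(reac, primaryid, pt)

  # seriousness: planted events can raise the report-level probability
  p_serious <- rep(config$serious_background, n)
  for (j in which(planted)) {
    has <- occ[, j] & focal
    p_serious[has] <- pmax(p_serious[has], panel$serious_probability[j])
  }
  serious <- runif(n) < p_serious
  outc_code <- rep("OT", n)
  outc_code[serious] <- sample(c("HO", "DE", "LT", "DS", "RI", "CA"),
                               sum(serious), TRUE,
                               prob = c(0.45, 0.08, 0.05, 0.03, 0.35, 0.04))
  outc <- data.table::data.table(primaryid = pid, outc_cod = outc_code)

  # dates: start within the reporting window, event = start + Weibull onset
  window_start <- as.Date("2023-01-01")
  window_days <- as.integer(as.Date("2025-02-01") - window_start)
  start <- window_start + sample.int(window_days, n, TRUE) - 1L
  onset <- round(rweibull(n, shape = config$onset_shape_beta,
                          scale = config$onset_scale_alpha))
  event <- start + onset
  neg <- focal & runif(n) < config$negative_interval_rate
  event[neg] <- start[neg] - sample(1:30, sum(neg), TRUE)
  fda <- event + sample(7:60, n, TRUE)
  fmt <- function(d) format(d, "%Y%m%d")
  start_s <- fmt(start); event_s <- fmt(event); fda_s <- fmt(fda)
  start_s[runif(n) < config$missing_start_date] <- ""
  event_s[runif(n) < config$missing_event_date] <- ""
  part <- runif(n) < config$partial_date_rate
  start_s[part & nzchar(start_s)] <- substr(start_s[part & nzchar(start_s)], 1, 6)

  country <- sample(c("US", "JP", "BR", "CN"), n, TRUE,
                    prob = c(0.684, 0.243, 0.058, 0.015))
  occp <- sample(c("CN", "MD", "HP", "PH", ""), n, TRUE,
                 prob = c(0.648, 0.194, 0.097, 0.057, 0.004))
  age_cod <- rep("YR", n)
  dec <- runif(n) < 0.05
  age_val <- ifelse(is.na(age), "", sprintf("%.1f", age))
  age_val[dec & !is.na(age)] <- sprintf("%.2f", age[dec & !is.na(age)] / 10)
  age_cod[dec] <- "DEC"
  age_cod[is.na(age)] <- ""
  qtr <- paste0(format(fda, "%Y"), "Q", (as.integer(format(fda, "%m")) - 1L) %/% 3L + 1L)

  demo <- data.table::data.table(
    primaryid = pid, caseid = cid, fda_dt = fda_s, event_dt = event_s,
    sex = c(female = "F", male = "M", unknown = "UNK")[sex],
    age = age_val, age_cod = age_cod,
    wt = ifelse(is.na(weight), "", sprintf("%.1f", weight)),
    wt_cod = ifelse(is.na(weight), "", "KG"),
    reporter_country = country, occp_cod = occp, quarter = qtr)

  # drug rows: focal PS drug (sometimes a salt form) plus 0-3 concomitants;
  # non-focal reports get a PS drug from the background pool
  pool <- c("ASPIRIN", "LEVOTHYROXINE", "FAMOTIDINE", "OMEPRAZOLE",
            "WARFARIN", "METFORMIN", "AMLODIPINE", "ATORVASTATIN",
            sprintf("BACKGROUND DRUG %03d", seq_len(config$n_background_drugs)))
  pool_w <- c(rep(6, 8), rep(1, config$n_background_drugs))
  ps_name <- character(n)
  salt <- runif(n) < 0.3
  ps_name[focal] <- ifelse(salt[focal],
                           paste(config$focal_drug, "FUMARATE"),
                           config$focal_drug)
  ps_name[!focal] <- sample(pool, sum(!focal), TRUE, prob = pool_w)
  n_con <- sample(0:3, n, TRUE, prob = c(0.35, 0.35, 0.2, 0.1))
  con_pid <- rep(pid, n_con)
  con_name <- sample(pool, sum(n_con), TRUE, prob = pool_w)
  drug <- rbind(
    data.table::data.table(primaryid = pid, drug_seq = "1", role_cod = "PS",
                           drugname = ps_name),
    data.table::data.table(primaryid = con_pid,
                           drug_seq = as.character(
                             sequence(n_con[n_con > 0]) + 1L),
                           role_cod = "C", drugname = con_name))
  data.table::setorder(drug, primaryid, drug_seq)

  ther <- data.table::data.table(primaryid = pid, dsg_drug_seq = "1",
                                 start_dt = start_s)
  indi <- data.table::data.table(
    primaryid = pid,
    indi_pt = sample(c("Gastrooesophageal reflux disease",
                       "Helicobacter infection", "Dyspepsia",
                       "Product used for unknown indication"),
                     n, TRUE, prob = c(0.5, 0.2, 0.15, 0.15)))
  rpsr <- data.table::data.table(primaryid = pid, rpsr_cod = "FGN")

  # duplicate injection: earlier FDA_DT and smaller PRIMARYID so the
  # "latest FDA_DT" branch of deduplication is exercised
  n_dup <- floor(config$duplicate_rate * n)
  if (n_dup > 0) {
    di <- sample.int(n, n_dup)
    dup_pid <- as.character(50000000 + seq_len(n_dup))
    dup_demo <- demo[di]
    dup_demo[, primaryid := dup_pid]
    dup_demo[, fda_dt := fmt(fda[di] - 30L)]
    demo <- rbind(demo, dup_demo)
    add_dup <- function(tab) {
      sub <- tab[tab$primaryid %in% pid[di]]
      sub[, primaryid := dup_pid[match(primaryid, pid[di])]]
      rbind(tab, sub)
    }
    drug <- add_dup(drug); reac <- add_dup(reac); outc <- add_dup(outc)
    ther <- add_dup(ther); indi <- add_dup(indi); rpsr <- add_dup(rpsr)
  }
  data.table::setorder(demo, primaryid)
  data.table::setorder(reac, primaryid, pt)
  data.table::setorder(drug, primaryid, drug_seq, drugname)
  data.table::setorder(outc, primaryid)
  data.table::setorder(ther, primaryid)
  data.table::setorder(indi, primaryid)
  data.table::setorder(rpsr, primaryid)

  bundle <- structure(list(DEMO = demo, DRUG = drug, REAC = reac,
                           OUTC = outc, THER = ther, INDI = indi,
                           RPSR = rpsr),
                      class = c("faers_bundle", "list"))
  data.table::setattr(bundle, "n_unique", n)
  bundle
}
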