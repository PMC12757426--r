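# In-code fixtures: tiny FAERS-style tables written to tempfiles, and a
# shared fast path from a synthetic bundle to a signal table.

write_fixture_quarter <- function(dir = withr::local_tempdir(.local_envir = parent.frame())) {
  w <- function(name, lines) {
    path <- file.path(dir, name)
    writeLines(lines, path)
    path
  }
  list(
    DEMO = w("demo.txt", c(
      "primaryid$caseid$fda_dt$event_dt$sex$age$age_cod$wt$wt_cod$reporter_country$occp_cod",
      "1001$501$20240101$20240108$F$5$DEC$154$LBS$US$CN",
      "1002$502$20240215$20240220$M$34$YR$70$KG$JP$MD",
      "1003$503$20240301$$UNK$$$$$$BR$"
    )),
    DRUG = w("drug.txt", c(
      "primaryid$drug_seq$role_cod$drugname",
      "1001$1$PS$Voquezna® (vonoprazan)",
      "1001$2$C$ASPIRIN",
      "1002$1$PS$OMEPRAZOLE",
      "1002$2$SS$VONOPRAZAN FUMARATE",
      "1003$1$PS$VONOPRAZAN",
      "1003$2$I$WARFARIN"
    )),
    REAC = w("reac.txt", c(
      "primaryid$pt",
      "1001$Nausea",
      "1001$Nausea",
      "1001$Headache",
      "1002$Diarrhoea",
      "1003$Nausea"
    )),
    OUTC = w("outc.txt", c(
      "primaryid$outc_cod",
      "1001$OT",
      "1002$HO",
      "1002$OT",
      "1003$DE"
    )),
    THER = w("ther.txt", c(
      "primaryid$dsg_drug_seq$start_dt",
      "1001$1$20240101",
      "1002$1$20240210",
      "1003$1$202402"
    )),
    INDI = w("indi.txt", c("primaryid$indi_pt", "1001$Dyspepsia")),
    RPSR = w("rpsr.txt", c("primaryid$rpsr_cod", "1001$FGN"))
  )
}

# Case table for deduplication tests: 10 records in 4 case groups.
dedup_fixture <- function() {
  data.table::data.table(
    primary_id = as.character(c(100, 200, 101, 102, 103, 300, 301, 400, 401, 402)),
    case_id = c("A", "A", "B", "B", "B", "C", "C", "D", "D", "D"),
    fda_date = c("20240101", "20240101",              # tie -> larger id
                 "20240101", "20240301", "20240201",  # latest date
                 "20230505", "20230506",              # latest date
                 "20240401", "20240401", "20240331")  # tie among first two
  )
}

# Brute-force group-by/max oracle for deduplication.
oracle_dedup <- function(cases) {
  keep <- character()
  for (cid in unique(cases$case_id)) {
    g <- cases[cases$case_id == cid, ]
    g <- g[g$fda_date == max(g$fda_date), ]
    pid <- g$primary_id[which.max(as.numeric(g$primary_id))]
    keep <- c(keep, pid)
  }
  sort(keep)
}

# Shared replicate path: synthetic bundle -> standardize -> dedup -> PS
# filter -> PT tables (skips file I/O for speed). With `prior = TRUE` the
# MGPS prior is fitted on the full drug-event matrix, as the pipeline does.
replicate_tables <- function(config, seed, prior = FALSE) {
  b <- generate_reports(config, seed = seed)
  s <- standardize_bundle(b)
  cases <- deduplicate_cases(s$cases)
  ids <- cases$primary_id
  drugs <- s$drugs[s$drugs$primary_id %in% ids, ]
  reactions <- s$reactions[s$reactions$primary_id %in% ids, ]
  focal <- select_primary_suspect(drugs, config$focal_drug)
  out <- list(cases = cases, focal = focal, reactions = reactions,
              drugs = drugs,
              tables = build_pt_tables(ids, reactions, focal))
  if (prior) {
    cells <- mgps_cells(ids, reactions, drugs)
    out$prior <- fit_mgps_prior(cells$a, cells$E)
  }
  out
}
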