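# Ingestion: parsing, standardization, deduplication, primary-suspect
# selection, weight imputation.

test_that("parse_quarter reads '$'-delimited tables and enforces PRIMARYID", {
  fx <- write_fixture_quarter()
  bundle <- parse_quarter(fx, quiet = TRUE)
  expect_s3_class(bundle, "faers_bundle")
  expect_equal(nrow(bundle$DEMO), 3L)
  expect_equal(nrow(bundle$REAC), 5L)

  bad <- file.path(withr::local_tempdir(), "demo.txt")
  writeLines(c("caseid$fda_dt", "1$20240101"), bad)
  expect_error(parse_quarter(list(DEMO = bad), quiet = TRUE), "PRIMARYID")

  empty <- file.path(withr::local_tempdir(), "outc.txt")
  writeLines("primaryid$outc_cod", empty)
  expect_silent(b2 <- parse_quarter(list(OUTC = empty), quiet = TRUE))
  expect_equal(nrow(b2$OUTC), 0L)
})

test_that("standardization converts units, normalizes names, maps codes", {
  fx <- write_fixture_quarter()
  std <- standardize_bundle(parse_quarter(fx, quiet = TRUE))
  cases <- std$cases[order(primary_id)]
  # age 5 decades -> 50 y; 154 lbs -> 69.85 kg (154 x 0.45359237)
  expect_equal(cases$age_years[1], 50)
  expect_equal(cases$weight_kg[1], 154 * 0.45359237)
  expect_equal(cases$sex, c("female", "male", "unknown"))
  expect_equal(cases$reporter_type, c("consumer", "physician", "unknown"))
  # trade-name decoration stripped by the stated normalization rule
  expect_equal(std$drugs$drug_name[std$drugs$primary_id == "1001" &
                                     std$drugs$role == "primary_suspect"],
               "VOQUEZNA VONOPRAZAN")
  # FAERS role codes are a fixed bijection
  expect_setequal(std$drugs$role,
                  c("primary_suspect", "secondary_suspect", "concomitant",
                    "interacting"))
  # seriousness from outcome codes: OT alone non-serious, HO and DE serious
  expect_equal(cases$serious, c(FALSE, TRUE, TRUE))
})

test_that("reaction rows collapse to one per (report, PT)", {
  fx <- write_fixture_quarter()
  raw <- parse_quarter(fx, quiet = TRUE)
  std <- standardize_bundle(raw)
  pairs <- unique(data.frame(id = raw$REAC$primaryid, pt = raw$REAC$pt))
  expect_equal(nrow(std$reactions), nrow(pairs))
  expect_equal(
    sort(paste(std$reactions$primary_id, std$reactions$pt)),
    sort(paste(pairs$id, pairs$pt)))
})

test_that("out-of-bound values become missing and missing stays missing", {
  demo <- data.table::data.table(
    primaryid = c("1", "2", "3", "4"), caseid = c("1", "2", "3", "4"),
    fda_dt = "20240101", sex = "F",
    age = c("300", "", "40", "50"), age_cod = c("YR", "", "YR", "XX"),
    wt = c("0.2", "70", "", "9000"), wt_cod = c("KG", "KG", "", "KG"))
  bundle <- structure(list(DEMO = demo), class = c("faers_bundle", "list"))
  expect_warning(std <- standardize_bundle(bundle), "unit code")
  expect_equal(std$cases$age_years, c(NA, NA, 40, NA))
  expect_equal(std$cases$weight_kg, c(NA, 70, NA, NA))
})

test_that("deduplication keeps latest FDA date then largest PRIMARYID", {
  # stated rules on two-record groups
  two <- data.table::data.table(primary_id = c("1", "2"),
                                case_id = c("X", "X"),
                                fda_date = c("20240101", "20240301"))
  expect_equal(deduplicate_cases(two)$primary_id, "2")
  tie <- data.table::data.table(primary_id = c("100", "200"),
                                case_id = c("X", "X"),
                                fda_date = c("20240101", "20240101"))
  expect_equal(deduplicate_cases(tie)$primary_id, "200")

  # 10-record fixture against the brute-force group-by/max oracle
  fx <- dedup_fixture()
  got <- deduplicate_cases(fx)
  expect_equal(nrow(got), 4L)
  expect_equal(sort(got$primary_id), oracle_dedup(fx))
})

test_that("deduplication is idempotent and never grows the input", {
  set.seed(11)
  for (i in 1:5) {
    n <- 50
    cases <- data.table::data.table(
      primary_id = as.character(sample(1000:9999, n)),
      case_id = as.character(sample(1:20, n, TRUE)),
      fda_date = format(as.Date("2024-01-01") + sample(0:365, n, TRUE),
                        "%Y%m%d"))
    once <- deduplicate_cases(cases)
    twice <- deduplicate_cases(once)
    expect_equal(as.data.frame(once), as.data.frame(twice),
                 ignore_attr = TRUE)
    expect_equal(attr(twice, "n_removed"), 0L)
    expect_lte(nrow(once), nrow(cases))
    expect_equal(nrow(once) == nrow(cases),
                 !anyDuplicated(cases$case_id) > 0)
  }
  # a missing case_id forms its own retained group
  miss <- data.table::data.table(primary_id = c("1", "2"),
                                 case_id = c("", "A"),
                                 fda_date = "20240101")
  expect_equal(nrow(deduplicate_cases(miss)), 2L)
})

test_that("primary-suspect selection matches a linear-scan oracle", {
  fx <- write_fixture_quarter()
  std <- standardize_bundle(parse_quarter(fx, quiet = TRUE))
  got <- select_primary_suspect(std$drugs, "VONOPRAZAN")
  # 1001: PS "VOQUEZNA VONOPRAZAN" (token match); 1002 has it only as
  # secondary suspect; 1003: PS "VONOPRAZAN"
  expect_equal(got, c("1001", "1003"))
  expect_error(select_primary_suspect(std$drugs, character()), "non-empty")
  # exact mode excludes the combination name
  expect_equal(select_primary_suspect(std$drugs, "VONOPRAZAN", match = "exact"),
               "1003")

  # 20-report random fixture vs a double-loop scan
  set.seed(21)
  drugs <- data.table::data.table(
    primary_id = as.character(rep(1:20, each = 2)),
    drug_name = sample(c("VONOPRAZAN", "VONOPRAZAN FUMARATE", "ASPIRIN",
                         "OMEPRAZOLE", "NOTVONOPRAZANX"), 40, TRUE),
    role = sample(c("primary_suspect", "concomitant"), 40, TRUE))
  oracle <- character()
  for (i in seq_len(nrow(drugs))) {
    if (drugs$role[i] == "primary_suspect" &&
        "VONOPRAZAN" %in% strsplit(drugs$drug_name[i], " ")[[1]]) {
      oracle <- c(oracle, drugs$primary_id[i])
    }
  }
  expect_equal(select_primary_suspect(drugs, "VONOPRAZAN"),
               sort(unique(oracle)))
})

test_that("weight imputation respects the missingness threshold", {
  # 80% missing: rule not triggered
  many_missing <- data.table::data.table(
    primary_id = as.character(1:10), sex = "female", age_years = 30,
    weight_kg = c(70, 72, rep(NA, 8)))
  out <- impute_weight(many_missing)
  expect_false(attr(out, "imputation")$performed)
  expect_equal(sum(is.na(out$weight_kg)), 8L)

  # 4% missing on 100 cases: imputed values equal hand group medians
  set.seed(31)
  cases <- data.table::data.table(
    primary_id = as.character(1:100),
    sex = rep(c("female", "male"), 50),
    age_years = rep(c(30, 70), each = 50),
    weight_kg = round(runif(100, 50, 90), 1))
  holes <- c(3, 18, 52, 77)
  cases$weight_kg[holes] <- NA
  out <- impute_weight(cases)
  expect_true(attr(out, "imputation")$performed)
  for (i in holes) {
    cell <- cases$sex == cases$sex[i] &
      age_band(cases$age_years, "descriptive") ==
        age_band(cases$age_years[i], "descriptive") & !is.na(cases$weight_kg)
    expect_equal(out$weight_kg[out$primary_id == as.character(i)],
                 median(cases$weight_kg[cell]))
    expect_true(out$weight_imputed[out$primary_id == as.character(i)])
  }
  # a cell with no observed weights stays missing with a warning
  lone <- data.table::data.table(
    primary_id = as.character(1:30), sex = c("male", rep("female", 29)),
    age_years = 30, weight_kg = c(NA, round(runif(29, 50, 90), 1)))
  expect_warning(out <- impute_weight(lone), "no observed")
  expect_true(is.na(out$weight_kg[out$primary_id == "1"]))
})
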