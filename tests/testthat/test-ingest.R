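test_that("drug-name normalization folds case, width and whitespace", {
  expect_equal(normalize_drug_name("  Clarithromycin "), "clarithromycin")
  expect_equal(normalize_drug_name("ＣＬＡＲＩＴＨＲＯＭＹＣＩＮ"),
               "clarithromycin")
  expect_equal(normalize_drug_name("sunitinib　 malate"),
               "sunitinib malate")
  # salt form stays a distinct key
  expect_false(normalize_drug_name("sunitinib malate") ==
                 normalize_drug_name("sunitinib"))
})

test_that("FAERS reader joins tables and keeps one row per input line", {
  dir <- withr::local_tempdir()
  demo <- data.frame(caseid = c("100", "100", "200"),
                     caseversion = c(1, 2, 1), age = c("50", "51", "60"),
                     age_cod = "YR", sex = c("F", "F", "M"),
                     occp_cod = "MD", event_dt = "20230410")
  drug <- data.frame(caseid = c("100", "100", "200"),
                     caseversion = c(1, 2, 1), drug_seq = 1,
                     role_cod = "PS", drugname = "Clarithromycin")
  reac <- data.frame(caseid = c("100", "100", "200"),
                     caseversion = c(1, 2, 1), pt_code = 10013911,
                     pt = "dysgeusia")
  ther <- data.frame(caseid = c("100", "100", "200"),
                     caseversion = c(1, 2, 1), dsg_drug_seq = 1,
                     start_dt = "20230401")
  paths <- Map(write_faers_file, list(demo, drug, reac, ther),
               file.path(dir, c("demo.txt", "drug.txt", "reac.txt",
                                "ther.txt")))
  x <- read_faers_tables(paths[[1]], paths[[2]], paths[[3]], paths[[4]])
  expect_equal(nrow(x$demo), 3L)          # row count equals line count
  expect_equal(x$drugs$start_date, rep("20230401", 3))
  expect_equal(x$events$onset_date, rep("20230410", 3))

  dd <- dedup_latest_version(x)
  expect_equal(nrow(dd$demo), 2L)
  expect_equal(dd$demo$version[dd$demo$case_id == "100"], 2L)
  expect_equal(dd$demo$age_years[dd$demo$case_id == "100"], 51)
})

test_that("FAERS age units convert to years; unknown units excluded later", {
  dir <- withr::local_tempdir()
  demo <- data.frame(caseid = as.character(1:4), caseversion = 1,
                     age = c("60", "18", "730", "5"),
                     age_cod = c("YR", "MON", "DY", "XX"),
                     sex = "F", occp_cod = "MD", event_dt = "")
  p <- write_faers_file(demo, file.path(dir, "demo.txt"))
  drug <- data.frame(caseid = "1", caseversion = 1, drug_seq = 1,
                     role_cod = "PS", drugname = "x")
  reac <- data.frame(caseid = "1", caseversion = 1, pt_code = 1, pt = "x")
  x <- read_faers_tables(p,
                         write_faers_file(drug, file.path(dir, "d.txt")),
                         write_faers_file(reac, file.path(dir, "r.txt")))
  expect_equal(x$demo$age_years, c(60, 1.5, 730 / 365.25, NA),
               tolerance = 1e-9)
  rep_ <- apply_exclusions(dedup_latest_version(x))
  expect_equal(unname(rep_$exclusions["missing_age"]), 1L)
})

test_that("malformed lines are rejected with a warning and counted", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "demo.txt")
  writeLines(c("caseid$caseversion$age$age_cod$sex$occp_cod$event_dt",
               "1$1$50$YR$F$MD$20230101",
               "2$1$60$YR$M",                      # too few fields
               "3$1$55$YR$F$MD$20230101"), p)
  drug <- data.frame(caseid = "1", caseversion = 1, drug_seq = 1,
                     role_cod = "PS", drugname = "x")
  reac <- data.frame(caseid = "1", caseversion = 1, pt_code = 1, pt = "x")
  expect_warning(
    x <- read_faers_tables(p,
                           write_faers_file(drug, file.path(dir, "d.txt")),
                           write_faers_file(reac, file.path(dir, "r.txt"))),
    "malformed")
  expect_equal(nrow(x$demo), 2L)
  expect_equal(x$rejected_lines, 1L)
})

test_that("a missing required column is a hard error naming it", {
  dir <- withr::local_tempdir()
  demo <- data.frame(caseid = "1", caseversion = 1, age = "50",
                     age_cod = "YR", occp_cod = "MD", event_dt = "")
  p <- write_faers_file(demo, file.path(dir, "demo.txt"))
  expect_error(read_faers_tables(p, p, p), "sex")
})

test_that("latest-version dedup matches a brute-force oracle and is idempotent", {
  set.seed(11)
  n <- 1000
  demo <- mk_demo(case_id = sample(1:300, n, replace = TRUE),
                  version = sample(0:5, n, replace = TRUE))
  x <- mk_srs_data(demo)
  dd <- dedup_latest_version(x)

  # oracle: independent split / max / last-row selection
  oracle <- do.call(rbind, lapply(split(demo, demo$case_id), function(g) {
    g[max(which(g$version == max(g$version))), ]
  }))
  oracle <- oracle[order(oracle$case_id), ]
  got <- dd$demo[order(dd$demo$case_id), ]
  rownames(oracle) <- rownames(got) <- NULL
  expect_equal(got, oracle)
  expect_equal(dedup_latest_version(dd)$demo, dd$demo)  # idempotent
})

test_that("ties on (case, version) keep the last-read row", {
  demo <- mk_demo(c("A", "A"), version = c(2L, 2L), age_years = c(1, 2))
  dd <- dedup_latest_version(mk_srs_data(demo))
  expect_equal(nrow(dd$demo), 1L)
  expect_equal(dd$demo$age_years, 2)
})

test_that("exclusions are tallied exactly and survivors + exclusions = input", {
  set.seed(21)
  n <- 100
  demo <- mk_demo(1:n, age_years = 50, sex = "male")
  planted_missing_age <- 1:4
  planted_anom_age <- 5:7
  planted_missing_sex <- 8:10
  demo$age_years[planted_missing_age] <- NA
  demo$age_years[planted_anom_age] <- c(-5, 130, 999)
  demo$sex[planted_missing_sex] <- NA
  rep_ <- apply_exclusions(mk_srs_data(demo))
  expect_equal(nrow(rep_$demo), 90L)
  expect_equal(unname(rep_$exclusions),
               c(4L, 3L, 3L))
  expect_equal(nrow(rep_$demo) + sum(rep_$exclusions), n)
})

test_that("case labelling matches a set-membership oracle and drops nothing", {
  set.seed(31)
  n <- 200
  demo <- mk_demo(1:n)
  codes <- sample(c(10013911L, 10082490L, 55L, 66L, 77L), n,
                  replace = TRUE)
  events <- mk_events(1:n, codes)
  rep_ <- apply_exclusions(mk_srs_data(demo, events = events))
  rep_ <- label_cases(rep_, c(10013911L, 10082490L))
  expect_equal(nrow(rep_$demo), n)
  oracle <- vapply(rep_$demo$case_id, function(id) {
    any(codes[match(id, as.character(1:n))] %in% c(10013911L, 10082490L))
  }, logical(1))
  expect_equal(unname(rep_$demo$is_case), unname(oracle))
  expect_error(label_cases(rep_, integer(0)), "non-empty")
})

test_that("onset computation applies the four date rules and tallies them", {
  demo <- mk_demo(1:6)
  drugs <- mk_drugs(1:6, "drug x",
                    start_date = c("20230410", "202304", "20230501",
                                   "2023", "20230101", NA))
  events <- mk_events(1:6, 10013911L,
                      onset_date = c("20230410", "202306", "20230401",
                                     "20230601", "20230131", "20230202"))
  rep_ <- label_cases(apply_exclusions(mk_srs_data(demo, drugs, events)),
                      10013911L)
  ons <- compute_onset(rep_, "Drug X", 10013911L)
  expect_equal(ons$time_to_onset_days[match(c("1", "2", "5"),
                                            ons$case_id)],
               c(0.5, 61, 30))
  tally <- attr(ons, "onset_exclusions")
  expect_equal(unname(tally["excluded_onset_before_start"]), 1L)
  expect_equal(unname(tally["excluded_year_only"]), 1L)
  expect_equal(unname(tally["excluded_missing_date"]), 1L)
  expect_equal(nrow(ons) + sum(tally), 6L)
  expect_true(all(ons$time_to_onset_days >= 0.5))
})

test_that("JADER reader maps decades, widths and collapses duplicates", {
  dir <- withr::local_tempdir()
  wcsv <- function(df, nm, path) {
    names(df) <- nm
    utils::write.table(df, path, sep = ",", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
    path
  }
  jn <- c("識別番号", "性別", "年齢", "報告者職種")
  demo <- data.frame(a = c("J1", "J2", "J2"),
                     b = c("男性", "女性", "女性"),
                     c = c("60歳代", "不明", "不明"), d = "医師")
  dn <- c("識別番号", "医薬品（一般名）", "医薬品の関与", "投与開始日")
  # half-width vs full-width variants of the same drug on one case
  drug <- data.frame(a = c("J1", "J1", "J2"),
                     b = c("ｓｕｎｉｔｉｎｉｂ ｍａｌａｔｅ",
                           "sunitinib malate", "metformin"),
                     c = "被疑薬", d = "20230401")
  rn <- c("識別番号", "PTコード", "有害事象", "有害事象の発現日")
  reac <- data.frame(a = c("J1", "J2"), b = c(10013911, 99),
                     c = c("dysgeusia", "other"), d = "20230410")
  x <- read_jader_tables(
    wcsv(demo, jn, file.path(dir, "demo.csv")),
    wcsv(drug, dn, file.path(dir, "drug.csv")),
    wcsv(reac, rn, file.path(dir, "reac.csv")))
  expect_equal(nrow(x$demo), 2L)            # exact dup row collapsed
  expect_equal(nrow(x$drugs), 2L)           # width variants collapse
  expect_equal(sort(unique(x$drugs$drug_name)),
               c("metformin", "sunitinib malate"))
  expect_equal(x$demo$age_years[x$demo$case_id == "J1"], 65)
  expect_true(is.na(x$demo$age_years[x$demo$case_id == "J2"]))
})

test_that("JADER exact-duplicate removal matches a distinct-count oracle", {
  dir <- withr::local_tempdir()
  dn <- c("識別番号", "医薬品（一般名）", "医薬品の関与", "投与開始日")
  set.seed(5)
  drug <- data.frame(a = sprintf("J%02d", 1:17), b = "x", c = "被疑薬",
                     d = "20230401")
  drug <- rbind(drug, drug[c(1, 5, 9), ])   # 3 exact duplicates -> 20 rows
  drug <- drug[sample(nrow(drug)), ]
  names(drug) <- dn
  p <- file.path(dir, "drug.csv")
  utils::write.table(drug, p, sep = ",", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  jn <- c("識別番号", "性別", "年齢", "報告者職種")
  demo <- data.frame(a = "J01", b = "男性", c = "60歳代", d = "医師")
  names(demo) <- jn
  pd <- file.path(dir, "demo.csv")
  utils::write.table(demo, pd, sep = ",", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  rn <- c("識別番号", "PTコード", "有害事象", "有害事象の発現日")
  reac <- data.frame(a = "J01", b = 1, c = "x", d = "")
  names(reac) <- rn
  pr <- file.path(dir, "reac.csv")
  utils::write.table(reac, pr, sep = ",", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  x <- read_jader_tables(pd, p, pr)
  expect_equal(nrow(x$drugs), 17L)
})
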