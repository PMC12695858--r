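# Synthetic spontaneous-report generator with known ground truth. Every
# downstream stage (ingestion, disproportionality, time-to-onset,
# adjusted ROR) is validated against data produced here, since the real
# databases cannot ship with the package. Each simulated report carries
# exactly one primary-suspect drug drawn from a catalog; case status
# follows a logistic model combining a base reporting rate, a per-drug
# odds multiplier and optional age and sex effects; onset times are
# Weibull per drug; dates are built backwards from the onset intervals
# so the partial-date rules can be stress-tested by degrading precision.

#' Define a simulation scenario for synthetic SRS data
#'
#' Defaults describe a FAERS-like population: a background target-event
#' reporting rate of 0.24%, age centred at 60 (SD 15, truncated to
#' 0-100), 64.8% female, a catalog mixing drugs with strong
#' taste-disorder associations (odds multipliers echoing published
#' reporting odds ratios) and null comparators, and per-drug Weibull
#' onset models spanning early- and random-failure shapes.
#'
#' @param n_reports number of unique case reports.
#' @param drug_catalog data.frame `drug_name`, `weight`; weights are
#'   normalized to sampling probabilities (one suspect drug per
#'   report).
#' @param target_ae_base_rate case probability for a null drug at the
#'   reference age and male sex.
#' @param drug_effects named odds multipliers; drugs absent from the
#'   catalog are an error, catalog drugs absent here default to 1.
#' @param age_mean,age_sd age distribution in years, truncated to
#'   `[0, 100]`.
#' @param sex_ratio probability a report is female.
#' @param age_effect,sex_effect log-odds per year of age (centred at
#'   `age_mean`) and for female sex.
#' @param onset_models data.frame `drug_name`, `shape`, `scale`
#'   (days); `.default` row covers unlisted drugs.
#' @param missingness named probabilities of blanking `age`, `sex`,
#'   `start_date`, `onset_date`.
#' @param precision_loss named probabilities that a written date is
#'   degraded to `year_month` or `year` precision.
#' @param duplicate_rate probability a case also receives an earlier
#'   submission version (FAERS) / a duplicated row (JADER).
#' @param seed integer master seed, expanded into per-component
#'   substreams.
#' @return list of class `srs_scenario`.
#' @export
srs_scenario <- function(
    n_reports = 5000,
    drug_catalog = data.frame(
      drug_name = c("nirmatrelvir/ritonavir", "clarithromycin",
                    "sunitinib malate", "terbinafine hydrochloride",
                    "enzalutamide", "amoxicillin", "metformin",
                    "lisinopril", "atorvastatin", "omeprazole"),
      weight = c(0.0075, 0.0015, 0.0029, 0.0002, 0.0051,
                 0.19, 0.20, 0.20, 0.20, 0.19),
      stringsAsFactors = FALSE),
    target_ae_base_rate = 0.0024,
    drug_effects = c("nirmatrelvir/ritonavir" = 27,
                     "clarithromycin" = 12, "sunitinib malate" = 7.6,
                     "terbinafine hydrochloride" = 26,
                     "enzalutamide" = 2.9),
    age_mean = 60, age_sd = 15, sex_ratio = 0.648,
    age_effect = 0, sex_effect = 0,
    onset_models = data.frame(
      drug_name = c("nirmatrelvir/ritonavir", "clarithromycin",
                    "sunitinib malate", "terbinafine hydrochloride",
                    "enzalutamide", ".default"),
      shape = c(0.88, 1.07, 0.53, 0.86, 0.56, 1),
      scale = c(3, 2, 60, 40, 140, 30), stringsAsFactors = FALSE),
    missingness = c(age = 0.05, sex = 0.02, start_date = 0.10,
                    onset_date = 0.10),
    precision_loss = c(year_month = 0.10, year = 0.03),
    duplicate_rate = 0.05,
    seed = 1L) {
  stopifnot(n_reports > 0, target_ae_base_rate >= 0,
            target_ae_base_rate <= 1, sex_ratio >= 0, sex_ratio <= 1,
            all(onset_models$shape > 0), all(onset_models$scale > 0),
            duplicate_rate >= 0, duplicate_rate <= 1,
            all(missingness >= 0 & missingness <= 1))
  drug_catalog$drug_name <- normalize_drug_name(drug_catalog$drug_name)
  onset_models$drug_name[onset_models$drug_name != ".default"] <-
    normalize_drug_name(
      onset_models$drug_name[onset_models$drug_name != ".default"])
  if (length(drug_effects))
    names(drug_effects) <- normalize_drug_name(names(drug_effects))
  unknown <- setdiff(names(drug_effects), drug_catalog$drug_name)
  if (length(unknown))
    stop("drug_effects refer to drugs not in the catalog: ",
         paste(unknown, collapse = ", "))
  structure(list(
    n_reports = as.integer(n_reports), drug_catalog = drug_catalog,
    target_ae_base_rate = target_ae_base_rate,
    drug_effects = drug_effects, age_mean = age_mean, age_sd = age_sd,
    sex_ratio = sex_ratio, age_effect = age_effect,
    sex_effect = sex_effect, onset_models = onset_models,
    missingness = missingness, precision_loss = precision_loss,
    duplicate_rate = duplicate_rate, seed = as.integer(seed)),
    class = "srs_scenario")
}

# substream seeds: deterministic offsets from the master seed, so adding
# a component does not reshuffle the others; kept under 2^31
sub_seed <- function(scenario, k) {
  (scenario$seed %% 1000000L) * 1000L + k
}

#' Draw Weibull onset times by inverse CDF
#'
#' `scale * (-log(1 - u))^(1/shape)` over a seeded uniform stream. With
#' `floor_half_day = TRUE`, draws below half a day are set to 0.5,
#' mirroring the same-day reporting convention of the ingestion rules.
#'
#' @param shape,scale Weibull parameters, both positive (scale in
#'   days).
#' @param n sample size.
#' @param seed integer seed.
#' @param floor_half_day apply the 0.5-day floor.
#' @return numeric vector of length `n`.
#' @export
simulate_onset_sample <- function(shape, scale, n, seed = NULL,
                                  floor_half_day = FALSE) {
  if (shape <= 0 || scale <= 0) stop("shape and scale must be positive")
  if (n < 1) stop("n must be at least 1")
  if (!is.null(seed)) set.seed(seed)
  u <- stats::runif(n)
  t <- scale * (-log(1 - u))^(1 / shape)
  if (floor_half_day) t <- pmax(t, 0.5)
  t
}

#' Simulate the clean report-level dataset of a scenario
#'
#' The analysis-ready truth before any defect is planted: one row per
#' report with its suspect drug, age, sex, case status, onset interval
#' and calendar dates. [simulate_reports()] degrades this into the raw
#' dialect files.
#'
#' @param scenario an `srs_scenario`.
#' @return data.frame `case_id`, `drug_name`, `age_years`, `sex`,
#'   `is_case`, `onset_days`, `start_date`, `onset_date` (Date
#'   columns).
#' @export
simulate_case_data <- function(scenario) {
  stopifnot(inherits(scenario, "srs_scenario"))
  n <- scenario$n_reports
  cat_names <- scenario$drug_catalog$drug_name
  prob <- scenario$drug_catalog$weight / sum(scenario$drug_catalog$weight)

  set.seed(sub_seed(scenario, 1L))
  drug <- sample(cat_names, n, replace = TRUE, prob = prob)
  set.seed(sub_seed(scenario, 2L))
  age <- pmin(pmax(stats::rnorm(n, scenario$age_mean, scenario$age_sd),
                   0), 100)
  set.seed(sub_seed(scenario, 3L))
  female <- stats::rbinom(n, 1, scenario$sex_ratio)

  eff <- rep(1, n)
  hit <- drug %in% names(scenario$drug_effects)
  eff[hit] <- unname(scenario$drug_effects[drug[hit]])
  lp <- stats::qlogis(scenario$target_ae_base_rate) + log(eff) +
    scenario$age_effect * (age - scenario$age_mean) +
    scenario$sex_effect * female
  set.seed(sub_seed(scenario, 4L))
  is_case <- stats::rbinom(n, 1, stats::plogis(lp)) == 1

  om <- scenario$onset_models
  idx <- match(drug, om$drug_name)
  idx[is.na(idx)] <- match(".default", om$drug_name)
  set.seed(sub_seed(scenario, 5L))
  u <- stats::runif(n)
  onset <- om$scale[idx] * (-log(1 - u))^(1 / om$shape[idx])

  set.seed(sub_seed(scenario, 6L))
  start <- as.Date("2015-01-01") +
    sample.int(3287L, n, replace = TRUE) - 1L
  data.frame(
    case_id = sprintf("C%07d", seq_len(n)), drug_name = drug,
    age_years = age, sex = ifelse(female == 1, "female", "male"),
    is_case = is_case, onset_days = onset, start_date = start,
    onset_date = start + floor(onset), stringsAsFactors = FALSE)
}

format_partial <- function(dates, precision) {
  full <- format(dates, "%Y%m%d")
  out <- full
  out[precision == "year_month"] <- format(dates[precision ==
                                                   "year_month"], "%Y%m")
  out[precision == "year"] <- format(dates[precision == "year"], "%Y")
  out[is.na(dates)] <- ""
  out
}

#' Emit raw FAERS- and JADER-dialect files plus ground truth
#'
#' Degrades the clean data of [simulate_case_data()] into realistic raw
#' tables: fields blanked at the scenario's missingness rates, date
#' precision degraded to year-month or year, and duplicate case
#' versions planted (an earlier FAERS version / an exact duplicate
#' JADER row). The same population is written in both dialects so the
#' two readers can be round-trip-checked against one another, along
#' with a ground-truth table recording every planted defect. Output is
#' byte-reproducible for a fixed scenario seed.
#'
#' @param scenario an `srs_scenario`.
#' @param dir output directory; `faers/` and `jader/` subdirectories
#'   and `ground_truth.tsv` are created inside it.
#' @return invisibly, a list with the ground-truth data.frame and the
#'   file paths.
#' @export
simulate_reports <- function(scenario, dir) {
  stopifnot(inherits(scenario, "srs_scenario"))
  truth <- simulate_case_data(scenario)
  n <- nrow(truth)
  ms <- scenario$missingness
  pl <- scenario$precision_loss

  set.seed(sub_seed(scenario, 7L))
  miss_age <- stats::runif(n) < ms["age"]
  miss_sex <- stats::runif(n) < ms["sex"]
  miss_start <- stats::runif(n) < ms["start_date"]
  miss_onset <- stats::runif(n) < ms["onset_date"]
  prec_draw <- function() {
    u <- stats::runif(n)
    ifelse(u < pl["year"], "year",
           ifelse(u < pl["year"] + pl["year_month"], "year_month",
                  "full"))
  }
  start_prec <- prec_draw()
  onset_prec <- prec_draw()
  set.seed(sub_seed(scenario, 8L))
  dup <- stats::runif(n) < scenario$duplicate_rate

  truth$missing_age <- miss_age
  truth$missing_sex <- miss_sex
  truth$missing_start <- miss_start
  truth$missing_onset <- miss_onset
  truth$start_precision <- start_prec
  truth$onset_precision <- onset_prec
  truth$dup_planted <- dup

  start_str <- format_partial(truth$start_date, start_prec)
  onset_str <- format_partial(truth$onset_date, onset_prec)
  start_str[miss_start] <- ""
  onset_str[miss_onset] <- ""
  age_str <- sprintf("%.0f", truth$age_years)
  age_str[miss_age] <- ""
  sex_code <- ifelse(truth$sex == "female", "F", "M")
  sex_code[miss_sex] <- ""
  pts <- taste_disorder_pts()
  set.seed(sub_seed(scenario, 9L))
  pt_code <- ifelse(truth$is_case,
                    pts[sample.int(length(pts), n, replace = TRUE)],
                    10019211L)   # filler PT for non-cases (headache)
  pt_name <- names(pts)[match(pt_code, pts)]
  pt_name[is.na(pt_name)] <- "headache"

  dir.create(file.path(dir, "faers"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(dir, "jader"), recursive = TRUE,
             showWarnings = FALSE)

  # --- FAERS dialect (version 1 = latest; planted dups get version 0,
  # with the defect fields of the later submission still blank)
  demo <- data.frame(caseid = truth$case_id, caseversion = 1L,
                     age = age_str, age_cod = ifelse(age_str == "", "",
                                                     "YR"),
                     sex = sex_code, occp_cod = "CN",
                     event_dt = onset_str, stringsAsFactors = FALSE)
  drug <- data.frame(caseid = truth$case_id, caseversion = 1L,
                     drug_seq = 1L, role_cod = "PS",
                     drugname = truth$drug_name, stringsAsFactors = FALSE)
  reac <- data.frame(caseid = truth$case_id, caseversion = 1L,
                     pt_code = pt_code, pt = pt_name,
                     stringsAsFactors = FALSE)
  ther <- data.frame(caseid = truth$case_id, caseversion = 1L,
                     dsg_drug_seq = 1L, start_dt = start_str,
                     stringsAsFactors = FALSE)
  if (any(dup)) {
    d0 <- demo[dup, ]; d0$caseversion <- 0L; d0$age <- ""
    d0$age_cod <- ""
    demo <- rbind(d0, demo)
    g0 <- drug[dup, ]; g0$caseversion <- 0L
    drug <- rbind(g0, drug)
    r0 <- reac[dup, ]; r0$caseversion <- 0L
    reac <- rbind(r0, reac)
    t0 <- ther[dup, ]; t0$caseversion <- 0L
    ther <- rbind(t0, ther)
  }
  wtab <- function(df, path, sep) {
    utils::write.table(df, path, sep = sep, quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
  }
  fa <- file.path(dir, "faers", c("DEMO.txt", "DRUG.txt", "REAC.txt",
                                  "THER.txt"))
  wtab(demo, fa[1], "$"); wtab(drug, fa[2], "$")
  wtab(reac, fa[3], "$"); wtab(ther, fa[4], "$")

  # --- JADER dialect (same population; decade-coded ages, Japanese
  # labels, duplicates as repeated identical rows)
  decade_txt <- function(a) {
    ifelse(a < 10, "10歳未満",
           ifelse(a >= 100, "100歳以上",
                  paste0(pmin(floor(a / 10) * 10, 90), "歳代")))
  }
  jage <- decade_txt(truth$age_years)
  jage[miss_age] <- "不明"
  jsex <- ifelse(truth$sex == "female", "女性",
                 "男性")
  jsex[miss_sex] <- "不明"
  jdemo <- data.frame(id = truth$case_id, sex = jsex, age = jage,
                      occ = "医師", stringsAsFactors = FALSE)
  names(jdemo) <- c("識別番号", "性別",
                    "年齢",
                    "報告者職種")
  jdrug <- data.frame(id = truth$case_id, nm = truth$drug_name,
                      role = "被疑薬", st = start_str,
                      stringsAsFactors = FALSE)
  names(jdrug) <- c("識別番号",
                    "医薬品（一般名）",
                    "医薬品の関与",
                    "投与開始日")
  jreac <- data.frame(id = truth$case_id, code = pt_code, nm = pt_name,
                      dt = onset_str, stringsAsFactors = FALSE)
  names(jreac) <- c("識別番号", "PTコード",
                    "有害事象",
                    "有害事象の発現日")
  jhist <- data.frame(id = truth$case_id,
                      dz = "なし", stringsAsFactors = FALSE)
  names(jhist) <- c("識別番号",
                    "原疾患等")
  if (any(dup)) {
    jdemo <- rbind(jdemo[dup, ], jdemo)
    jdrug <- rbind(jdrug[dup, ], jdrug)
    jreac <- rbind(jreac[dup, ], jreac)
  }
  ja <- file.path(dir, "jader", c("demo.csv", "drug.csv", "reac.csv",
                                  "hist.csv"))
  wtab(jdemo, ja[1], ","); wtab(jdrug, ja[2], ",")
  wtab(jreac, ja[3], ","); wtab(jhist, ja[4], ",")

  gt_path <- file.path(dir, "ground_truth.tsv")
  gt <- truth
  gt$start_date <- format(gt$start_date, "%Y-%m-%d")
  gt$onset_date <- format(gt$onset_date, "%Y-%m-%d")
  utils::write.table(gt, gt_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(list(truth = truth, faers_paths = fa, jader_paths = ja,
                 ground_truth_path = gt_path))
}
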