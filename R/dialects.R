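#' Dialect configuration for FAERS-style quarterly ASCII tables
#'
#' Describes how to read the dollar-sign-delimited DEMO/DRUG/REAC/THER
#' tables: which physical column holds each logical field, how drug role
#' codes map onto the common role enum, and how age units convert to
#' years. Column names changed across FAERS eras; pass overrides to adapt
#' a quarter whose headers differ.
#'
#' @param ... named overrides for any element of the default list.
#' @return a list of class `srs_dialect`.
#' @export
faers_dialect <- function(...) {
  d <- list(
    source = "FAERS",
    sep = "$",
    demo = c(case_id = "caseid", version = "caseversion", age = "age",
             age_unit = "age_cod", sex = "sex", occupation = "occp_cod",
             event_date = "event_dt"),
    drug = c(case_id = "caseid", version = "caseversion",
             drug_seq = "drug_seq", role = "role_cod",
             drug_name = "drugname"),
    reac = c(case_id = "caseid", version = "caseversion",
             pt_code = "pt_code", pt_name = "pt"),
    ther = c(case_id = "caseid", version = "caseversion",
             drug_seq = "dsg_drug_seq", start_date = "start_dt"),
    role_map = c(PS = "primary_suspect", SS = "suspect", C = "concomitant",
                 I = "interacting"),
    accepted_roles = "primary_suspect",
    # years per one unit of age_cod
    age_units = c(YR = 1, DEC = 10, MON = 1 / 12, WK = 7 / 365.25,
                  DY = 1 / 365.25, HR = 1 / 8766),
    sex_map = c(M = "male", F = "female"),
    missing_markers = c("", "NA", "UNK", "unknown")
  )
  utils::modifyList(d, list(...))
}

#' Dialect configuration for JADER-style CSV tables
#'
#' JADER ships comma-separated tables with Japanese headers; ages arrive
#' as decade buckets ("60歳代"), sex and roles as Japanese labels, and text
#' mixes full- and half-width characters. The dialect maps headers to the
#' common logical fields, decade buckets to midpoint ages in years, and
#' Japanese role labels to the role enum.
#'
#' @param ... named overrides for any element of the default list.
#' @return a list of class `srs_dialect`.
#' @export
jader_dialect <- function(...) {
  decades <- c(5, seq(15, 95, by = 10), 100)
  names(decades) <- c("10歳未満",
                      paste0(seq(10, 90, by = 10), "歳代"),
                      "100歳以上")
  d <- list(
    source = "JADER",
    sep = ",",
    demo = c(case_id = "識別番号", sex = "性別",
             age = "年齢",
             occupation = "報告者職種"),
    drug = c(case_id = "識別番号",
             drug_name = "医薬品（一般名）",
             role = "医薬品の関与",
             start_date = "投与開始日"),
    reac = c(case_id = "識別番号",
             pt_code = "PTコード",
             pt_name = "有害事象",
             onset_date = "有害事象の発現日"),
    hist = c(case_id = "識別番号",
             disease = "原疾患等"),
    role_map = c("被疑薬" = "suspect",
                 "併用薬" = "concomitant",
                 "相互作用" = "interacting"),
    accepted_roles = "suspect",
    age_decades = decades,
    sex_map = c("男性" = "male", "女性" = "female"),
    missing_markers = c("", "NA", "不明", "unknown")
  )
  utils::modifyList(d, list(...))
}

#' MedDRA preferred-term codes defining the taste-disorder case
#'
#' The four preferred terms whose union defines a taste-disorder case:
#' taste disorder (10082490), dysgeusia (10013911), hypogeusia (10020989)
#' and ageusia (10001480).
#'
#' @return named integer vector of PT codes.
#' @export
taste_disorder_pts <- function() {
  c(taste_disorder = 10082490L, dysgeusia = 10013911L,
    hypogeusia = 10020989L, ageusia = 10001480L)
}
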