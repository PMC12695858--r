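#' Normalize a drug name for matching across reports
#'
#' Case-folds, trims, collapses internal whitespace and transliterates
#' full-width (zenkaku) ASCII to half-width so that variants of the same
#' label used across FAERS and JADER map to one key. Salt forms (e.g.
#' "sunitinib malate") remain distinct from the parent name, matching the
#' way SRS signal tables list drugs.
#'
#' @param x character vector of raw drug names.
#' @return character vector of normalized names.
#' @examples
#' normalize_drug_name(c("  Clarithromycin ", "ＣLARITHROMYCIN"))
#' @export
normalize_drug_name <- function(x) {
  x <- zenkaku_to_hankaku(as.character(x))
  x <- tolower(trimws(x))
  gsub("[[:space:]]+", " ", x)
}

#' Transliterate full-width characters to half-width
#'
#' Maps the full-width ASCII block (U+FF01..U+FF5E) onto plain ASCII and
#' the ideographic space (U+3000) onto a space. Other characters pass
#' through unchanged. JADER free-text fields mix the two widths freely;
#' this makes string comparison deterministic.
#'
#' @param x character vector.
#' @return character vector with full-width ASCII replaced.
#' @export
zenkaku_to_hankaku <- function(x) {
  vapply(as.character(x), function(s) {
    if (is.na(s)) return(NA_character_)
    cp <- utf8ToInt(s)
    wide <- cp >= 0xFF01L & cp <= 0xFF5EL
    cp[wide] <- cp[wide] - 0xFEE0L
    cp[cp == 0x3000L] <- 0x20L
    intToUtf8(cp)
  }, character(1), USE.NAMES = FALSE)
}
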