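# Variable recoding: outcome classification, media composite, education and
# wealth collapsing, and district-level community aggregation.

#' Controlled vocabularies for contraceptive method codes
#'
#' Modern methods: female/male sterilization, IUD, injectables, implants,
#' pill, male/female condom, emergency contraception and other modern
#' methods. Traditional methods: rhythm, withdrawal, lactational amenorrhea
#' and other traditional methods.
#'
#' @export
modern_method_codes <- c(
  "female sterilization", "male sterilization", "iud", "injectables",
  "implants", "pill", "male condom", "female condom",
  "emergency contraception", "other modern"
)

#' @rdname modern_method_codes
#' @export
traditional_method_codes <- c(
  "rhythm", "withdrawal", "lactational amenorrhea", "other traditional"
)

#' Classify a contraceptive method code as modern or traditional
#'
#' @param method_code character vector of method labels (case-insensitive).
#' @return character vector, each element \code{"modern"} or
#'   \code{"traditional"}.
#' @examples
#' classify_method("injectables")   # "modern"
#' classify_method("withdrawal")    # "traditional"
#' @export
classify_method <- function(method_code) {
  code <- tolower(trimws(as.character(method_code)))
  out <- rep(NA_character_, length(code))
  out[code %in% modern_method_codes] <- "modern"
  out[code %in% traditional_method_codes] <- "traditional"
  bad <- !is.na(code) & is.na(out)
  if (any(bad)) {
    stop(sprintf(
      "unknown contraceptive method code(s): %s",
      paste(unique(code[bad]), collapse = ", ")
    ), call. = FALSE)
  }
  out
}

#' Media-exposure composite from three frequency items
#'
#' Each of the three media items (newspaper/magazine, radio, television) is
#' coded 0 = not at all, 1 = less than once a week, 2 = at least once a
#' week. Items are first dichotomised to access (1-2) vs no access (0); the
#' sum of the three access indicators (0-3) is then classed as
#' 0 = low, 1 = medium, 2-3 = high.
#'
#' @param items numeric matrix/data.frame with 3 columns (or a length-3
#'   vector for one woman), codes in \code{{0, 1, 2}}.
#' @return factor with levels \code{low < medium < high}.
#' @examples
#' media_composite(c(0, 0, 0))  # low
#' media_composite(c(2, 0, 0))  # medium
#' media_composite(c(1, 1, 2))  # high
#' @export
media_composite <- function(items) {
  if (is.null(dim(items)) && length(items) != 3L) {
    stop("media_composite needs exactly three items", call. = FALSE)
  }
  m <- if (is.null(dim(items))) matrix(items, ncol = 3L) else as.matrix(items)
  if (ncol(m) != 3L) stop("media_composite needs exactly three items", call. = FALSE)
  ok <- is.na(m) | m %in% c(0, 1, 2)
  if (!all(ok)) {
    stop(sprintf("media item codes must be 0, 1 or 2; got %s",
                 paste(unique(m[!ok]), collapse = ", ")), call. = FALSE)
  }
  s <- rowSums(m >= 1)
  lab <- rep(NA_character_, nrow(m))
  lab[s == 0] <- "low"
  lab[s == 1] <- "medium"
  lab[s >= 2] <- "high"
  factor(lab, levels = c("low", "medium", "high"))
}

#' Collapse raw education to the three analysis categories
#'
#' Secondary and higher are combined into \code{secondary+} because of the
#' small numbers in the higher category.
#'
#' @param education_raw character/factor in
#'   \code{{none, primary, secondary, higher}}.
#' @return factor with levels \code{none, primary, secondary+}.
#' @export
recode_education <- function(education_raw) {
  x <- as.character(education_raw)
  bad <- !is.na(x) & !x %in% c("none", "primary", "secondary", "higher")
  if (any(bad)) stop("unknown education category: ", paste(unique(x[bad]), collapse = ", "), call. = FALSE)
  x[x %in% c("secondary", "higher")] <- "secondary+"
  factor(x, levels = c("none", "primary", "secondary+"))
}

#' Collapse raw wealth quintiles to poor / middle / rich
#'
#' @param wealth_raw character/factor in
#'   \code{{poorest, poorer, middle, richer, richest}}.
#' @return factor with levels \code{poor, middle, rich}.
#' @export
recode_wealth <- function(wealth_raw) {
  x <- as.character(wealth_raw)
  bad <- !is.na(x) & !x %in% c("poorest", "poorer", "middle", "richer", "richest")
  if (any(bad)) stop("unknown wealth category: ", paste(unique(x[bad]), collapse = ", "), call. = FALSE)
  x[x %in% c("poorest", "poorer")] <- "poor"
  x[x %in% c("richer", "richest")] <- "rich"
  factor(x, levels = c("poor", "middle", "rich"))
}

#' Apply every individual-level recode to a women data frame
#'
#' Adds \code{education}, \code{wealth}, \code{media_exposure} and
#' \code{outcome_modern} (0/1, derived from \code{method_code} where
#' available, otherwise taken from a pre-existing \code{outcome} column).
#' Rows without a usable method (non-users) get \code{NA}.
#'
#' @param records data.frame of woman records (see
#'   \code{\link{simulate_women}} for the column contract).
#' @return the input data.frame with the coded columns appended.
#' @export
code_women <- function(records) {
  stopifnot(is.data.frame(records))
  out <- records
  out$education <- recode_education(records$education_raw)
  out$wealth <- recode_wealth(records$wealth_raw)
  out$media_exposure <- media_composite(
    records[, c("media_newspaper", "media_radio", "media_tv")]
  )
  if ("method_code" %in% names(records)) {
    has_code <- !is.na(records$method_code)
    cls <- rep(NA_character_, nrow(records))
    cls[has_code] <- classify_method(records$method_code[has_code])
    out$outcome_modern <- ifelse(is.na(cls), NA_integer_,
                                 as.integer(cls == "modern"))
  } else if ("outcome" %in% names(records)) {
    out$outcome_modern <- as.integer(records$outcome)
  } else {
    stop("records need either a method_code or an outcome column", call. = FALSE)
  }
  out
}

#' District-level community aggregates with median-split dichotomies
#'
#' Per district this computes the share of young women (15-29), the share in
#' middle/rich wealth households, the share exposed to family-planning
#' media messages, the share with at least secondary education and the
#' share who visited a health facility in the last 12 months, plus modern
#' prevalence among users. Each proportion is dichotomised at the median of
#' the district-level distribution, with ties (>= median) labelled
#' \code{high}; majority residence gives \code{residence_majority}.
#'
#' @param coded data.frame from \code{\link{code_women}} with a
#'   \code{district_id} column.
#' @param fp_media_col column holding the family-planning media indicator
#'   (\code{"no"}/\code{"yes"}); if absent, any media exposure above
#'   \code{low} is used instead.
#' @return data.frame with one row per district: proportions, dichotomised
#'   labels, \code{prevalence_modern} (percent modern among the district's
#'   users) and \code{share_national_modern_pct} (the district's share of
#'   all modern users, the map denominator).
#' @export
aggregate_community <- function(coded, fp_media_col = "fp_media_message") {
  stopifnot(is.data.frame(coded))
  if (nrow(coded) == 0L) stop("cannot aggregate an empty district set", call. = FALSE)
  if (!"district_id" %in% names(coded)) stop("records need a district_id column", call. = FALSE)

  fp_any <- if (fp_media_col %in% names(coded)) {
    as.character(coded[[fp_media_col]]) == "yes"
  } else {
    coded$media_exposure != "low"
  }
  young <- coded$age_group %in% c("15-19", "20-29")
  ses_high <- coded$wealth %in% c("middle", "rich")
  educ_high <- coded$education == "secondary+"
  visited <- as.character(coded$visited_facility_12m) == "yes"
  rural <- as.character(coded$residence) == "rural"

  d <- split(seq_len(nrow(coded)), as.character(coded$district_id))
  prop <- function(x, idx) mean(x[idx], na.rm = TRUE)
  res <- data.frame(
    district_id = names(d),
    n_women = vapply(d, length, integer(1)),
    prevalence_modern = vapply(d, function(i)
      100 * mean(coded$outcome_modern[i], na.rm = TRUE), numeric(1)),
    prop_young = vapply(d, prop, numeric(1), x = young),
    prop_ses_high = vapply(d, prop, numeric(1), x = ses_high),
    prop_media_fp = vapply(d, prop, numeric(1), x = fp_any),
    prop_educ_high = vapply(d, prop, numeric(1), x = educ_high),
    prop_facility = vapply(d, prop, numeric(1), x = visited),
    prop_rural = vapply(d, prop, numeric(1), x = rural),
    stringsAsFactors = FALSE, row.names = NULL
  )
  res$prevalence_modern[is.nan(res$prevalence_modern)] <- NA_real_
  # district share of all modern users (the denominator used by the
  # national district map, where the largest district holds a few percent)
  modern_d <- vapply(d, function(i)
    sum(coded$outcome_modern[i], na.rm = TRUE), numeric(1))
  tot <- sum(modern_d)
  res$share_national_modern_pct <- if (tot > 0) 100 * modern_d / tot else
    rep(NA_real_, length(d))

  dich <- function(p, labels = c("low", "high")) {
    factor(ifelse(p >= median(p), labels[2], labels[1]), levels = labels)
  }
  res$community_age <- dich(res$prop_young, c("old", "young"))
  res$community_age <- factor(res$community_age, levels = c("young", "old"))
  res$community_ses <- dich(res$prop_ses_high)
  res$community_media_fp <- dich(res$prop_media_fp)
  res$community_education <- dich(res$prop_educ_high)
  res$community_facility_access <- dich(res$prop_facility)
  res$residence_majority <- factor(
    ifelse(res$prop_rural > 0.5, "rural", "urban"), levels = c("urban", "rural")
  )
  res
}

#' Attach district-level community labels back onto women records
#'
#' @param coded data.frame from \code{\link{code_women}}.
#' @param summaries data.frame from \code{\link{aggregate_community}}.
#' @return \code{coded} with the community factor columns appended.
#' @export
add_community_vars <- function(coded, summaries) {
  idx <- match(as.character(coded$district_id), summaries$district_id)
  if (anyNA(idx)) stop("some districts are missing from the community summaries", call. = FALSE)
  for (col in c("community_age", "community_ses", "community_media_fp",
                "community_education", "community_facility_access",
                "residence_majority")) {
    coded[[col]] <- summaries[[col]][idx]
  }
  coded
}
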