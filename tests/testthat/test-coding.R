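test_that("method classification follows the modern/traditional vocabularies", {
  expect_equal(classify_method("injectables"), "modern")
  expect_equal(classify_method("pill"), "modern")
  expect_equal(classify_method("withdrawal"), "traditional")
  expect_equal(classify_method("rhythm"), "traditional")
  expect_equal(classify_method(c("IUD", "lactational amenorrhea")),
               c("modern", "traditional"))
  expect_error(classify_method("abstinence"), "abstinence")
  expect_true(all(classify_method(modern_method_codes) == "modern"))
  expect_true(all(classify_method(traditional_method_codes) == "traditional"))
})

test_that("media composite: dichotomise items, sum, median-rule classes", {
  expect_equal(as.character(media_composite(c(0, 0, 0))), "low")
  expect_equal(as.character(media_composite(c(2, 0, 0))), "medium")
  expect_equal(as.character(media_composite(c(1, 1, 2))), "high")
  expect_equal(as.character(media_composite(c(0, 2, 2))), "high")
  m <- rbind(c(0, 0, 0), c(0, 1, 0), c(2, 2, 0), c(1, 1, 1))
  expect_equal(as.character(media_composite(m)),
               c("low", "medium", "high", "high"))
  expect_error(media_composite(c(3, 0, 0)), "0, 1 or 2")
  expect_error(media_composite(c(0, 0)), "three items")
})

test_that("education and wealth collapse per the stated rules", {
  expect_equal(as.character(recode_education(c("none", "primary", "secondary",
                                               "higher"))),
               c("none", "primary", "secondary+", "secondary+"))
  expect_equal(as.character(recode_wealth(c("poorest", "poorer", "middle",
                                            "richer", "richest"))),
               c("poor", "poor", "middle", "rich", "rich"))
  expect_error(recode_education("kindergarten"), "unknown education")
  expect_error(recode_wealth("destitute"), "unknown wealth")
})

test_that("recoding is idempotent and survives a CSV round trip", {
  w <- apply_sample_filter(simulate_women(small_config(seed = 21)))
  cd <- code_women(w)
  # education=secondary+ iff raw in {secondary, higher}; wealth likewise
  expect_identical(cd$education == "secondary+",
                   cd$education_raw %in% c("secondary", "higher"))
  expect_identical(cd$wealth == "poor",
                   cd$wealth_raw %in% c("poorest", "poorer"))
  expect_identical(cd$wealth == "rich",
                   cd$wealth_raw %in% c("richer", "richest"))
  cd2 <- code_women(cd)   # idempotent on already-coded records
  expect_equal(cd2$education, cd$education)
  expect_equal(cd2$outcome_modern, cd$outcome_modern)

  tmp <- tempfile(fileext = ".csv")
  on.exit(unlink(tmp))
  write.csv(cd, tmp, row.names = FALSE, na = "NA")
  back <- code_women(read.csv(tmp, stringsAsFactors = FALSE))
  for (col in c("education", "wealth", "media_exposure")) {
    expect_equal(as.character(back[[col]]), as.character(cd[[col]]), label = col)
  }
  expect_equal(back$outcome_modern, cd$outcome_modern)
})

test_that("community aggregation dichotomises at the district median", {
  base <- data.frame(
    district_id = rep(c("A", "B"), each = 10),
    age_group = factor(rep(c("20-29", "40+"), c(2, 8))[c(1:10, 1:10)],
                       levels = c("15-19", "20-29", "30-39", "40+")),
    wealth = factor("middle", levels = c("poor", "middle", "rich")),
    education = factor("primary", levels = c("none", "primary", "secondary+")),
    media_exposure = factor("low", levels = c("low", "medium", "high")),
    visited_facility_12m = "no",
    residence = rep(c("urban", "rural"), each = 10),
    fp_media_message = c(rep(c("yes", "no"), c(2, 8)),
                         rep(c("yes", "no"), c(8, 2))),
    outcome_modern = rep(c(0L, 1L), 10),
    stringsAsFactors = FALSE
  )
  cs <- aggregate_community(base)
  # fp media proportions 0.2 vs 0.8 -> low, high however the cut falls
  expect_equal(as.character(cs$community_media_fp[cs$district_id == "A"]), "low")
  expect_equal(as.character(cs$community_media_fp[cs$district_id == "B"]), "high")
  expect_equal(as.character(cs$residence_majority), c("urban", "rural"))
  # identical proportions tie at the median -> all high
  expect_equal(as.character(cs$community_ses), c("high", "high"))
  expect_equal(as.character(cs$community_education), c("high", "high"))
  # single district: its proportion is the median -> high
  one <- aggregate_community(base[base$district_id == "A", ])
  expect_equal(as.character(one$community_media_fp), "high")
  expect_error(aggregate_community(base[0, ]), "empty")
})

test_that("every high district proportion is >= every low district proportion", {
  w <- apply_sample_filter(simulate_women(small_config(seed = 31)))
  cs <- aggregate_community(code_women(w))
  checks <- list(c("prop_young", "community_age", "young"),
                 c("prop_ses_high", "community_ses", "high"),
                 c("prop_media_fp", "community_media_fp", "high"),
                 c("prop_educ_high", "community_education", "high"),
                 c("prop_facility", "community_facility_access", "high"))
  for (ch in checks) {
    hi <- cs[[ch[1]]][cs[[ch[2]]] == ch[3]]
    lo <- cs[[ch[1]]][cs[[ch[2]]] != ch[3]]
    if (length(hi) && length(lo)) expect_gte(min(hi), max(lo))
  }
  expect_true(all(cs$prevalence_modern >= 0 & cs$prevalence_modern <= 100))
})
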