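# Synthetic women-level records with the hierarchical structure the
# multilevel model assumes: district random intercepts on the log-odds
# scale, independently drawn categorical covariates, and a Bernoulli
# outcome from the inverse-logit linear predictor.

sample_cat <- function(n, probs) {
  factor(sample(names(probs), n, replace = TRUE, prob = probs),
         levels = names(probs))
}

#' Simulate women-level survey records
#'
#' For each district j a random intercept u_j ~ N(0, sigma_u2) is drawn;
#' covariates are drawn independently per woman from the configured
#' margins; the modern-vs-traditional outcome is Bernoulli with
#' probability \code{plogis(beta0 + sum(beta * x) + u_j)}. Use of any
#' method and current pregnancy are independent flags so the published
#' sample-selection filter can be exercised; the outcome (and a concrete
#' method code consistent with it) is defined only for users.
#'
#' @param config an \code{\link{sim_config}} object.
#' @return data.frame with one row per woman; attributes \code{u} (the
#'   district intercepts) and \code{config}.
#' @export
simulate_women <- function(config) {
  stopifnot(inherits(config, "mcp_sim_config"))
  set.seed(derive_seed(config$seed, "women"))
  J <- config$n_districts
  npd <- config$women_per_district
  n_j <- if (length(npd) == 2L) {
    sample(seq(npd[1], npd[2]), J, replace = TRUE)
  } else rep(as.integer(npd), J)
  n <- sum(n_j)
  district <- rep(sprintf("D%03d", seq_len(J)), n_j)
  u <- rnorm(J, 0, sqrt(config$sigma_u2))

  m <- config$covariate_margins
  rec <- data.frame(
    woman_id = sprintf("W%06d", seq_len(n)),
    district_id = district,
    age_group = sample_cat(n, m$age_group),
    marital = sample_cat(n, m$marital),
    head_sex = sample_cat(n, m$head_sex),
    parity = sample_cat(n, m$parity),
    ever_terminated = sample_cat(n, m$ever_terminated),
    education_raw = sample_cat(n, m$education_raw),
    media_newspaper = as.integer(as.character(sample_cat(n, m$media_newspaper))),
    media_radio = as.integer(as.character(sample_cat(n, m$media_radio))),
    media_tv = as.integer(as.character(sample_cat(n, m$media_tv))),
    wanted_last = sample_cat(n, m$wanted_last),
    wealth_raw = sample_cat(n, m$wealth_raw),
    religion = sample_cat(n, m$religion),
    employed = sample_cat(n, m$employed),
    fp_media_message = sample_cat(n, m$fp_media_message),
    stringsAsFactors = FALSE
  )

  # residence is clustered by district (districts are predominantly urban
  # or rural, as in a two-stage design): each district gets a type, and
  # women take the district type with probability 0.9. The district-type
  # rate is chosen so the marginal rural share matches the margins.
  p_rural <- unname(m$residence["rural"])
  t_rural <- min(1, max(0, (p_rural - 0.1) / 0.8))
  dtype <- ifelse(runif(J) < t_rural, "rural", "urban")
  keep_type <- runif(n) < 0.9
  dt_w <- dtype[match(district, sprintf("D%03d", seq_len(J)))]
  rec$residence <- factor(
    ifelse(keep_type, dt_w, ifelse(dt_w == "rural", "urban", "rural")),
    levels = c("urban", "rural"))

  # facility visits are likewise a community attribute: districts carry a
  # true access propensity (logit-normal around the marginal rate, sd 0.5
  # on the log-odds scale), so the district-level high/low dichotomy
  # reflects a real contextual difference rather than sampling noise
  p_vis <- unname(m$visited_facility_12m["yes"])
  q_j <- plogis(qlogis(p_vis) + rnorm(J, 0, 0.5))
  rec$visited_facility_12m <- factor(
    ifelse(runif(n) < q_j[match(district, sprintf("D%03d", seq_len(J)))],
           "yes", "no"), levels = c("no", "yes"))

  # coded analysis categories the effects are keyed on
  coded <- data.frame(
    education = recode_education(rec$education_raw),
    wealth = recode_wealth(rec$wealth_raw),
    media_exposure = media_composite(
      rec[, c("media_newspaper", "media_radio", "media_tv")])
  )
  lp <- rep(config$beta0, n) + u[match(district, sprintf("D%03d", seq_len(J)))]
  for (v in names(config$betas)) {
    val <- if (v %in% names(coded)) coded[[v]] else rec[[v]]
    eff <- config$betas[[v]]
    hit <- match(as.character(val), names(eff))
    lp <- lp + ifelse(is.na(hit), 0, eff[hit])
  }

  # contextual (district-level) effects: median-split district share of
  # facility visits, acting on every woman in the district (an Eq.-style
  # community covariate, not an aggregate of the individual effect)
  cb <- config$community_betas %||% list()
  if (!is.null(cb$community_facility_access)) {
    share <- tapply(rec$visited_facility_12m == "yes", district, mean)
    high <- names(share)[share >= median(share)]
    eff <- cb$community_facility_access
    if (!is.null(eff["high"]) && !is.na(eff["high"])) {
      lp <- lp + ifelse(district %in% high, unname(eff["high"]), 0)
    }
  }

  rec$pregnant_now <- factor(ifelse(runif(n) < config$p_pregnant, "yes", "no"),
                             levels = c("no", "yes"))
  rec$used_any_method <- factor(ifelse(runif(n) < config$p_use, "yes", "no"),
                                levels = c("no", "yes"))
  outcome <- rbinom(n, 1L, plogis(lp))
  users <- rec$used_any_method == "yes"
  rec$outcome <- ifelse(users, outcome, NA_integer_)

  # a concrete method label consistent with the realized outcome
  modern_w <- c(0.45, 0.005, 0.04, 0.45, 0.20, 0.12, 0.10, 0.005, 0.02, 0.01)
  trad_w <- c(0.45, 0.40, 0.10, 0.05)
  rec$method_code <- NA_character_
  im <- which(users & outcome == 1L)
  it <- which(users & outcome == 0L)
  rec$method_code[im] <- sample(modern_method_codes, length(im),
                                replace = TRUE, prob = modern_w)
  rec$method_code[it] <- sample(traditional_method_codes, length(it),
                                replace = TRUE, prob = trad_w)

  attr(rec, "u") <- setNames(u, sprintf("D%03d", seq_len(J)))
  attr(rec, "config") <- config
  rec
}

#' Sample-selection filter: users of any method, not currently pregnant
#'
#' Mirrors the published screening flow: women not using any method to
#' prevent pregnancy are excluded first, then currently pregnant users.
#' Row order is preserved, and the exclusion accounting is attached so the
#' pipeline log can verify
#' \code{n_input - n_excluded_nonuser - n_excluded_pregnant == n_analytic}.
#'
#' @param records women data.frame carrying \code{used_any_method} and
#'   \code{pregnant_now}.
#' @return the retained rows, with an \code{accounting} attribute.
#' @export
apply_sample_filter <- function(records) {
  stopifnot(all(c("used_any_method", "pregnant_now") %in% names(records)))
  user <- as.character(records$used_any_method) == "yes"
  pregnant <- as.character(records$pregnant_now) == "yes"
  keep <- user & !pregnant
  out <- records[keep, , drop = FALSE]
  attr(out, "accounting") <- list(
    n_input = nrow(records),
    n_excluded_nonuser = sum(!user),
    n_excluded_pregnant = sum(user & pregnant),
    n_analytic = sum(keep)
  )
  out
}
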