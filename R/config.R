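# Simulation configuration: sampling design, covariate margins, effect
# sizes on the log-odds scale, and the toy-geography block.

#' Default covariate margins for the synthetic population
#'
#' Category probabilities per covariate, matching the background-
#' characteristics distribution of a 2016 Ugandan women's survey sample of
#' 9,238 users of any contraceptive method (counts normalised to
#' probabilities). The raw secondary/higher education split and the raw
#' wealth quintile split are not separately tabulated there and are fixed
#' at plausible shares; the three media items get per-item frequency
#' distributions whose composite roughly reproduces the published
#' low/medium/high mix.
#'
#' @return named list of named probability vectors.
#' @export
default_margins <- function() {
  n <- 9238
  list(
    age_group = c("15-19" = 675, "20-29" = 3859, "30-39" = 3043, "40+" = 1661) / n,
    marital = c(single = 979, married = 3547, living_together = 3204,
                previously_married = 1508) / n,
    head_sex = c(male = 6217, female = 3021) / n,
    parity = c("1" = 1850, "2" = 1376, "3" = 1275, "4+" = 4737) / n,
    ever_terminated = c(no = 7152, yes = 2086) / n,
    education_raw = c(none = 849, primary = 5355, secondary = 2427, higher = 607) / n,
    media_newspaper = c("0" = 0.55, "1" = 0.20, "2" = 0.25),
    media_radio = c("0" = 0.20, "1" = 0.25, "2" = 0.55),
    media_tv = c("0" = 0.60, "1" = 0.15, "2" = 0.25),
    wanted_last = c(wanted_then = 3432, wanted_later = 2129, wanted_no_more = 824) / 6385,
    wealth_raw = c(poorest = 1600, poorer = 1601, middle = 1768,
                   richer = 2134, richest = 2135) / n,
    religion = c(anglican = 3035, catholic = 3622, muslim = 1125, other = 1456) / n,
    employed = c(no = 1675, yes = 7563) / n,
    residence = c(urban = 2460, rural = 6778) / n,
    visited_facility_12m = c(no = 0.5, yes = 0.5),
    fp_media_message = c(no = 0.55, yes = 0.45)
  )
}

#' Default log-odds effects for the synthetic outcome model
#'
#' Effects are keyed by analysis (coded) covariate and category; categories
#' not listed have effect zero, as do entire covariates not listed. Only
#' covariates reported as associated with modern-method choice carry
#' nonzero defaults (marital status, household-head sex, pregnancy
#' termination, education, wealth, religion), plus the individual
#' facility-visit indicator whose district-level aggregate is the
#' community access variable. Signs follow the reported marginal effects;
#' magnitudes are roughly four times the reported probability-scale
#' effects (the logistic derivative at p = 1/2).
#'
#' @return named list: covariate -> named numeric vector of category
#'   log-odds offsets (reference categories implicitly zero).
#' @export
default_betas <- function() {
  list(
    marital = c(married = 0.40, living_together = 0.32),
    head_sex = c(female = -0.32),
    ever_terminated = c(yes = -0.18),
    education = c(primary = 0.24, "secondary+" = 0.26),
    wealth = c(middle = 0.16, rich = 0.17),
    religion = c(catholic = -0.09, muslim = -0.25, other = -0.17),
    visited_facility_12m = c(yes = -0.17)
  )
}

#' Default district-level (contextual) log-odds effects
#'
#' One contextual effect: living in a district with high (above-median)
#' community access to health facilities lowers the log-odds of modern
#' use, the direction reported for the community access variable. The
#' magnitude is a moderate contextual effect chosen so that the community
#' level genuinely carries signal at the default design size.
#'
#' @return named list keyed like \code{\link{default_betas}}.
#' @export
default_community_betas <- function() {
  list(community_facility_access = c(high = -0.35))
}

#' Default toy-geography block
#'
#' A planar road grid in kilometres with five road classes, health-facility
#' points (a configurable fraction deliberately placed beyond the snapping
#' tolerance), lake polygons acting as barriers, and a rectangular district
#' partition.
#'
#' @return list of geography settings.
#' @export
default_geography <- function() {
  list(
    nx = 8, ny = 8,            # grid nodes per side
    spacing_km = 12,           # node spacing
    n_facilities = 6,
    unlocated_fraction = 0,    # share of facilities placed off-network
    n_lakes = 1,
    speeds = default_speeds()
  )
}

# map raw -> analysis category distributions needed by the calibration
derived_margins <- function(margins) {
  m <- margins
  educ <- m$education_raw
  m$education <- c(
    none = unname(educ["none"]), primary = unname(educ["primary"]),
    "secondary+" = unname(educ["secondary"] + educ["higher"])
  )
  w <- m$wealth_raw
  m$wealth <- c(
    poor = unname(w["poorest"] + w["poorer"]), middle = unname(w["middle"]),
    rich = unname(w["richer"] + w["richest"])
  )
  # media composite distribution from independent items
  acc <- vapply(list(m$media_newspaper, m$media_radio, m$media_tv),
                function(p) unname(p["1"] + p["2"]), numeric(1))
  ps <- c(
    (1 - acc[1]) * (1 - acc[2]) * (1 - acc[3]),
    acc[1] * (1 - acc[2]) * (1 - acc[3]) + (1 - acc[1]) * acc[2] * (1 - acc[3]) +
      (1 - acc[1]) * (1 - acc[2]) * acc[3]
  )
  m$media_exposure <- c(low = ps[1], medium = ps[2], high = 1 - ps[1] - ps[2])
  m
}

#' Calibrate the intercept to a target marginal prevalence
#'
#' Computes the exact distribution of the covariate part of the linear
#' predictor (covariates are drawn independently, so the distribution is a
#' finite convolution of per-covariate atoms), integrates the logistic
#' probability over the Gaussian random intercept with Gauss-Hermite
#' quadrature, and solves for the intercept giving the target marginal
#' outcome prevalence. Fully deterministic.
#'
#' @param betas effect list as in \code{\link{default_betas}}.
#' @param margins margins list as in \code{\link{default_margins}}.
#' @param sigma_u2 random-intercept variance.
#' @param target target marginal prevalence in (0, 1).
#' @param community_betas contextual effects; a median-split district
#'   dichotomy puts half the population in each arm, so each contributes
#'   a two-atom term to the convolution.
#' @return the intercept (log-odds scale).
#' @export
calibrate_intercept <- function(betas, margins, sigma_u2, target,
                                community_betas = list()) {
  stopifnot(target > 0, target < 1, sigma_u2 >= 0)
  dm <- derived_margins(margins)
  atoms <- data.frame(val = 0, p = 1)
  for (cb in community_betas) {
    atoms <- data.frame(
      val = c(atoms$val, atoms$val + sum(cb)),
      p = c(atoms$p, atoms$p) / 2
    )
  }
  for (v in names(betas)) {
    if (!v %in% names(dm)) stop("no margins for covariate ", v, call. = FALSE)
    pr <- dm[[v]]
    eff <- setNames(rep(0, length(pr)), names(pr))
    eff[names(betas[[v]])] <- betas[[v]]
    grid <- expand.grid(a = seq_len(nrow(atoms)), b = seq_along(pr))
    atoms <- data.frame(
      val = atoms$val[grid$a] + eff[grid$b],
      p = atoms$p[grid$a] * pr[grid$b]
    )
    # merge duplicate values to keep the atom count bounded
    atoms <- aggregate(p ~ val, data = atoms, FUN = sum)
  }
  gh <- gh_rule(20L)
  u <- sqrt(2 * sigma_u2) * gh$x
  wu <- gh$w / sqrt(pi)
  prev <- function(b0) {
    pm <- plogis(outer(b0 + atoms$val, u, "+"))
    sum(atoms$p * (pm %*% wu)) - target
  }
  uniroot(prev, c(-15, 15), tol = 1e-10)$root
}

#' Build a validated simulation configuration
#'
#' @param n_districts number of districts (clusters); at least 2.
#' @param women_per_district women sampled per district (scalar, or a
#'   length-2 range sampled uniformly per district).
#' @param beta0 intercept log-odds; if \code{NULL}, calibrated with
#'   \code{\link{calibrate_intercept}} so the marginal modern share among
#'   users is \code{target_prevalence}.
#' @param betas log-odds effects (see \code{\link{default_betas}}).
#' @param community_betas log-odds effects of district-level (contextual)
#'   covariates, keyed like \code{betas}; currently supported:
#'   \code{community_facility_access} (the median-split district share of
#'   women who visited a facility). These act on every woman in the
#'   district, over and above her individual covariates.
#' @param sigma_u2 district random-intercept variance (>= 0).
#' @param covariate_margins category probabilities per covariate.
#' @param target_prevalence marginal modern prevalence used when
#'   \code{beta0} is NULL. Default 0.532, the published user share.
#' @param p_use probability a woman used any method (pre-filter).
#' @param p_pregnant probability a woman is currently pregnant.
#' @param seed master seed.
#' @param geography toy-geography block (see \code{\link{default_geography}}).
#' @return object of class \code{mcp_sim_config}.
#' @export
sim_config <- function(n_districts = 112, women_per_district = c(60, 270),
                       beta0 = NULL, betas = default_betas(),
                       community_betas = default_community_betas(),
                       sigma_u2 = 0.08,
                       covariate_margins = default_margins(),
                       target_prevalence = 0.532,
                       p_use = 0.5566, p_pregnant = 0.1034,
                       seed = 1L, geography = default_geography()) {
  if (n_districts < 2) stop("need at least 2 districts", call. = FALSE)
  if (sigma_u2 < 0) stop("sigma_u2 must be non-negative", call. = FALSE)
  if (!length(women_per_district) %in% 1:2 || any(women_per_district < 1)) {
    stop("women_per_district must be a positive scalar or range", call. = FALSE)
  }
  for (v in names(covariate_margins)) {
    p <- covariate_margins[[v]]
    if (any(p < 0) || abs(sum(p) - 1) > 1e-12) {
      stop(sprintf("margins for %s must be non-negative and sum to 1", v),
           call. = FALSE)
    }
  }
  extra <- setdiff(names(betas),
                   c(names(derived_margins(covariate_margins)), "media_exposure"))
  if (length(extra)) {
    stop("betas refer to covariates without margins: ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
  if (is.null(beta0)) {
    beta0 <- calibrate_intercept(betas, covariate_margins, sigma_u2,
                                 target_prevalence, community_betas)
  }
  structure(list(
    n_districts = as.integer(n_districts),
    women_per_district = women_per_district,
    beta0 = beta0, betas = betas, community_betas = community_betas,
    sigma_u2 = sigma_u2,
    covariate_margins = covariate_margins,
    p_use = p_use, p_pregnant = p_pregnant,
    seed = as.integer(seed), geography = geography
  ), class = "mcp_sim_config")
}

#' @export
print.mcp_sim_config <- function(x, ...) {
  cat("Synthetic survey configuration\n")
  cat(sprintf("  districts: %d, women/district: %s\n", x$n_districts,
              paste(x$women_per_district, collapse = "-")))
  cat(sprintf("  beta0 = %.4f, sigma_u2 = %.3f, seed = %d\n",
              x$beta0, x$sigma_u2, x$seed))
  cat(sprintf("  covariates with nonzero effects: %s\n",
              paste(names(x$betas), collapse = ", ")))
  invisible(x)
}
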