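# Random-intercept binary logistic regression fitted by maximising the
# marginal likelihood, with the cluster integral computed by adaptive
# Gauss-Hermite quadrature. The latent-variable ICC, AIC, likelihood-ratio
# tests and average marginal effects sit on top of the fit.

# cached Gauss-Hermite rule (weight exp(-x^2))
gh_cache <- new.env(parent = emptyenv())
gh_rule <- function(nq) {
  key <- as.character(nq)
  if (is.null(gh_cache[[key]])) {
    r <- pracma::gaussHermite(nq)
    gh_cache[[key]] <- list(x = r$x, w = r$w)
  }
  gh_cache[[key]]
}

# stable bernoulli log-likelihood contributions for linear predictor lp
bern_ll <- function(y, lp) {
  y * plogis(lp, log.p = TRUE) + (1 - y) * plogis(-lp, log.p = TRUE)
}

# Core AGQ evaluation. cl is an integer cluster index 1..J; returns the
# marginal log-likelihood and (optionally) its gradient in (beta, logsigma),
# with the adaptive centering (per-cluster mode and curvature) treated as
# fixed when differentiating.
agq_core <- function(beta, logsigma, y, X, cl, nq = 7L, adaptive = TRUE,
                     grad = FALSE) {
  n <- length(y)
  J <- max(cl)
  eta <- drop(X %*% beta)
  eta <- pmin(pmax(eta, -35), 35)
  sigma <- exp(logsigma)

  if (sigma < 1e-8) {
    ll <- sum(bern_ll(y, eta))
    if (!grad) return(list(ll = ll))
    return(list(ll = ll,
                grad = c(drop(crossprod(X, y - plogis(eta))), 0)))
  }

  if (adaptive) {
    # Newton for the per-cluster posterior mode of u_j (strictly concave)
    u <- rep(0, J)
    for (it in 1:50) {
      p <- plogis(eta + u[cl])
      g1 <- drop(rowsum(y - p, cl, reorder = TRUE)) - u / sigma^2
      h <- drop(rowsum(p * (1 - p), cl, reorder = TRUE)) + 1 / sigma^2
      step <- g1 / h
      step <- pmin(pmax(step, -4), 4)
      u <- u + step
      if (max(abs(step)) < 1e-10) break
    }
    p <- plogis(eta + u[cl])
    h <- drop(rowsum(p * (1 - p), cl, reorder = TRUE)) + 1 / sigma^2
    mu <- u
    tau <- 1 / sqrt(h)
  } else {
    mu <- rep(0, J)
    tau <- rep(sigma, J)
  }

  gh <- gh_rule(nq)
  K <- length(gh$x)
  lt <- matrix(0, J, K)
  umat <- matrix(0, J, K)
  for (k in seq_len(K)) {
    uk <- mu + sqrt(2) * tau * gh$x[k]
    umat[, k] <- uk
    cll <- drop(rowsum(bern_ll(y, eta + uk[cl]), cl, reorder = TRUE))
    lt[, k] <- cll + dnorm(uk, 0, sigma, log = TRUE) +
      log(gh$w[k]) + gh$x[k]^2 + 0.5 * log(2) + log(tau)
  }
  llj <- logsumexp_rows(lt)
  ll <- sum(llj)
  if (!grad) return(list(ll = ll))

  om <- exp(lt - llj)           # J x K posterior quadrature weights
  rho <- numeric(n)
  gls <- 0
  for (k in seq_len(K)) {
    uk <- umat[, k]
    pk <- plogis(eta + uk[cl])
    rho <- rho + om[cl, k] * (y - pk)
    gls <- gls + sum(om[, k] * (uk^2 / sigma^2 - 1))
  }
  list(ll = ll, grad = c(drop(crossprod(X, rho)), gls))
}

#' Marginal log-likelihood of the random-intercept logistic model
#'
#' For each cluster j the conditional Bernoulli likelihood is integrated
#' over the Gaussian random intercept u_j ~ N(0, sigma_u^2), by adaptive
#' Gauss-Hermite quadrature (nodes recentred at the per-cluster posterior
#' mode and rescaled by its curvature). With \code{adaptive = FALSE} a
#' plain prior-centred rule is used.
#'
#' @param beta fixed-effect vector matching the columns of \code{X}.
#' @param sigma_u random-intercept standard deviation (>= 0).
#' @param y 0/1 outcome vector.
#' @param X design matrix (including the intercept column).
#' @param cluster cluster identifier vector (any type; coerced to index).
#' @param nq number of quadrature nodes.
#' @param adaptive recentre/rescale nodes per cluster.
#' @return the marginal log-likelihood (a scalar).
#' @export
melogit_loglik <- function(beta, sigma_u, y, X, cluster, nq = 7L,
                           adaptive = TRUE) {
  stopifnot(sigma_u >= 0, length(y) == nrow(X))
  cl <- as.integer(factor(cluster))
  logsigma <- if (sigma_u <= 0) -Inf else log(sigma_u)
  if (sigma_u <= 0) {
    return(agq_core(beta, log(1e-12), y, X, cl, nq, adaptive)$ll)
  }
  agq_core(beta, logsigma, y, X, cl, nq, adaptive)$ll
}

#' Fit a random-intercept binary logistic model
#'
#' Maximises the adaptive-quadrature marginal likelihood over
#' \code{(beta, log sigma_u)} with L-BFGS-B, starting from the ordinary
#' logistic fit. Standard errors come from the inverse observed
#' information (finite differences of the analytic score); the variance CI
#' is computed on the log-sigma scale and back-transformed.
#'
#' @param formula model formula, e.g. \code{outcome_modern ~ marital + wealth}.
#' @param data data.frame containing outcome, covariates and the cluster id.
#' @param cluster name of the cluster (district/PSU) column.
#' @param nq quadrature nodes (default 7).
#' @param adaptive use adaptive quadrature (default TRUE).
#' @param start optional list with \code{beta} and \code{logsigma}.
#' @return object of class \code{melogit}: coefficients, \code{sigma_u2}
#'   with CI, loglik, AIC, ICC, Wald chi-square over the non-intercept
#'   fixed effects, vcov, convergence flag.
#' @export
melogit <- function(formula, data, cluster, nq = 7L, adaptive = TRUE,
                    start = NULL) {
  mf <- model.frame(formula, data = data, na.action = stats::na.omit)
  keep <- rownames(data) %in% rownames(mf)
  y <- model.response(mf)
  if (!all(y %in% c(0, 1))) stop("outcome must be binary 0/1", call. = FALSE)
  X <- model.matrix(attr(mf, "terms"), mf)
  clv <- data[[cluster]][keep]
  cl <- as.integer(factor(clv))
  if (max(cl) < 2L) stop("need at least 2 clusters", call. = FALSE)
  p <- ncol(X)

  if (is.null(start)) {
    g0 <- suppressWarnings(glm.fit(X, y, family = binomial()))
    beta0 <- coef(g0)
    if (anyNA(beta0)) {
      stop("fixed-effects design is rank deficient (possible separation); ",
           "aliased terms: ",
           paste(colnames(X)[is.na(beta0)], collapse = ", "), call. = FALSE)
    }
    start <- list(beta = beta0, logsigma = log(0.3))
  }
  par0 <- c(start$beta, start$logsigma)

  cache <- new.env(parent = emptyenv())
  evalc <- function(par) {
    if (!is.null(cache$par) && identical(par, cache$par)) return(cache$res)
    res <- agq_core(par[1:p], par[p + 1], y, X, cl, nq, adaptive, grad = TRUE)
    cache$par <- par
    cache$res <- res
    res
  }
  fn <- function(par) -evalc(par)$ll
  gr <- function(par) -evalc(par)$grad

  lower <- c(rep(-Inf, p), log(1e-5))
  upper <- c(rep(Inf, p), log(20))
  opt <- optim(par0, fn, gr, method = "L-BFGS-B", lower = lower,
               upper = upper, control = list(maxit = 500, factr = 1e7))
  if (opt$convergence != 0) {
    # one restart from the terminal point clears most line-search stalls
    opt2 <- optim(opt$par, fn, gr, method = "L-BFGS-B", lower = lower,
                  upper = upper, control = list(maxit = 500, factr = 1e8))
    if (opt2$value <= opt$value) opt <- opt2
  }
  if (opt$convergence != 0) {
    warning(sprintf("melogit did not fully converge (code %d): %s",
                    opt$convergence, opt$message %||% ""), call. = FALSE)
  }
  par <- unname(opt$par)
  beta <- setNames(par[1:p], colnames(X))
  logsigma <- par[p + 1]
  sigma_u2 <- exp(2 * logsigma)

  # observed information: central differences of the analytic score
  q <- p + 1L
  H <- matrix(0, q, q)
  hstep <- 1e-5 * pmax(1, abs(par))
  for (j in seq_len(q)) {
    e <- numeric(q); e[j] <- hstep[j]
    gp <- agq_core((par + e)[1:p], (par + e)[q], y, X, cl, nq, adaptive, TRUE)$grad
    gm <- agq_core((par - e)[1:p], (par - e)[q], y, X, cl, nq, adaptive, TRUE)$grad
    H[, j] <- -(gp - gm) / (2 * hstep[j])
  }
  H <- (H + t(H)) / 2
  V <- tryCatch(solve(H), error = function(e) pracma::pinv(H))
  dimnames(V) <- list(c(colnames(X), "logsigma"), c(colnames(X), "logsigma"))
  se <- sqrt(pmax(diag(V), 0))

  se_ls <- se[q]
  ci_s2 <- exp(2 * c(logsigma - 1.96 * se_ls, logsigma + 1.96 * se_ls))

  ll <- evalc(par)$ll
  k <- q
  nonint <- which(colnames(X) != "(Intercept)")
  wald <- if (length(nonint)) {
    b <- beta[nonint]
    Vi <- tryCatch(solve(V[nonint, nonint, drop = FALSE]),
                   error = function(e) pracma::pinv(V[nonint, nonint, drop = FALSE]))
    w <- drop(t(b) %*% Vi %*% b)
    list(chi2 = w, df = length(nonint), p = pchisq(w, length(nonint), lower.tail = FALSE))
  } else list(chi2 = NA_real_, df = 0L, p = NA_real_)

  structure(list(
    coefficients = beta, se = se[1:p],
    sigma_u2 = sigma_u2, sigma_u2_ci = ci_s2, logsigma = logsigma,
    loglik = ll, aic = 2 * k - 2 * ll, n_params = k,
    icc = icc(sigma_u2), wald = wald,
    vcov = V, n_obs = length(y), n_clusters = max(cl),
    converged = opt$convergence == 0,
    nq = nq, adaptive = adaptive,
    formula = formula, cluster = cluster,
    term_labels = attr(terms(formula), "term.labels"),
    xlevels = stats::.getXlevels(attr(mf, "terms"), mf),
    data_rows = rownames(mf)
  ), class = "melogit")
}

#' @export
print.melogit <- function(x, ...) {
  cat("Random-intercept logistic model (adaptive Gauss-Hermite,",
      x$nq, "nodes)\n")
  cat(sprintf("  n = %d women in %d clusters\n", x$n_obs, x$n_clusters))
  cat(sprintf("  log-likelihood %.2f | AIC %.2f | sigma_u2 %.4f (%.4f-%.4f) | ICC %.3f\n",
              x$loglik, x$aic, x$sigma_u2, x$sigma_u2_ci[1], x$sigma_u2_ci[2],
              x$icc))
  tab <- data.frame(estimate = x$coefficients, se = x$se,
                    z = x$coefficients / x$se)
  print(round(tab, 4))
  invisible(x)
}

#' @export
logLik.melogit <- function(object, ...) {
  structure(object$loglik, df = object$n_params, class = "logLik")
}

#' Latent-variable intraclass correlation for the logistic model
#'
#' ICC = sigma_u2 / (sigma_u2 + pi^2 / 3): the share of latent-response
#' variance attributable to between-cluster variation, with the logistic
#' residual variance fixed at pi^2/3.
#'
#' @param sigma_u2 random-intercept variance (>= 0).
#' @return the ICC, in [0, 1).
#' @examples
#' icc(0.07)  # 0.021 to 3 decimals
#' @export
icc <- function(sigma_u2) {
  if (any(sigma_u2 < 0)) stop("sigma_u2 must be non-negative", call. = FALSE)
  sigma_u2 / (sigma_u2 + pi^2 / 3)
}

#' Likelihood-ratio test between nested fits
#'
#' @param fit_restricted,fit_full \code{melogit} fits on the same rows;
#'   the restricted model's terms must be a subset of the full model's.
#' @return list with \code{statistic}, \code{df}, \code{p}.
#' @export
likelihood_ratio_test <- function(fit_restricted, fit_full) {
  if (fit_restricted$n_obs != fit_full$n_obs) {
    stop("fits use different numbers of observations", call. = FALSE)
  }
  if (!all(fit_restricted$term_labels %in% fit_full$term_labels)) {
    stop("models are not nested", call. = FALSE)
  }
  df <- fit_full$n_params - fit_restricted$n_params
  if (df < 0) stop("models are not nested", call. = FALSE)
  lr <- max(0, 2 * (fit_full$loglik - fit_restricted$loglik))
  list(statistic = lr, df = df,
       p = if (df == 0) 1 else pchisq(lr, df, lower.tail = FALSE))
}

# population-averaged probabilities, integrating the random intercept over
# its prior with a (non-adaptive) Gauss-Hermite rule
pop_avg_prob <- function(X, beta, sigma_u, nq = 15L) {
  gh <- gh_rule(nq)
  eta <- drop(X %*% beta)
  pm <- plogis(outer(eta, sqrt(2) * sigma_u * gh$x, "+"))
  drop(pm %*% (gh$w / sqrt(pi)))
}

#' Average marginal effects for categorical covariates
#'
#' For each non-reference category c of each model covariate, the AME is
#' the mean over all women of the difference in population-averaged
#' probability between the covariate set to c and set to its reference,
#' integrating the random intercept over its prior. Standard errors by the
#' delta method (numerical Jacobian in (beta, log sigma_u) against the
#' fit's vcov). Significance stars at the 1%/5%/10% levels.
#'
#' @param fit a \code{\link{melogit}} fit.
#' @param data the data the model was fitted on.
#' @return data.frame: variable, level, ame, se, z, p, stars.
#' @export
average_marginal_effects <- function(fit, data) {
  data <- data[rownames(data) %in% fit$data_rows, , drop = FALSE]
  tt <- stats::delete.response(terms(fit$formula))
  p <- length(fit$coefficients)
  rows <- list()
  for (v in names(fit$xlevels)) {
    levs <- fit$xlevels[[v]]
    ref <- levs[1]
    d0 <- data
    d0[[v]] <- factor(ref, levels = levs)
    X0 <- model.matrix(tt, model.frame(tt, d0, xlev = fit$xlevels))
    for (lv in levs[-1]) {
      d1 <- data
      d1[[v]] <- factor(lv, levels = levs)
      X1 <- model.matrix(tt, model.frame(tt, d1, xlev = fit$xlevels))
      ame_at <- function(par) {
        mean(pop_avg_prob(X1, par[1:p], exp(par[p + 1])) -
               pop_avg_prob(X0, par[1:p], exp(par[p + 1])))
      }
      par <- c(fit$coefficients, fit$logsigma)
      a <- ame_at(par)
      jac <- numeric(p + 1)
      h <- 1e-5 * pmax(1, abs(par))
      for (j in seq_len(p + 1)) {
        e <- numeric(p + 1); e[j] <- h[j]
        jac[j] <- (ame_at(par + e) - ame_at(par - e)) / (2 * h[j])
      }
      se <- sqrt(max(0, drop(t(jac) %*% fit$vcov %*% jac)))
      rows[[length(rows) + 1L]] <- data.frame(
        variable = v, level = lv, ame = a, se = se,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(variable = character(), level = character(),
                      ame = numeric(), se = numeric(), z = numeric(),
                      p = numeric(), stars = character()))
  }
  out <- do.call(rbind, rows)
  out$z <- out$ame / out$se
  out$p <- 2 * pnorm(-abs(out$z))
  out$stars <- cut(out$p, c(-Inf, 0.01, 0.05, 0.10, Inf),
                   labels = c("***", "**", "*", ""))
  out
}

#' Individual-level and community-level covariates of the standard sequence
#'
#' @return character vectors of coded column names.
#' @export
individual_terms <- function() {
  c("age_group", "marital", "head_sex", "parity", "ever_terminated",
    "education", "media_exposure", "wanted_last", "wealth", "religion",
    "employed")
}

#' @rdname individual_terms
#' @export
community_terms <- function() {
  c("residence_majority", "community_age", "community_ses",
    "community_media_fp", "community_education",
    "community_facility_access")
}

#' Fit the four-model sequence
#'
#' Model 1: empty (intercept + random intercept). Model 2: individual
#' covariates. Model 3: community covariates. Model 4: both. Each fit
#' reports sigma_u2, ICC, log-likelihood and AIC; the sequence selects the
#' lowest-AIC model. A failing model is recorded and the sequence
#' continues.
#'
#' @param data coded analytic data with community columns attached.
#' @param individual,community term sets (defaults mirror the published
#'   model).
#' @param cluster cluster column name.
#' @param outcome outcome column name.
#' @param nq quadrature nodes.
#' @return object of class \code{melogit_sequence}: \code{fits} (list of 4,
#'   NULL where failed), \code{errors}, \code{comparison} data.frame,
#'   \code{best} (index of the lowest-AIC fit).
#' @export
run_model_sequence <- function(data, individual = individual_terms(),
                               community = community_terms(),
                               cluster = "district_id",
                               outcome = "outcome_modern", nq = 7L) {
  # terms observed at a single level cannot enter any model; note and drop
  usable <- function(v) length(unique(data[[v]][!is.na(data[[v]])])) >= 2
  ind_ok <- individual[vapply(individual, usable, logical(1))]
  com_ok <- community[vapply(community, usable, logical(1))]
  dropped <- setdiff(c(individual, community), c(ind_ok, com_ok))
  rhs <- function(tt) if (length(tt)) paste(tt, collapse = " + ") else "1"
  specs <- list(
    "Model 1" = paste(outcome, "~ 1"),
    "Model 2" = paste(outcome, "~", rhs(ind_ok)),
    "Model 3" = paste(outcome, "~", rhs(com_ok)),
    "Model 4" = paste(outcome, "~", rhs(c(ind_ok, com_ok)))
  )
  fits <- vector("list", 4L)
  errs <- vector("list", 4L)
  names(fits) <- names(errs) <- names(specs)
  for (i in seq_along(specs)) {
    fits[[i]] <- tryCatch(
      melogit(stats::as.formula(specs[[i]]), data, cluster, nq = nq),
      error = function(e) { errs[[i]] <<- conditionMessage(e); NULL })
  }
  comparison <- do.call(rbind, lapply(seq_along(fits), function(i) {
    f <- fits[[i]]
    if (is.null(f)) {
      data.frame(model = names(specs)[i], n_params = NA, loglik = NA,
                 aic = NA, sigma_u2 = NA, icc = NA, wald_chi2 = NA,
                 wald_p = NA)
    } else {
      data.frame(model = names(specs)[i], n_params = f$n_params,
                 loglik = f$loglik, aic = f$aic, sigma_u2 = f$sigma_u2,
                 icc = f$icc, wald_chi2 = f$wald$chi2, wald_p = f$wald$p)
    }
  }))
  best <- if (all(is.na(comparison$aic))) NA_integer_ else
    which.min(comparison$aic)
  structure(list(fits = fits, errors = errs, comparison = comparison,
                 best = best, dropped_terms = dropped),
            class = "melogit_sequence")
}

#' @export
print.melogit_sequence <- function(x, ...) {
  cat("Four-model random-intercept logistic sequence\n")
  print(transform(x$comparison,
                  loglik = round(loglik, 2), aic = round(aic, 2),
                  sigma_u2 = round(sigma_u2, 4), icc = round(icc, 3),
                  wald_chi2 = round(wald_chi2, 2)))
  if (!is.na(x$best)) {
    cat(sprintf("Lowest AIC: %s\n", x$comparison$model[x$best]))
  }
  invisible(x)
}
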