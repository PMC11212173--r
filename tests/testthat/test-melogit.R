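# clustered binary fixture used across the model tests
mk_cluster_data <- function(seed, J = 40, nj = 25, beta = c(-0.3, 0.8),
                            s2 = 0.25) {
  set.seed(seed)
  cl <- rep(seq_len(J), each = nj)
  x <- rbinom(J * nj, 1, 0.5)
  u <- rnorm(J, 0, sqrt(s2))
  y <- rbinom(J * nj, 1, plogis(beta[1] + beta[2] * x + u[cl]))
  data.frame(y = y, x = factor(x), cl = cl)
}

test_that("the sigma -> 0 limit equals the ordinary logistic log-likelihood", {
  d <- mk_cluster_data(1)
  X <- model.matrix(~ x, d)
  beta <- c(-0.2, 0.5)
  plain <- sum(d$y * plogis(drop(X %*% beta), log.p = TRUE) +
                 (1 - d$y) * plogis(-drop(X %*% beta), log.p = TRUE))
  expect_equal(melogit_loglik(beta, 0, d$y, X, d$cl), plain,
               tolerance = 1e-8)
  expect_equal(melogit_loglik(beta, 1e-6, d$y, X, d$cl), plain,
               tolerance = 1e-6)
})

test_that("quadrature agrees with dense trapezoid integration on one cluster", {
  set.seed(2)
  n <- 40
  X <- cbind(1, rbinom(n, 1, 0.5))
  y <- rbinom(n, 1, 0.5)
  beta <- c(0.2, -0.6)
  for (s in c(0.3, 0.8)) {
    oracle <- trapezoid_loglik_1cluster(beta, s, y, X)
    expect_equal(melogit_loglik(beta, s, y, X, rep(1, n), nq = 7),
                 oracle, tolerance = 1e-6)
  }
})

test_that("adaptive quadrature is converged at 7 nodes", {
  d <- mk_cluster_data(3)
  X <- model.matrix(~ x, d)
  beta <- c(-0.3, 0.8)
  l7 <- melogit_loglik(beta, 0.5, d$y, X, d$cl, nq = 7)
  l15 <- melogit_loglik(beta, 0.5, d$y, X, d$cl, nq = 15)
  expect_lt(abs(l7 - l15), 1e-6)
})

test_that("the analytic score matches finite differences of the objective", {
  d <- mk_cluster_data(4, J = 15, nj = 20)
  X <- model.matrix(~ x, d)
  par <- c(-0.2, 0.6, log(0.4))
  core <- getFromNamespace("agq_core", "mcpaccess")
  g <- unname(core(par[1:2], par[3], d$y, X, d$cl, grad = TRUE)$grad)
  num <- vapply(1:3, function(j) {
    h <- 1e-6
    e <- numeric(3); e[j] <- h
    (core((par + e)[1:2], (par + e)[3], d$y, X, d$cl)$ll -
       core((par - e)[1:2], (par - e)[3], d$y, X, d$cl)$ll) / (2 * h)
  }, numeric(1))
  expect_equal(g, num, tolerance = 1e-4)
})

test_that("with the variance pinned at zero the MLE intercept is logit(mean)", {
  set.seed(5)
  y <- rbinom(300, 1, 0.6)
  X <- matrix(1, 300, 1)
  cl <- rep(1:10, each = 30)
  b_hat <- optimize(function(b) -melogit_loglik(b, 0, y, X, cl),
                    c(-3, 3), tol = 1e-10)$minimum
  expect_equal(b_hat, qlogis(mean(y)), tolerance = 1e-6)
})

test_that("estimates match an independent mixed-model fitter within 2%", {
  skip_if_not_installed("lme4")
  d <- mk_cluster_data(6, J = 60, nj = 30, s2 = 0.3)
  f <- melogit(y ~ x, d, "cl", nq = 7)
  g <- lme4::glmer(y ~ x + (1 | cl), family = binomial, data = d, nAGQ = 7)
  expect_equal(unname(coef(f)), unname(lme4::fixef(g)), tolerance = 0.02)
  expect_equal(f$sigma_u2, unname(lme4::VarCorr(g)$cl[1]), tolerance = 0.02)
  expect_equal(f$loglik, as.numeric(stats::logLik(g)), tolerance = 1e-4)
  # standard errors in the same ballpark as the cross-fitter
  expect_equal(unname(f$se),
               unname(coef(summary(g))[, "Std. Error"]), tolerance = 0.05)
})

test_that("fit errors are explicit for degenerate designs", {
  d <- mk_cluster_data(7, J = 10, nj = 10)
  d$z <- d$x   # aliased copy
  expect_error(melogit(y ~ x + z, d, "cl"), "rank deficient")
  d1 <- d[d$cl == 1, ]
  expect_error(melogit(y ~ x, d1, "cl"), "at least 2 clusters")
})

test_that("the ICC formula and its properties hold", {
  expect_equal(round(icc(0.07), 3), 0.021)
  expect_equal(icc(0), 0)
  expect_equal(icc(pi^2 / 3), 0.5)
  expect_error(icc(-0.01), "non-negative")
  s <- seq(0, 5, by = 0.25)
  expect_true(all(diff(icc(s)) > 0))
  expect_true(all(icc(s) >= 0 & icc(s) < 1))
})

test_that("AIC identity 2k - 2*loglik holds exactly for every fit", {
  d <- mk_cluster_data(8)
  f <- melogit(y ~ x, d, "cl")
  expect_identical(f$aic, 2 * f$n_params - 2 * f$loglik)
  f0 <- melogit(y ~ 1, d, "cl")
  expect_identical(f0$aic, 2 * f0$n_params - 2 * f0$loglik)
})

test_that("likelihood-ratio test: identity, nesting, and the LR = 2*delta rule", {
  d <- mk_cluster_data(9)
  f0 <- melogit(y ~ 1, d, "cl")
  f1 <- melogit(y ~ x, d, "cl")
  same <- likelihood_ratio_test(f0, f0)
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)
  lr <- likelihood_ratio_test(f0, f1)
  expect_equal(lr$statistic, 2 * (f1$loglik - f0$loglik), tolerance = 1e-12)
  expect_equal(lr$df, f1$n_params - f0$n_params)
  expect_error(likelihood_ratio_test(f1, f0), "not nested")
  d2 <- d; d2$w <- factor(rbinom(nrow(d), 1, 0.5))
  f2 <- melogit(y ~ w, d2, "cl")
  expect_error(likelihood_ratio_test(f1, f2), "not nested")
})

test_that("marginal effects: zero for a null coefficient, closed form at sigma=0", {
  d <- mk_cluster_data(10, J = 30, nj = 30)
  f <- melogit(y ~ x, d, "cl")
  # null out the covariate: its AME must be exactly zero
  f0 <- f
  f0$coefficients["x1"] <- 0
  ame0 <- average_marginal_effects(f0, d)
  expect_equal(ame0$ame, 0, tolerance = 1e-10)
  # at sigma ~ 0 the AME is the plain difference of logistic probabilities
  fz <- f
  fz$logsigma <- log(1e-8)
  amez <- average_marginal_effects(fz, d)
  b <- fz$coefficients
  expect_equal(amez$ame, plogis(b[1] + b[2]) - plogis(b[1]),
               tolerance = 1e-8, ignore_attr = TRUE)
  # population-averaged AME is attenuated but same-signed
  amef <- average_marginal_effects(f, d)
  expect_equal(sign(amef$ame), sign(b[2]), ignore_attr = TRUE)
})

test_that("AME signs equal coefficient signs on the default synthetic design", {
  cd <- code_women(apply_sample_filter(simulate_women(
    small_config(seed = 60, n_districts = 40, women_per_district = 80))))
  f <- melogit(outcome_modern ~ education + wealth + head_sex, cd,
               "district_id")
  ame <- average_marginal_effects(f, cd)
  bs <- coef(f)[-1]
  expect_equal(sign(ame$ame), sign(unname(bs)))
})

test_that("the four-model sequence reports ICC, AIC and picks the best model", {
  cd <- code_women(apply_sample_filter(simulate_women(small_config(seed = 61))))
  cd <- add_community_vars(cd, aggregate_community(cd))
  sq <- run_model_sequence(cd, nq = 5)
  expect_s3_class(sq, "melogit_sequence")
  expect_equal(nrow(sq$comparison), 4)
  ok <- !is.na(sq$comparison$aic)
  expect_true(sum(ok) >= 3)
  expect_equal(sq$best, which.min(sq$comparison$aic))
  expect_true(all(sq$comparison$icc[ok] >= 0 & sq$comparison$icc[ok] < 1))
  expect_equal(sq$comparison$aic[ok],
               2 * sq$comparison$n_params[ok] - 2 * sq$comparison$loglik[ok])
  # empty model on unclustered data: ICC near zero
  cd0 <- code_women(apply_sample_filter(simulate_women(
    small_config(seed = 62, sigma_u2 = 0, betas = list(),
                 community_betas = list()))))
  f0 <- melogit(outcome_modern ~ 1, cd0, "district_id")
  expect_lt(f0$icc, 0.02)
})
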