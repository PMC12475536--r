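# Oracle-based checks of the mixed-model wrapper: OLS limit, closed-form
# balanced one-way likelihood, dispersion-scale recovery, and the H1-H4
# model builders.

test_that("fixed effects match OLS when groups carry no signal", {
  set.seed(41)
  n <- 600
  d <- data.frame(x = rnorm(n), g = sample(letters[1:10], n, TRUE),
                  b = sample(LETTERS[1:5], n, TRUE))
  d$y <- 1.5 + 2 * d$x + rnorm(n)
  fit <- suppressWarnings(fit_lmm(y ~ x + (1 | g) + (1 | b), d))
  ols <- coef(lm(y ~ x, d))
  expect_equal(fit$coefficients$estimate, as.numeric(ols), tolerance = 1e-2)
  expect_lt(sum(fit$ranef_var), 0.05)
})

test_that("balanced one-way fit maximizes the exact marginal likelihood", {
  # independent oracle: closed-form compound-symmetry log-likelihood of a
  # balanced one-way layout, maximized numerically
  set.seed(42)
  k <- 25; n <- 8
  g <- rep(seq_len(k), each = n)
  y <- 2 + rep(rnorm(k, 0, 0.7), each = n) + rnorm(k * n, 0, 0.5)
  oracle_nll <- function(par) {
    mu <- par[1]; s2e <- exp(par[2]); s2b <- exp(par[3])
    ybar <- tapply(y, g, mean)
    ssw <- sum((y - rep(ybar, each = n))^2)
    0.5 * (k * n * log(2 * pi) + k * ((n - 1) * log(s2e) + log(s2e + n * s2b)) +
             ssw / s2e + sum(n * (ybar - mu)^2 / (s2e + n * s2b)))
  }
  opt <- optim(c(0, 0, 0), oracle_nll, method = "BFGS")
  fit <- fit_lmm(y ~ 1 + (1 | g), data.frame(y = y, g = factor(g)))
  expect_equal(fit$coefficients$estimate, opt$par[1], tolerance = 1e-4)
  expect_equal(fit$sigma2, exp(opt$par[2]), tolerance = 1e-3)
  expect_equal(as.numeric(fit$ranef_var), exp(opt$par[3]), tolerance = 1e-3)
  expect_equal(fit$logLik, -opt$value, tolerance = 1e-6)
  expect_equal(fit$AIC, 2 * 3 - 2 * fit$logLik)
})

test_that("dispersion coefficients are reported on the log-variance scale", {
  set.seed(43)
  n <- 4000
  x <- runif(n, 0, 6)
  y <- 1 + 0.2 * x + rnorm(n, 0, sqrt(exp(-0.5 + 0.3 * x)))
  fit <- fit_lmm(y ~ x, data.frame(y, x), dispformula = ~x)
  disp <- coef_table(fit, "disp")
  expect_equal(disp$estimate[disp$term == "x"], 0.3, tolerance = 0.05)
  expect_equal(disp$estimate[disp$term == "(Intercept)"], -0.5, tolerance = 0.1)
})

test_that("freeing the dispersion slope never lowers the likelihood", {
  d <- simulate_richness_data(n_plots = 400, n_experiments = 6,
                              delta = c(-1, -0.2), seed = 44)
  f0 <- fit_h1(d, dispersion = FALSE)
  f1 <- fit_h1(d, dispersion = TRUE)
  expect_gte(f1$logLik, f0$logLik - 1e-8)
})

test_that("estimates are invariant to row order", {
  d <- simulate_richness_data(n_plots = 300, n_experiments = 5, seed = 45)
  f1 <- fit_h1(d)
  set.seed(1)
  f2 <- fit_h1(d[sample(nrow(d)), ])
  expect_equal(f1$coefficients$estimate, f2$coefficients$estimate,
               tolerance = 1e-6)
  expect_equal(f1$logLik, f2$logLik, tolerance = 1e-8)
})

test_that("quadratic richness model recovers injected parameters", {
  beta <- c(0.2, 0.3, -0.03)
  hits <- 0L
  for (r in 1:10) {
    d <- simulate_richness_data(n_plots = 500, n_experiments = 10,
                                beta = beta, delta = c(-1.2, 0), seed = 100 + r)
    fit <- fit_h1(d)
    ci <- wald_ci(fit)
    covered <- beta >= ci$lower & beta <= ci$upper
    hits <- hits + all(covered[2:3])
  }
  expect_gte(hits, 8L)  # ~95% CIs: nearly all of 10 replicates cover truth
})

test_that("null richness effect yields CIs covering zero", {
  d <- simulate_richness_data(n_plots = 600, n_experiments = 10,
                              beta = c(0, 0, 0), delta = c(-1, 0), seed = 46)
  fit <- fit_h1(d)
  ci <- wald_ci(fit)
  expect_true(all(ci$lower[2:3] <= 0 & ci$upper[2:3] >= 0))
  disp <- coef_table(fit, "disp")
  expect_lt(abs(disp$estimate[2]), 3 * disp$se[2])  # dispersion slope ~ 0
})

test_that("diversity-effect model recovers trait-linked coefficients", {
  set.seed(47)
  n <- 800
  d <- data.frame(experiment = sprintf("E%02d", rep_len(1:8, n)),
                  richness = sample(2:6, n, TRUE))
  d$block <- paste0(d$experiment, "_B", sample(1:3, n, TRUE))
  d$composition <- paste0(d$experiment, "_C", sample(1:12, n, TRUE))
  d$cwm_WD_std <- rnorm(n); d$cwm_LNC_std <- rnorm(n)
  d$fdis_WD_std <- runif(n); d$fdis_LNC_std <- runif(n)
  re <- function(f, s) setNames(rnorm(length(unique(f)), 0, s), unique(f))[f]
  d$SE <- 0.2 - 0.15 * d$cwm_WD_std + 1.3 * d$fdis_WD_std +
    re(d$composition, 0.2) + re(d$block, 0.1) + rnorm(n, 0, 0.4)
  fit <- fit_h3(d, "SE")
  ct <- coef_table(fit)
  expect_lt(abs(ct$estimate[ct$term == "fdis_WD_std"] - 1.3), 0.2)
  expect_lt(abs(ct$estimate[ct$term == "cwm_WD_std"] + 0.15), 0.1)
  expect_gt(ct$estimate[ct$term == "fdis_WD_std"] /
              ct$se[ct$term == "fdis_WD_std"], 2)
})

test_that("species-level model exposes back-transformed richness curves", {
  gen <- generate_experiments(scenario_config("selection", n_experiments = 3),
                              seed = 48)
  spp <- species_productivity(gen$trees, gen$plots)
  spp <- merge(spp, gen$plots[, c("plot_id", "composition", "richness")],
               by = "plot_id")
  tz <- gen$traits
  tz$WD_z <- zscore(tz$WD); tz$LNC_z <- zscore(tz$LNC)
  spp <- merge(spp, tz[, c("species", "WD_z", "LNC_z", "class")], by = "species")
  fit <- fit_h4(spp)
  expect_gt(fit$constant, 0)
  # default offset: half the smallest positive productivity
  expect_equal(fit$constant, min(spp$productivity[spp$productivity > 0]) / 2)
  crv <- h4_curve(fit, richness = 1:6, WD_z = 0, LNC_z = 0)
  # at mean traits the interactions vanish: slope equals the main effect
  b <- setNames(fit$coefficients$estimate, fit$coefficients$term)
  expect_equal(diff(crv$linear_predictor), rep(b[["richness"]], 5))
  # back-transform identity
  expect_equal(crv$productivity, exp(crv$linear_predictor) - fit$constant)
  # acquisitive boost under the selection regime: positive LNC interaction
  expect_gt(b[["richness:LNC_z"]], b[["richness:WD_z"]])
})

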