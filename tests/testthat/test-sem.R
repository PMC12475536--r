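test_that("basis set enumerates d-separation claims", {
  chain <- data.frame(from = c("X", "M"), to = c("M", "Y"))
  bs <- basis_set(chain)
  expect_length(bs, 1)
  expect_equal(bs[[1]]$x, "X")
  expect_equal(bs[[1]]$y, "Y")
  expect_equal(bs[[1]]$cond, "M")

  # the study DAG: exactly one claim, structural vs functional dispersion
  # given richness, hence df = 2
  spec <- sem_spec()
  bs2 <- basis_set(spec$dag)
  expect_length(bs2, 1)
  expect_setequal(c(bs2[[1]]$x, bs2[[1]]$y), c("structural", "fdis_all"))
  expect_equal(bs2[[1]]$cond, "richness")

  # saturated triangle: no claims
  tri <- data.frame(from = c("A", "A", "B"), to = c("B", "C", "C"))
  expect_length(basis_set(tri), 0)

  cyc <- data.frame(from = c("A", "B"), to = c("B", "A"))
  expect_error(basis_set(cyc), "cyclic")
})

test_that("Fisher's C combines claim p-values correctly", {
  expect_equal(fishers_c(1)$C, 0)
  expect_equal(fishers_c(1)$p, 1)
  fc <- fishers_c(0.5)
  expect_equal(fc$C, -2 * log(0.5), tolerance = 1e-12)
  expect_equal(fc$df, 2L)
  expect_equal(fc$p, 0.5, tolerance = 1e-12)
  # chi-squared with 2 df: survival function is exp(-C/2)
  fc2 <- fishers_c(exp(-1.063 / 2))
  expect_equal(fc2$C, 1.063, tolerance = 1e-12)
  expect_equal(fc2$p, exp(-1.063 / 2), tolerance = 1e-12)
  expect_equal(round(fc2$p, 2), 0.59)
  # additivity over independent claim sets
  p <- c(0.2, 0.7, 0.05)
  expect_equal(fishers_c(p)$C, fishers_c(p[1])$C + fishers_c(p[2:3])$C)
  expect_equal(fishers_c(p)$df, 6L)
  expect_warning(fc0 <- fishers_c(c(0.5, 0)), "infinite")
  expect_equal(fc0$p, 0)
  expect_error(fishers_c(numeric()), "saturated")
  expect_error(fishers_c(c(0.5, 1.2)))
})

test_that("path standardization and indirect effects", {
  expect_equal(standardize_path(2, 1, 2), 1)
  expect_equal(standardize_path(0.7, 3, 3), 0.7)  # pre-standardized: identity
  expect_error(standardize_path(1, 0, 1), "zero-SD")
  expect_equal(indirect_effect(c(0.59, 0.27)), 0.1593)
  expect_equal(indirect_effect(c(0.38, -0.55)), -0.209)
  expect_equal(indirect_effect(c(1, 0.42)), 0.42)
  expect_error(indirect_effect(numeric()))
})

test_that("piecewise SEM recovers injected path coefficients", {
  paths <- c(r_s = 0.6, r_f = 0.3, s_p = -0.5, f_p = 0.3, r_p = 0.05)
  d <- simulate_sem_data(n_plots = 2000, paths = paths, seed = 7,
                         sd_comp = 0.15, sd_block = 0.1)
  sem <- fit_piecewise(d, sem_spec(interaction = "none"))
  est <- setNames(sem$paths$estimate, paste(sem$paths$from, sem$paths$to))
  expect_lt(abs(est[["richness structural"]] - 0.6), 0.05)
  expect_lt(abs(est[["richness fdis_all"]] - 0.3), 0.05)
  expect_lt(abs(est[["structural productivity"]] + 0.5), 0.05)
  expect_lt(abs(est[["fdis_all productivity"]] - 0.3), 0.05)
  # standardized = raw * sd(x)/sd(y), and the claim p is the SEM p (df = 2)
  i <- which(sem$paths$from == "structural" & sem$paths$to == "productivity")
  expect_equal(sem$paths$std_estimate[i],
               sem$paths$estimate[i] * sd(d$gini_height_std) /
                 sd(d$productivity_std))
  expect_equal(sem$p, sem$claims$p[1], tolerance = 1e-12)
  expect_equal(sem$df, 2L)
  expect_true(all(names(sem$r2_marginal) %in%
                    c("structural", "fdis_all", "productivity")))
  expect_true(all(sem$r2_marginal >= 0 & sem$r2_marginal <= 1))
})

test_that("direct plus indirect effects reproduce the total richness effect", {
  d <- simulate_sem_data(n_plots = 5000, n_experiments = 10,
                         paths = c(r_s = 0.3, r_f = 0.4, s_p = -0.35,
                                   f_p = 0.3, r_p = 0.1),
                         sd_comp = 0.1, sd_block = 0.1, seed = 8)
  sem <- fit_piecewise(d, sem_spec(interaction = "none"))
  direct <- sem$paths$std_estimate[sem$paths$from == "richness" &
                                     sem$paths$to == "productivity"]
  ind_f <- sem_indirect(sem, c("richness", "fdis_all", "productivity"))
  ind_s <- sem_indirect(sem, c("richness", "structural", "productivity"))
  total_model <- fit_lmm(productivity_std ~ richness +
                           (1 | experiment:composition) +
                           (1 | experiment:block), d)
  total <- total_model$coefficients$estimate[2] * sd(d$richness) /
    sd(d$productivity_std)
  expect_equal(direct + ind_f + ind_s, total, tolerance = 0.02)
  expect_error(sem_indirect(sem, c("fdis_all", "richness")), "not a directed path")
})

test_that("interaction variants are expressible and AIC-comparable", {
  d <- simulate_sem_data(n_plots = 800, seed = 9)
  # inject a richness x structural interaction into productivity
  d$productivity_std <- d$productivity_std +
    0.15 * d$richness * d$gini_height_std
  s0 <- fit_piecewise(d, sem_spec(interaction = "none"))
  s1 <- fit_piecewise(d, sem_spec(interaction = "richness_structural"))
  expect_lt(s1$AIC, s0$AIC)
  expect_true("richness:structural" %in% s1$paths$from)
  # interaction never enters the conditioning set of the claim
  expect_equal(s1$claims$conditioning, "richness")
})

test_that("structural metric is selectable between Gini and CV", {
  gen <- generate_experiments(scenario_config("paper_like", n_experiments = 4),
                              seed = 10)
  m <- apply_scaling(plot_metrics(gen$trees, gen$plots, gen$traits))
  sg <- fit_piecewise(m, sem_spec(structural = "gini"))
  sc <- fit_piecewise(m, sem_spec(structural = "cv"))
  expect_true(is.finite(sg$AIC) && is.finite(sc$AIC))
  expect_equal(sg$n, sum(!is.na(m$gini_height)))
})
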