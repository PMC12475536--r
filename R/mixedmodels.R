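# Gaussian mixed models with nested random intercepts and an optional
# richness-dependent residual-dispersion submodel. Fitting is delegated to
# glmmTMB (maximum likelihood throughout so AIC comparisons across fixed
# structures are valid); this file defines the model specs used in the
# analysis chain and a uniform result container.

#' Fit a Gaussian linear mixed model with a dispersion submodel
#'
#' Thin wrapper around [glmmTMB::glmmTMB()] (Gaussian family, ML). The
#' dispersion formula models the residual variance as
#' `exp(delta_0 + delta_1 * covariate + ...)`; coefficients are reported on
#' the log-variance scale. Nested random intercepts are written with `:`
#' (e.g. `(1 | experiment:block)`), so the grouping labels themselves
#' encode the nesting.
#'
#' @param formula Model formula including random-effect terms.
#' @param data Data frame.
#' @param dispformula One-sided formula for the log residual variance
#'   (default `~ 1`, constant variance).
#' @param ... Passed on to [glmmTMB::glmmTMB()].
#' @return Object of class `standiv_fit`: list with `model` (the glmmTMB
#'   fit), `coefficients` (term/estimate/se/statistic/p), `dispersion`
#'   (log-variance scale coefficients), `ranef_var` (random-effect
#'   variances), `sigma2` (residual variance at covariate 0), `logLik`,
#'   `AIC`, `n`.
#' @export
fit_lmm <- function(formula, data, dispformula = ~1, ...) {
  fit <- glmmTMB::glmmTMB(formula, data = data, dispformula = dispformula,
                          family = stats::gaussian(), REML = FALSE, ...)
  if (isFALSE(fit$fit$convergence == 0)) {
    stop("mixed model did not converge (optimizer message: ",
         fit$fit$message, ")", call. = FALSE)
  }
  if (!isTRUE(fit$sdr$pdHess)) {
    # typically a random-effect variance collapsing to zero
    warning("non-positive-definite Hessian (singular fit?); ",
            "estimates retained, standard errors may be unreliable",
            call. = FALSE)
  }
  sm <- summary(fit)
  ctab <- as.data.frame(sm$coefficients$cond)
  names(ctab) <- c("estimate", "se", "statistic", "p")
  ctab <- cbind(term = rownames(ctab), ctab)
  rownames(ctab) <- NULL
  dtab <- sm$coefficients$disp
  if (is.null(dtab)) {
    disp <- data.frame(term = "(Intercept)",
                       estimate = 2 * log(glmmTMB::sigma(fit)),
                       se = NA_real_, statistic = NA_real_, p = NA_real_)
  } else {
    dtab <- as.data.frame(dtab)
    names(dtab) <- c("estimate", "se", "statistic", "p")
    # glmmTMB parameterizes the Gaussian dispersion model on the log-SD
    # scale; double to report log residual variance.
    dtab$estimate <- 2 * dtab$estimate
    dtab$se <- 2 * dtab$se
    disp <- cbind(term = rownames(dtab), dtab)
    rownames(disp) <- NULL
  }
  vc <- glmmTMB::VarCorr(fit)$cond
  rv <- vapply(vc, function(m) as.numeric(m[1, 1]), 0)
  structure(list(model = fit, coefficients = ctab, dispersion = disp,
                 ranef_var = rv, sigma2 = glmmTMB::sigma(fit)^2,
                 logLik = as.numeric(logLik(fit)), AIC = AIC(fit),
                 n = stats::nobs(fit), formula = formula,
                 dispformula = dispformula),
            class = "standiv_fit")
}

#' @export
print.standiv_fit <- function(x, ...) {
  cat("Gaussian mixed model (ML) --", deparse(x$formula), "\n")
  cat("n =", x$n, " logLik =", round(x$logLik, 2), " AIC =", round(x$AIC, 2), "\n")
  cat("\nFixed effects:\n")
  print(x$coefficients, digits = 4)
  if (nrow(x$dispersion) > 1 || !is.na(x$dispersion$se[1])) {
    cat("\nDispersion model (log residual variance):\n")
    print(x$dispersion, digits = 4)
  }
  if (length(x$ranef_var)) {
    cat("\nRandom-effect variances:\n")
    print(round(x$ranef_var, 5))
  }
  invisible(x)
}

#' Extract the coefficient table of a fit
#' @param fit A `standiv_fit`.
#' @param component `"cond"` for the mean model, `"disp"` for the
#'   dispersion model.
#' @return Data frame with `term`, `estimate`, `se`, `statistic`, `p`.
#' @export
coef_table <- function(fit, component = c("cond", "disp")) {
  component <- match.arg(component)
  if (component == "cond") fit$coefficients else fit$dispersion
}

#' Wald confidence intervals for fixed effects
#' @param fit A `standiv_fit`.
#' @param level Confidence level.
#' @return Data frame with `term`, `lower`, `upper`.
#' @export
wald_ci <- function(fit, level = 0.95) {
  z <- qnorm(1 - (1 - level) / 2)
  ct <- fit$coefficients
  data.frame(term = ct$term, lower = ct$estimate - z * ct$se,
             upper = ct$estimate + z * ct$se)
}

# Shared nested random-intercept structure of the plot-level models.
.random_terms <- function(class_effect = FALSE) {
  terms <- c("(1 | experiment:composition)", "(1 | experiment:block)")
  if (class_effect) terms <- c(terms, "(1 | experiment:class)")
  terms
}

.build_formula <- function(response, fixed, class_effect = FALSE) {
  as.formula(paste(response, "~", paste(c(fixed, .random_terms(class_effect)),
                                        collapse = " + ")))
}

#' Richness-productivity model (quadratic, richness-dependent dispersion)
#'
#' Fits standardized stand productivity against species richness with a
#' quadratic term, nested random intercepts for composition and block
#' within experiment, and residual variance varying with richness:
#'
#' `productivity_std ~ richness + richness^2 + (1 | experiment:composition)
#'  + (1 | experiment:block)`, dispersion `~ richness`.
#'
#' @param data Plot-metric table with a `productivity_std` column (see
#'   [apply_scaling()]) plus `richness`, `experiment`, `block`,
#'   `composition`.
#' @param dispersion Model residual variance as a function of richness?
#' @return A `standiv_fit`.
#' @export
fit_h1 <- function(data, dispersion = TRUE) {
  fit_lmm(.build_formula("productivity_std", c("richness", "I(richness^2)")),
          data = data,
          dispformula = if (dispersion) ~richness else ~1)
}

#' Diversity-effect models on functional identity and diversity
#'
#' Regresses a diversity effect (selection, complementarity or net effect,
#' untransformed) on community weighted means and functional dispersion of
#' wood density and leaf nitrogen (standardized within experiment), with
#' the shared nested random structure and richness-dependent dispersion.
#'
#' @param data Mixture-plot table carrying the partition columns (`SE`,
#'   `CE`, `NBE`) merged with standardized metrics (`cwm_WD_std`,
#'   `cwm_LNC_std`, `fdis_WD_std`, `fdis_LNC_std`).
#' @param response One of `"SE"`, `"CE"`, `"NBE"`.
#' @param dispersion Model residual variance as a function of richness?
#' @return A `standiv_fit`.
#' @export
fit_h3 <- function(data, response = c("SE", "CE", "NBE"), dispersion = TRUE) {
  response <- match.arg(response)
  fit_lmm(.build_formula(response, c("cwm_WD_std", "cwm_LNC_std",
                                     "fdis_WD_std", "fdis_LNC_std")),
          data = data,
          dispformula = if (dispersion) ~richness else ~1)
}

#' Species-level productivity model with trait-richness interactions
#'
#' Fits log(species productivity + c) against species richness, species
#' wood density and leaf nitrogen (z-scored across experiments) and their
#' interactions with richness, with random intercepts for composition,
#' block and taxonomic class (angiosperm/gymnosperm) nested within
#' experiment, and richness-dependent dispersion. The constant `c` keeps
#' all values positive before the log; by default it is half the smallest
#' positive productivity in the data.
#'
#' @param data Species-by-plot table with columns `productivity`,
#'   `richness`, `WD_z`, `LNC_z`, `experiment`, `block`, `composition`,
#'   `class`.
#' @param constant Positive offset added before the log transform;
#'   `NULL` for the default.
#' @param dispersion Model residual variance as a function of richness?
#' @return A `standiv_fit` with the offset stored as `$constant`.
#' @export
fit_h4 <- function(data, constant = NULL, dispersion = TRUE) {
  if (is.null(constant)) {
    pos <- data$productivity[data$productivity > 0]
    if (!length(pos)) stop("no positive productivity values", call. = FALSE)
    constant <- min(pos) / 2
  }
  stopifnot(constant > 0)
  data$log_sp_prod <- log(data$productivity + constant)
  fit <- fit_lmm(.build_formula("log_sp_prod",
                                c("richness * WD_z", "richness * LNC_z"),
                                class_effect = TRUE),
                 data = data,
                 dispformula = if (dispersion) ~richness else ~1)
  fit$constant <- constant
  fit
}

#' Back-transformed species-productivity curves across richness
#'
#' Evaluates the population-level (fixed-effects) prediction of a
#' [fit_h4()] model over a richness gradient for given standardized trait
#' values, and back-transforms it to the productivity scale
#' (`exp(linear predictor) - c`).
#'
#' @param fit A `standiv_fit` from [fit_h4()].
#' @param richness Numeric vector of richness values.
#' @param WD_z,LNC_z Standardized trait values of the focal species.
#' @return Data frame with `richness`, `WD_z`, `LNC_z`, `linear_predictor`
#'   and back-transformed `productivity`.
#' @export
h4_curve <- function(fit, richness = 1:6, WD_z = 0, LNC_z = 0) {
  b <- setNames(fit$coefficients$estimate, fit$coefficients$term)
  lp <- b["(Intercept)"] + b["richness"] * richness + b["WD_z"] * WD_z +
    b["LNC_z"] * LNC_z + b["richness:WD_z"] * richness * WD_z +
    b["richness:LNC_z"] * richness * LNC_z
  data.frame(richness = richness, WD_z = WD_z, LNC_z = LNC_z,
             linear_predictor = as.numeric(lp),
             productivity = exp(as.numeric(lp)) - fit$constant)
}
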