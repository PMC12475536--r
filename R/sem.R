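# Piecewise structural equation modeling: local mixed models on a DAG,
# d-separation basis set, Fisher's C, standardized paths and indirect
# effects.

#' SEM specification for the richness -> diversity -> productivity DAG
#'
#' Builds the three-equation piecewise SEM used in the analysis chain:
#' species richness drives structural diversity and functional dispersion,
#' and productivity responds to richness, structural diversity and
#' functional dispersion, optionally with one interaction term. All
#' submodels share the nested random-intercept structure
#' `(1 | experiment:composition) + (1 | experiment:block)` and a fixed
#' residual variance (no dispersion submodel, so marginal R-squared values
#' are well defined).
#'
#' @param interaction `"none"`, `"richness_structural"` (product of
#'   richness and structural diversity in the productivity equation) or
#'   `"fdis_structural"`.
#' @param structural Structural-diversity metric: `"gini"` (default;
#'   consistently the better-fitting choice by AIC) or `"cv"`.
#' @return Object of class `standiv_sem_spec`: list with `dag` (edge data
#'   frame), `interaction`, `structural`, and the variable-to-column map.
#' @export
sem_spec <- function(interaction = c("none", "richness_structural",
                                     "fdis_structural"),
                     structural = c("gini", "cv")) {
  interaction <- match.arg(interaction)
  structural <- match.arg(structural)
  dag <- data.frame(
    from = c("richness", "richness", "richness", "structural", "fdis_all"),
    to = c("structural", "fdis_all", "productivity", "productivity",
           "productivity"),
    stringsAsFactors = FALSE
  )
  cols <- c(richness = "richness",
            structural = paste0(structural, "_height_std"),
            fdis_all = "fdis_all_std",
            productivity = "productivity_std")
  structure(list(dag = dag, interaction = interaction,
                 structural = structural, columns = cols),
            class = "standiv_sem_spec")
}

# Topological order of a DAG given as an edge data frame.
.topo_order <- function(dag) {
  vars <- unique(c(dag$from, dag$to))
  order <- character()
  remaining <- vars
  while (length(remaining)) {
    sub <- dag[dag$from %in% remaining & dag$to %in% remaining, ]
    roots <- setdiff(remaining, sub$to)
    if (!length(roots)) stop("graph is cyclic: not a valid SEM DAG", call. = FALSE)
    order <- c(order, roots)
    remaining <- setdiff(remaining, roots)
  }
  order
}

#' d-separation basis set of a DAG
#'
#' One independence claim per non-adjacent variable pair: the pair is
#' claimed independent conditional on the union of the parents of both
#' variables. Each claim is oriented so that the topologically later
#' variable is the response of the claim test. Interaction terms are never
#' part of the DAG and never appear in conditioning sets.
#'
#' @param dag Edge data frame with columns `from` and `to` (acyclic).
#' @return List of claims, each a list with `x` (earlier variable), `y`
#'   (later variable) and `cond` (character vector of conditioning
#'   variables). Empty list for a saturated (fully connected) DAG.
#' @export
basis_set <- function(dag) {
  ord <- .topo_order(dag)
  adj <- paste(dag$from, dag$to)
  claims <- list()
  for (i in seq_along(ord)) {
    for (j in seq_along(ord)) {
      if (j <= i) next
      x <- ord[i]; y <- ord[j]
      if (paste(x, y) %in% adj || paste(y, x) %in% adj) next
      pa <- union(dag$from[dag$to == x], dag$from[dag$to == y])
      claims[[length(claims) + 1L]] <- list(x = x, y = y,
                                            cond = setdiff(pa, c(x, y)))
    }
  }
  claims
}

#' Fisher's C statistic
#'
#' Combines the p-values of the d-separation claims:
#' `C = -2 * sum(log(p))`, which follows a chi-squared distribution with
#' `2k` degrees of freedom when all `k` claims hold.
#'
#' @param p Numeric vector of claim p-values in `(0, 1]`.
#' @return List with `C`, `df` (= `2 * length(p)`) and `p` (upper-tail
#'   chi-squared probability). A zero input p-value yields `C = Inf`,
#'   `p = 0`, with a warning.
#' @export
fishers_c <- function(p) {
  if (!length(p)) stop("no independence claims: saturated model, C undefined",
                       call. = FALSE)
  if (any(is.na(p) | p < 0 | p > 1)) stop("claim p-values must lie in [0, 1]",
                                          call. = FALSE)
  if (any(p == 0)) warning("claim p-value of 0: Fisher's C is infinite",
                           call. = FALSE)
  C <- -2 * sum(log(p))
  df <- 2L * length(p)
  list(C = C, df = df, p = pchisq(C, df, lower.tail = FALSE))
}

#' Standardize a path coefficient
#'
#' Converts a raw regression coefficient to standard-deviation units:
#' `beta * sd(x) / sd(y)`, i.e. how many SDs the response changes per SD
#' change in the predictor. When both variables are already z-scored the
#' coefficient is returned unchanged (SD ratio 1).
#'
#' @param beta Raw coefficient.
#' @param sd_x,sd_y Standard deviations of predictor and response in the
#'   analysis data.
#' @return Standardized coefficient.
#' @export
standardize_path <- function(beta, sd_x, sd_y) {
  if (is.na(sd_x) || sd_x == 0) stop("zero-SD predictor: path undefined", call. = FALSE)
  if (is.na(sd_y) || sd_y == 0) stop("zero-SD response: path undefined", call. = FALSE)
  beta * sd_x / sd_y
}

#' Indirect effect along a directed route
#'
#' Product of the standardized path coefficients along a route, e.g.
#' richness -> functional dispersion -> productivity.
#'
#' @param coefs Numeric vector of path coefficients along the route.
#' @return Their product.
#' @export
indirect_effect <- function(coefs) {
  if (!length(coefs) || anyNA(coefs)) stop("invalid route coefficients", call. = FALSE)
  prod(coefs)
}

#' Fit a piecewise SEM
#'
#' Fits the local mixed models of a [sem_spec()] on a plot-level analysis
#' table, evaluates the d-separation basis set (each claim tested by adding
#' the claimed-independent predictor to the mixed model of the claim's
#' response and taking the two-tailed Wald p-value of its coefficient),
#' combines claim p-values into Fisher's C, and reports standardized path
#' coefficients and marginal R-squared per endogenous variable.
#'
#' Rows with missing values in any SEM column (e.g. plots without
#' structural diversity) are dropped before fitting.
#'
#' @param data Plot-metric table after [apply_scaling()], with columns for
#'   richness, standardized productivity, standardized structural
#'   diversity and min-max scaled functional dispersion, plus
#'   `experiment`, `block`, `composition`.
#' @param spec A `standiv_sem_spec`.
#' @return Object of class `standiv_sem`: list with `paths` (data frame:
#'   `from`, `to`, `estimate`, `std_estimate`, `se`, `p`), `claims`
#'   (data frame with the basis set and p-values), `C`, `df`, `p`, `AIC`
#'   (sum over submodels), `r2_marginal` (per endogenous variable),
#'   `submodels`, `n`.
#' @export
fit_piecewise <- function(data, spec = sem_spec()) {
  stopifnot(inherits(spec, "standiv_sem_spec"))
  cols <- spec$columns
  miss <- setdiff(unname(cols), names(data))
  if (length(miss)) stop("data lacks SEM columns: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  keep <- stats::complete.cases(data[, unname(cols)])
  d <- data[keep, ]
  sds <- vapply(cols, function(cl) sd(d[[cl]]), 0)

  dag <- spec$dag
  endo <- unique(dag$to)
  submodels <- list()
  paths <- list()
  r2 <- numeric()
  for (v in endo) {
    parents <- dag$from[dag$to == v]
    fixed <- unname(cols[parents])
    if (v == "productivity" && spec$interaction != "none") {
      pair <- switch(spec$interaction,
                     richness_structural = c("richness", "structural"),
                     fdis_structural = c("fdis_all", "structural"))
      int_col <- paste0(".int_", paste(pair, collapse = "_"))
      d[[int_col]] <- d[[cols[pair[1]]]] * d[[cols[pair[2]]]]
      fixed <- c(fixed, int_col)
    }
    f <- as.formula(paste(cols[v], "~", paste(c(fixed, .random_terms()),
                                              collapse = " + ")))
    fit <- fit_lmm(f, d)
    submodels[[v]] <- fit
    ct <- fit$coefficients
    for (p_ in parents) {
      row <- ct[ct$term == cols[p_], ]
      paths[[length(paths) + 1L]] <- data.frame(
        from = p_, to = v, estimate = row$estimate,
        std_estimate = standardize_path(row$estimate, sds[p_], sds[v]),
        se = row$se, p = row$p, stringsAsFactors = FALSE)
    }
    if (v == "productivity" && spec$interaction != "none") {
      row <- ct[ct$term == int_col, ]
      paths[[length(paths) + 1L]] <- data.frame(
        from = paste(pair, collapse = ":"), to = v, estimate = row$estimate,
        std_estimate = standardize_path(row$estimate, sd(d[[int_col]]), sds[v]),
        se = row$se, p = row$p, stringsAsFactors = FALSE)
    }
    r2[v] <- marginal_r2(fit)
  }

  claims <- basis_set(dag)
  ctab <- do.call(rbind, lapply(claims, function(cl) {
    fixed <- unname(cols[c(cl$x, cl$cond)])
    f <- as.formula(paste(cols[cl$y], "~", paste(c(fixed, .random_terms()),
                                                 collapse = " + ")))
    fit <- fit_lmm(f, d)
    p <- fit$coefficients$p[fit$coefficients$term == cols[cl$x]]
    data.frame(x = cl$x, y = cl$y,
               conditioning = paste(cl$cond, collapse = ","),
               p = p, stringsAsFactors = FALSE)
  }))
  fc <- if (length(claims)) fishers_c(ctab$p) else list(C = NA_real_, df = 0L, p = NA_real_)
  structure(list(paths = do.call(rbind, paths), claims = ctab,
                 C = fc$C, df = fc$df, p = fc$p,
                 AIC = sum(vapply(submodels, `[[`, 0, "AIC")),
                 r2_marginal = r2, submodels = submodels, n = nrow(d),
                 spec = spec),
            class = "standiv_sem")
}

#' Marginal R-squared of a mixed model
#'
#' Variance of the fixed-effects predictions over the total modeled
#' variance (fixed + summed random-intercept variances + residual
#' variance).
#'
#' @param fit A `standiv_fit` (constant-dispersion).
#' @return Marginal R-squared in `[0, 1]`.
#' @export
marginal_r2 <- function(fit) {
  mu <- predict(fit$model, re.form = NA)
  vf <- var(mu)
  vf / (vf + sum(fit$ranef_var) + fit$sigma2)
}

#' Indirect effect of richness along a named route in a fitted SEM
#'
#' @param sem A `standiv_sem`.
#' @param route Character vector of variable names forming a directed path
#'   in the DAG, e.g. `c("richness", "fdis_all", "productivity")`.
#' @return Product of the standardized path coefficients along the route.
#' @export
sem_indirect <- function(sem, route) {
  stopifnot(inherits(sem, "standiv_sem"), length(route) >= 2)
  key <- paste(sem$paths$from, sem$paths$to)
  steps <- paste(route[-length(route)], route[-1])
  idx <- match(steps, key)
  if (anyNA(idx)) stop("route is not a directed path of the fitted DAG", call. = FALSE)
  indirect_effect(sem$paths$std_estimate[idx])
}

#' @export
print.standiv_sem <- function(x, ...) {
  cat("Piecewise SEM (", x$n, " plots)\n", sep = "")
  cat("\nStandardized paths:\n")
  print(cbind(x$paths[, c("from", "to")],
              round(x$paths[, c("std_estimate", "p")], 4)))
  cat("\nIndependence claims:\n")
  if (nrow(x$claims)) {
    print(cbind(x$claims[, c("x", "y", "conditioning")],
                p = round(x$claims$p, 4)))
    cat(sprintf("\nFisher's C = %.3f, df = %d, p = %.3f\n", x$C, x$df, x$p))
  } else {
    cat("  (saturated model: none)\n")
  }
  cat("AIC (sum over submodels) =", round(x$AIC, 2), "\n")
  cat("Marginal R2:", paste(names(x$r2_marginal),
                            round(x$r2_marginal, 3), sep = "=", collapse = "  "), "\n")
  invisible(x)
}
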