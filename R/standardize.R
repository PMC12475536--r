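# Within-group variable scaling applied per analysis subset.

#' Group-wise z-score transformation
#'
#' Centers and scales values within each group to mean 0 and sample
#' standard deviation 1 (n - 1 denominator). Degenerate groups (zero SD)
#' map to all zeros with a warning rather than dropping observations.
#'
#' @param values Numeric vector.
#' @param groups Grouping vector (e.g. experiment labels); a single group
#'   when omitted.
#' @return Transformed vector, same length and order as `values`.
#' @export
zscore <- function(values, groups = NULL) {
  .scale_by(values, groups, function(x) {
    s <- sd(x)
    if (is.na(s) || s == 0) {
      warning("zero-variance group in z-score: mapped to 0", call. = FALSE)
      rep(0, length(x))
    } else {
      (x - mean(x)) / s
    }
  })
}

#' Group-wise min-max scaling
#'
#' Rescales values within each group to `[0, 1]` by subtracting the group
#' minimum and dividing by the range. Zero-range groups map to zeros with
#' a warning.
#'
#' @inheritParams zscore
#' @return Transformed vector in `[0, 1]`.
#' @export
minmax <- function(values, groups = NULL) {
  .scale_by(values, groups, function(x) {
    r <- range(x)
    if (diff(r) == 0) {
      warning("zero-range group in min-max scaling: mapped to 0", call. = FALSE)
      rep(0, length(x))
    } else {
      (x - r[1]) / diff(r)
    }
  })
}

.scale_by <- function(values, groups, f) {
  if (is.null(groups)) groups <- rep(1L, length(values))
  stopifnot(length(groups) == length(values))
  out <- rep(NA_real_, length(values))
  ok <- !is.na(values)
  for (g in unique(groups[ok])) {
    idx <- ok & groups == g
    out[idx] <- f(values[idx])
  }
  out
}

#' Default scaling rules for the plot-metric table
#'
#' Productivity, CWMs and structural diversity are z-scored within
#' experiment; functional dispersion metrics are min-max scaled within
#' experiment (comparable on a uniform 0-1 scale while preserving relative
#' range); the diversity effects (NBE/SE/CE) are left untransformed since
#' they are already centered on each mixture's own monocultures.
#'
#' @return Data frame with columns `variable`, `method`
#'   (`"zscore"`/`"minmax"`/`"none"`) and `grouping`.
#' @export
default_scaling_rules <- function() {
  data.frame(
    variable = c("productivity", "cwm_WD", "cwm_LNC", "gini_height",
                 "cv_height", "fdis_WD", "fdis_LNC", "fdis_all",
                 "NBE", "SE", "CE"),
    method = c(rep("zscore", 5), rep("minmax", 3), rep("none", 3)),
    grouping = c(rep("within-experiment", 8), rep("none", 3)),
    stringsAsFactors = FALSE
  )
}

#' Apply scaling rules to an analysis subset
#'
#' Adds a `<variable>_std` column for every rule whose variable is present
#' in `data`. Scaling is always recomputed on the rows of `data` itself,
#' so each analysis subset gets its own standardization (never reuse
#' columns standardized on a different subset).
#'
#' @param data Plot-level data frame containing an `experiment` column.
#' @param rules Scaling-rule table, see [default_scaling_rules()].
#' @return `data` with `_std` columns appended.
#' @export
apply_scaling <- function(data, rules = default_scaling_rules()) {
  for (i in seq_len(nrow(rules))) {
    v <- rules$variable[i]
    if (!v %in% names(data)) next
    g <- if (identical(rules$grouping[i], "within-experiment")) data$experiment else NULL
    data[[paste0(v, "_std")]] <- switch(
      rules$method[i],
      zscore = zscore(data[[v]], g),
      minmax = minmax(data[[v]], g),
      none = data[[v]],
      stop("unknown scaling method: ", rules$method[i], call. = FALSE)
    )
  }
  data
}
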