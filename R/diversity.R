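# Functional identity/diversity and structural diversity metrics.

#' Community weighted mean of a trait
#'
#' Abundance-weighted mean trait value, `sum(a_j * x_j) / sum(a_j)`.
#'
#' @param abundances Named numeric vector of species abundances (counts),
#'   all `>= 0`, at least one positive.
#' @param trait Named numeric vector of trait values covering every species
#'   with positive abundance.
#' @return The weighted mean trait value.
#' @export
cwm <- function(abundances, trait) {
  a <- .check_abund(abundances)
  x <- trait[names(a)]
  if (anyNA(x)) stop("trait values missing for some abundant species", call. = FALSE)
  sum(a * x) / sum(a)
}

#' Functional dispersion (FDis)
#'
#' Abundance-weighted mean Euclidean distance of species to the
#' abundance-weighted centroid of trait space (Laliberte & Legendre).
#' Monocultures have FDis 0 by construction.
#'
#' @param abundances Named numeric vector of abundances (counts).
#' @param traits Either a named numeric vector (one trait) or a numeric
#'   matrix with species as rownames and one column per trait. Traits
#'   should already be on a common scale (the pipeline z-scores species
#'   trait values across experiments first).
#' @return Non-negative dispersion in trait-distance units.
#' @export
fdis <- function(abundances, traits) {
  a <- .check_abund(abundances)
  if (is.null(dim(traits))) {
    traits <- matrix(traits, ncol = 1, dimnames = list(names(traits), "trait"))
  }
  x <- traits[names(a), , drop = FALSE]
  if (anyNA(x)) stop("trait values missing for some abundant species", call. = FALSE)
  w <- a / sum(a)
  centroid <- colSums(x * w)
  d <- sqrt(rowSums(sweep(x, 2, centroid)^2))
  sum(w * d)
}

.check_abund <- function(abundances) {
  if (is.null(names(abundances))) stop("abundances must be named by species", call. = FALSE)
  if (any(is.na(abundances) | abundances < 0)) {
    stop("abundances must be non-negative", call. = FALSE)
  }
  a <- abundances[abundances > 0]
  if (length(a) == 0L) stop("all abundances are zero: metric undefined", call. = FALSE)
  a
}

#' Gini coefficient of size inequality
#'
#' Population form `sum_ij |x_i - x_j| / (2 n^2 mean(x))`, without a
#' small-sample correction: 0 for perfectly equal values, approaching 1
#' under extreme inequality. Used here on individual tree heights as a
#' relative structural-diversity metric.
#'
#' @param values Numeric vector (length >= 2, all >= 0, positive mean).
#' @return Gini coefficient in `[0, 1)`.
#' @export
gini <- function(values) {
  x <- .check_heights(values)
  n <- length(x)
  x <- sort(x)
  # sum_ij |x_i - x_j| = 2 * sum_i (2i - n - 1) x_(i)
  g <- 2 * sum((2 * seq_len(n) - n - 1) * x)
  g / (2 * n^2 * mean(x))
}

#' Coefficient of variation
#'
#' Sample standard deviation (n - 1 denominator) over the mean.
#'
#' @inheritParams gini
#' @return Non-negative CV.
#' @export
cv <- function(values) {
  x <- .check_heights(values)
  sd(x) / mean(x)
}

.check_heights <- function(values) {
  x <- values[!is.na(values)]
  if (length(x) < 2L) stop("need at least 2 values", call. = FALSE)
  if (any(x < 0)) stop("values must be >= 0", call. = FALSE)
  if (mean(x) <= 0) stop("zero mean: metric undefined", call. = FALSE)
  x
}

#' Principal component analysis of species traits
#'
#' PCA of the species x trait matrix after z-scoring each trait, used to
#' inspect the correlation structure of the trait syndrome (e.g. an
#' SLA-LNC leaf-economics axis orthogonal to a wood-density axis).
#'
#' @param traits Trait table ([validate_traits()]) or a numeric matrix with
#'   species rownames.
#' @param columns Trait columns to use (default WD, LNC, SLA).
#' @return List with `loadings` (orthonormal, traits x components),
#'   `variance_fraction` (non-increasing, sums to 1) and `scores`.
#' @export
trait_pca <- function(traits, columns = c("WD", "LNC", "SLA")) {
  if (is.data.frame(traits)) {
    m <- as.matrix(traits[, columns])
    rownames(m) <- traits$species
  } else {
    m <- as.matrix(traits)
  }
  if (nrow(m) < ncol(m)) {
    warning("fewer species than traits: PCA is rank deficient", call. = FALSE)
  }
  sds <- apply(m, 2, sd)
  if (any(sds == 0)) stop("degenerate trait matrix: a trait has zero variance", call. = FALSE)
  p <- prcomp(m, center = TRUE, scale. = TRUE)
  list(loadings = p$rotation,
       variance_fraction = p$sdev^2 / sum(p$sdev^2),
       scores = p$x)
}

#' Per-plot productivity and diversity metric table
#'
#' Builds the plot-level analysis table: productivity (annual basal-area
#' increment), community weighted means and functional dispersion of wood
#' density and leaf nitrogen (plus FDis over the full WD/LNC/SLA profile),
#' and the Gini coefficient and CV of tree heights. Species trait values
#' are z-scored across experiments before any FDis computation so that
#' traits contribute on a common scale. Plots with fewer than two measured
#' heights get `NA` structural diversity.
#'
#' @param trees,plots,traits Validated input tables.
#' @param weighting Abundance weighting for CWM/FDis: `"live"` (count of
#'   live trees at inventory, the default) or `"planted"` (design counts).
#' @param include_dead Passed to [plot_productivity()].
#' @return Data frame keyed by (`experiment`, `block`, `plot_id`) with
#'   metric columns `productivity`, `cwm_WD`, `cwm_LNC`, `fdis_WD`,
#'   `fdis_LNC`, `fdis_all`, `gini_height`, `cv_height`, plus `richness`,
#'   `composition`, `n_heights`.
#' @export
plot_metrics <- function(trees, plots, traits,
                         weighting = c("live", "planted"),
                         include_dead = FALSE) {
  weighting <- match.arg(weighting)
  trees <- validate_trees(trees, plots)
  plots <- validate_plots(plots)
  traits <- validate_traits(traits, plots)
  prod <- plot_productivity(trees, plots, include_dead)
  zt <- traits
  for (v in c("WD", "LNC", "SLA")) zt[[paste0(v, "_z")]] <- as.numeric(scale(traits[[v]]))
  zmat <- as.matrix(zt[, c("WD_z", "LNC_z", "SLA_z")])
  rownames(zmat) <- zt$species
  raw <- as.matrix(traits[, c("WD", "LNC")])
  rownames(raw) <- traits$species

  rows <- lapply(seq_len(nrow(plots)), function(i) {
    p <- plots[i, ]
    comp <- parse_composition(as.character(p$composition))
    idx <- trees$plot_id == p$plot_id & as.logical(trees$in_sample)
    if (weighting == "live") {
      live_sp <- trees$species[idx & as.logical(trees$alive)]
      ab <- table(factor(live_sp, levels = names(comp)))
      ab <- setNames(as.numeric(ab), names(comp))
      if (all(ab == 0)) ab <- comp  # fully dead plot: fall back to design counts
    } else {
      ab <- comp
    }
    h <- trees$height_m[idx & as.logical(trees$alive)]
    h <- h[!is.na(h)]
    data.frame(
      cwm_WD = cwm(ab, raw[, "WD"]),
      cwm_LNC = cwm(ab, raw[, "LNC"]),
      fdis_WD = fdis(ab, zmat[, "WD_z"]),
      fdis_LNC = fdis(ab, zmat[, "LNC_z"]),
      fdis_all = fdis(ab, zmat),
      gini_height = if (length(h) >= 2) gini(h) else NA_real_,
      cv_height = if (length(h) >= 2) cv(h) else NA_real_,
      n_heights = length(h)
    )
  })
  out <- cbind(prod, do.call(rbind, rows))
  rownames(out) <- NULL
  out
}
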