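# Additive partitioning of the net diversity effect (Loreau & Hector 2001).

#' Loreau-Hector partition for one mixture
#'
#' Partitions the net biodiversity effect (NBE) of one mixture into
#' complementarity (CE) and selection (SE) components from species-level
#' observed yields `Y_i`, monoculture references `M_i` and planted
#' proportions `p_i`:
#'
#' \deqn{\Delta RY_i = Y_i / M_i - p_i}
#' \deqn{CE = N \,\overline{\Delta RY}\, \overline{M}, \quad
#'       SE = N \,\mathrm{cov}(\Delta RY, M)}
#'
#' with the population covariance (divide by `N`), under which
#' `SE + CE = NBE = sum(Y) - sum(p * M)` holds as an algebraic identity.
#'
#' @param Y Observed per-species yields in the mixture (same units as `M`).
#' @param M Monoculture reference yields, all `> 0`.
#' @param p Planted proportions, summing to 1.
#' @return List with `NBE`, `SE`, `CE`, `expected`, `observed` and the
#'   per-species `deltaRY`.
#' @export
partition_plot <- function(Y, M, p) {
  n <- length(Y)
  if (length(M) != n || length(p) != n) stop("Y, M, p must have equal length", call. = FALSE)
  if (n < 2L) stop("partition requires at least 2 species", call. = FALSE)
  if (any(is.na(M)) || any(M <= 0)) {
    stop("monoculture reference must be positive for every species", call. = FALSE)
  }
  if (abs(sum(p) - 1) > 1e-8) stop("proportions must sum to 1", call. = FALSE)
  dRY <- Y / M - p
  cov_pop <- mean(dRY * M) - mean(dRY) * mean(M)
  CE <- n * mean(dRY) * mean(M)
  SE <- n * cov_pop
  list(NBE = sum(Y) - sum(p * M), SE = SE, CE = CE,
       expected = sum(p * M), observed = sum(Y), deltaRY = dRY)
}

#' Monoculture reference productivities
#'
#' Mean productivity of each species over its monoculture plots, pooled
#' across blocks within each experiment.
#'
#' @param prod Plot productivity table ([plot_productivity()]).
#' @return Data frame with `experiment`, `species`, `M` (mean monoculture
#'   productivity) and `n_mono` (number of monoculture plots).
#' @export
monoculture_reference <- function(prod) {
  mono <- prod[prod$richness == 1L, ]
  if (nrow(mono) == 0L) {
    return(data.frame(experiment = character(), species = character(),
                      M = numeric(), n_mono = integer()))
  }
  mono$species <- vapply(as.character(mono$composition),
                         function(x) names(parse_composition(x))[1], "")
  agg <- aggregate(productivity ~ experiment + species, data = mono,
                   FUN = mean)
  cnt <- aggregate(productivity ~ experiment + species, data = mono,
                   FUN = length)
  names(agg)[3] <- "M"
  agg$n_mono <- cnt$productivity
  agg
}

#' Expected mixture productivity from monocultures
#'
#' Weighted mean of the component species' monoculture productivities,
#' weights being the planted proportions: `sum(p_i * M_i)`.
#'
#' @param p Named vector of planted proportions (summing to 1).
#' @param M Named vector of monoculture productivities covering `names(p)`.
#' @return Expected productivity (same units as `M`).
#' @export
expected_productivity <- function(p, M) {
  if (abs(sum(p) - 1) > 1e-8) stop("proportions must sum to 1", call. = FALSE)
  m <- M[names(p)]
  if (anyNA(m)) stop("monoculture reference missing for some species", call. = FALSE)
  sum(p * m)
}

#' Partition diversity effects for every mixture plot
#'
#' Runs the Loreau-Hector partition across all mixture plots of all
#' experiments. Per-species observed yields come from
#' [species_productivity()]; monoculture references from
#' [monoculture_reference()] within the same experiment; proportions from
#' planted counts by default. Mixtures containing a species with no
#' monoculture (or a zero monoculture reference) are flagged missing, not
#' zero.
#'
#' @param trees,plots Validated input tables.
#' @param proportions `"planted"` (design counts, default) or
#'   `"surviving"` (live counts at inventory).
#' @param include_dead Passed to the productivity computations.
#' @return Data frame with one row per mixture plot: `experiment`, `block`,
#'   `plot_id`, `richness`, `expected`, `observed`, `NBE`, `SE`, `CE`, and
#'   logical `complete` (FALSE when a monoculture reference was missing; in
#'   that case the effect columns are NA). The per-species long table
#'   (`species`, `M`, `deltaRY`) is attached as attribute `"species"`.
#' @export
partition_diversity_effects <- function(trees, plots,
                                        proportions = c("planted", "surviving"),
                                        include_dead = FALSE) {
  proportions <- match.arg(proportions)
  plots <- validate_plots(plots)
  prod <- plot_productivity(trees, plots, include_dead)
  spp <- species_productivity(trees, plots, include_dead)
  mono <- monoculture_reference(prod)
  mix <- plots[plots$richness >= 2L, ]
  long <- list()
  rows <- lapply(seq_len(nrow(mix)), function(i) {
    p <- mix[i, ]
    sp <- spp[spp$plot_id == p$plot_id, ]
    cnt <- if (proportions == "planted") sp$planted_count else sp$live_count
    prop <- cnt / sum(cnt)
    m <- mono$M[match(paste(p$experiment, sp$species),
                      paste(mono$experiment, mono$species))]
    base <- data.frame(experiment = p$experiment, block = p$block,
                       plot_id = p$plot_id, richness = p$richness)
    if (anyNA(m) || any(m <= 0, na.rm = TRUE) || any(is.na(prop))) {
      return(cbind(base, expected = NA_real_, observed = NA_real_,
                   NBE = NA_real_, SE = NA_real_, CE = NA_real_,
                   complete = FALSE))
    }
    pr <- partition_plot(sp$productivity, m, prop)
    long[[length(long) + 1L]] <<- data.frame(
      plot_id = p$plot_id, species = sp$species, M = m,
      proportion = prop, Y = sp$productivity, deltaRY = pr$deltaRY)
    cbind(base, expected = pr$expected, observed = pr$observed,
          NBE = pr$NBE, SE = pr$SE, CE = pr$CE, complete = TRUE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(experiment = character(), block = character(),
                      plot_id = character(), richness = integer(),
                      expected = numeric(), observed = numeric(),
                      NBE = numeric(), SE = numeric(), CE = numeric(),
                      complete = logical())
  }
  rownames(out) <- NULL
  attr(out, "species") <- if (length(long)) do.call(rbind, long) else NULL
  out
}
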