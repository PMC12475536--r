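# Tree inventory data model and basal-area productivity.
#
# Unit conventions are fixed across the package: stem diameters in cm,
# heights in m, plot areas in ha, basal area in m^2, productivity in
# m^2 ha^-1 yr^-1.

#' Basal-area-equivalent diameter of a multi-stemmed tree
#'
#' Collapses the stem diameters of one tree into the single diameter whose
#' cross-sectional (basal) area equals the sum of the per-stem basal areas,
#' i.e. `sqrt(sum(d_i^2))`. For a single-stemmed tree this is the identity.
#'
#' @param stems Numeric vector of stem diameters (cm), all `> 0`.
#' @return Equivalent diameter in cm (length 1).
#' @examples
#' equivalent_diameter(c(3, 4)) # 5
#' @export
equivalent_diameter <- function(stems) {
  if (length(stems) == 0L || anyNA(stems)) {
    stop("`stems` must be a non-empty numeric vector without NA", call. = FALSE)
  }
  if (any(stems <= 0)) {
    stop("all stem diameters must be > 0", call. = FALSE)
  }
  sqrt(sum(stems^2))
}

#' Basal area of a tree from its diameter
#'
#' `pi * (diameter / 200)^2`: cross-sectional area in m^2 of a stem of the
#' given diameter in cm (the factor 200 converts a cm diameter to an m
#' radius).
#'
#' @param diameter Numeric vector of diameters (cm), all `> 0`.
#' @return Basal area(s) in m^2.
#' @examples
#' tree_basal_area(200) # pi
#' @export
tree_basal_area <- function(diameter) {
  if (length(diameter) == 0L || anyNA(diameter) || any(diameter <= 0)) {
    stop("`diameter` must be positive and non-missing", call. = FALSE)
  }
  pi * (diameter / 200)^2
}

# Parse a composition string "SpA:12;SpB:12" into a named integer vector.
#' Parse a plot composition string
#'
#' Compositions are stored in plot tables as `"species:count"` pairs
#' separated by `";"`. Returns the planted counts as a named vector.
#'
#' @param x A single composition string.
#' @return Named numeric vector of planted counts per species.
#' @export
parse_composition <- function(x) {
  stopifnot(is.character(x), length(x) == 1L, nzchar(x))
  parts <- strsplit(x, ";", fixed = TRUE)[[1]]
  kv <- strsplit(parts, ":", fixed = TRUE)
  bad <- vapply(kv, length, 1L) != 2L
  if (any(bad)) stop("malformed composition string: ", x, call. = FALSE)
  counts <- as.numeric(vapply(kv, `[`, "", 2L))
  names(counts) <- vapply(kv, `[`, "", 1L)
  if (anyNA(counts) || any(counts <= 0)) {
    stop("composition counts must be positive numbers: ", x, call. = FALSE)
  }
  counts
}

#' Format a composition vector as a string
#' @param counts Named numeric vector of planted counts.
#' @return A `"species:count;..."` string with species sorted alphabetically.
#' @export
format_composition <- function(counts) {
  counts <- counts[order(names(counts))]
  paste(paste0(names(counts), ":", counts), collapse = ";")
}

#' Validate a tree inventory table
#'
#' Checks the schema and invariants of a tree table: required columns,
#' positive stem diameters for live trees, positive heights where present,
#' and (when `plots` is supplied) that every tree references a known plot.
#'
#' @param trees Data frame with columns `tree_id`, `plot_id`, `species`,
#'   `stems` (semicolon-separated diameters in cm), `height_m` (may be NA),
#'   `alive` (logical), `in_sample` (logical).
#' @param plots Optional plot design table ([validate_plots()]).
#' @return `trees`, invisibly, with a `diameter` column added (equivalent
#'   diameter per tree; NA for dead trees without stems).
#' @export
validate_trees <- function(trees, plots = NULL) {
  req <- c("tree_id", "plot_id", "species", "stems", "height_m", "alive", "in_sample")
  miss <- setdiff(req, names(trees))
  if (length(miss)) stop("tree table lacks columns: ", paste(miss, collapse = ", "), call. = FALSE)
  if (anyDuplicated(trees$tree_id)) stop("duplicated tree_id values", call. = FALSE)
  stems <- lapply(strsplit(as.character(trees$stems), ";", fixed = TRUE), as.numeric)
  live <- as.logical(trees$alive)
  empty <- vapply(stems, function(s) length(s) == 0L || all(is.na(s)), TRUE)
  if (any(live & empty)) stop("live trees must have at least one stem diameter", call. = FALSE)
  bad <- vapply(stems, function(s) any(!is.na(s) & s <= 0), TRUE)
  if (any(bad)) stop("stem diameters must be > 0", call. = FALSE)
  h <- trees$height_m
  if (any(!is.na(h) & h <= 0)) stop("heights must be > 0 where present", call. = FALSE)
  if (!is.null(plots)) {
    unknown <- setdiff(unique(trees$plot_id), plots$plot_id)
    if (length(unknown)) {
      stop("trees reference unknown plots: ", paste(unknown, collapse = ", "), call. = FALSE)
    }
  }
  trees$diameter <- vapply(stems, function(s) {
    s <- s[!is.na(s)]
    if (length(s) == 0L) NA_real_ else equivalent_diameter(s)
  }, 0)
  invisible(trees)
}

#' Validate a plot design table
#'
#' @param plots Data frame with columns `plot_id`, `experiment`, `block`,
#'   `composition` (see [parse_composition()]), `area_ha`, `sampled_fraction`,
#'   `age_years`. Optional columns: `abiotic_treatment` (anything other
#'   than `"none"` marks plots with extra manipulations) and
#'   `height_lag_years` (time between height and diameter inventories).
#' @return `plots`, invisibly, with a derived integer `richness` column.
#' @export
validate_plots <- function(plots) {
  req <- c("plot_id", "experiment", "block", "composition", "area_ha",
           "sampled_fraction", "age_years")
  miss <- setdiff(req, names(plots))
  if (length(miss)) stop("plot table lacks columns: ", paste(miss, collapse = ", "), call. = FALSE)
  if (anyDuplicated(plots$plot_id)) stop("duplicated plot_id values", call. = FALSE)
  if (any(plots$area_ha <= 0)) stop("area_ha must be > 0", call. = FALSE)
  if (any(plots$age_years <= 0)) stop("age_years must be > 0", call. = FALSE)
  sf <- plots$sampled_fraction
  if (any(sf <= 0 | sf > 1)) stop("sampled_fraction must be in (0, 1]", call. = FALSE)
  comps <- lapply(as.character(plots$composition), parse_composition)
  plots$richness <- vapply(comps, function(x) length(unique(names(x))), 0L)
  invisible(plots)
}

#' Validate a species trait table
#'
#' @param traits Data frame with columns `species`, `WD` (g cm^-3),
#'   `LNC` (%), `SLA` (cm^2 g^-1), `class` (`"angiosperm"` or
#'   `"gymnosperm"`), `provenance` (`"measured"` or `"literature"`).
#' @param plots Optional plot table; when given, every species planted in
#'   any composition must have a trait row.
#' @return `traits`, invisibly.
#' @export
validate_traits <- function(traits, plots = NULL) {
  req <- c("species", "WD", "LNC", "SLA", "class")
  miss <- setdiff(req, names(traits))
  if (length(miss)) stop("trait table lacks columns: ", paste(miss, collapse = ", "), call. = FALSE)
  if (anyDuplicated(traits$species)) stop("duplicated species in trait table", call. = FALSE)
  num <- c("WD", "LNC", "SLA")
  for (v in num) {
    if (any(is.na(traits[[v]]) | traits[[v]] <= 0)) {
      stop("trait ", v, " must be positive and non-missing", call. = FALSE)
    }
  }
  if (!all(traits$class %in% c("angiosperm", "gymnosperm"))) {
    stop("class must be 'angiosperm' or 'gymnosperm'", call. = FALSE)
  }
  if (!is.null(plots)) {
    planted <- unique(unlist(lapply(as.character(plots$composition),
                                    function(x) names(parse_composition(x)))))
    miss <- setdiff(planted, traits$species)
    if (length(miss)) {
      stop("species without trait rows: ", paste(miss, collapse = ", "), call. = FALSE)
    }
  }
  invisible(traits)
}

#' Read inventory tables from CSV
#'
#' Thin readers around [utils::read.csv()] for the three input tables.
#' Unknown columns are retained but ignored downstream; lines starting with
#' `#` are treated as comments.
#'
#' @param path Path to a CSV file.
#' @return The validated table (see the corresponding `validate_*()`).
#' @name inventory-io
NULL

#' @rdname inventory-io
#' @export
read_trees <- function(path) {
  validate_trees(read.csv(path, comment.char = "#", stringsAsFactors = FALSE))
}

#' @rdname inventory-io
#' @export
read_plots <- function(path) {
  validate_plots(read.csv(path, comment.char = "#", stringsAsFactors = FALSE))
}

#' @rdname inventory-io
#' @export
read_traits <- function(path) {
  validate_traits(read.csv(path, comment.char = "#", stringsAsFactors = FALSE))
}

#' Write a table to CSV with a provenance header
#'
#' @param x Data frame to write.
#' @param path Output path.
#' @param comment Optional character vector written as `#`-prefixed header
#'   lines (e.g. the pipeline seed).
#' @export
write_table <- function(x, path, comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  write.csv(x, con, row.names = FALSE)
  invisible(path)
}

# Per-tree basal areas counted towards the plot sum: live, in-sample trees
# (dead trees contribute zero unless include_dead, in which case their
# last-known size is used where available).
.tree_ba_contrib <- function(trees, include_dead = FALSE) {
  keep <- as.logical(trees$in_sample) &
    (as.logical(trees$alive) | (include_dead & !is.na(trees$diameter)))
  ba <- numeric(nrow(trees))
  if (any(keep)) ba[keep] <- tree_basal_area(trees$diameter[keep])
  ba
}

#' Plot productivity: annual basal-area increment per hectare
#'
#' Sums the basal areas of live, in-sample trees in each plot, adjusts for
#' partial sampling (dividing by `sampled_fraction`), scales to a hectare
#' and divides by stand age. Dead trees contribute zero basal area by
#' default, so mortality lowers the plot sum; set `include_dead = TRUE` to
#' retain the last measured size of dead trees.
#'
#' @param trees Tree table (validated; see [validate_trees()]).
#' @param plots Plot table (validated).
#' @param include_dead Count dead trees at their last-known diameter?
#' @return Data frame keyed by (`experiment`, `block`, `plot_id`) with
#'   columns `richness`, `composition`, `age_years`, `productivity`
#'   (m^2 ha^-1 yr^-1).
#' @export
plot_productivity <- function(trees, plots, include_dead = FALSE) {
  trees <- validate_trees(trees, plots)
  plots <- validate_plots(plots)
  ba <- .tree_ba_contrib(trees, include_dead)
  tot <- tapply(ba, factor(trees$plot_id, levels = plots$plot_id), sum, default = 0)
  out <- plots[, c("experiment", "block", "plot_id", "composition", "richness",
                   "age_years")]
  out$productivity <- as.numeric(tot) / plots$sampled_fraction /
    plots$area_ha / plots$age_years
  rownames(out) <- NULL
  out
}

#' Per-species productivity within plots
#'
#' Decomposes [plot_productivity()] by species: same scaling, restricted to
#' each planted species in turn. Species planted but with no surviving
#' trees get zero. Within every plot the species values sum exactly to the
#' plot productivity.
#'
#' @inheritParams plot_productivity
#' @return Long data frame keyed by (`experiment`, `block`, `plot_id`,
#'   `species`) with `planted_count`, `live_count` and `productivity`.
#' @export
species_productivity <- function(trees, plots, include_dead = FALSE) {
  trees <- validate_trees(trees, plots)
  plots <- validate_plots(plots)
  ba <- .tree_ba_contrib(trees, include_dead)
  out <- do.call(rbind, lapply(seq_len(nrow(plots)), function(i) {
    p <- plots[i, ]
    comp <- parse_composition(as.character(p$composition))
    idx <- trees$plot_id == p$plot_id
    extra <- setdiff(unique(trees$species[idx]), names(comp))
    if (length(extra)) {
      stop("plot ", p$plot_id, " contains unplanted species: ",
           paste(extra, collapse = ", "), call. = FALSE)
    }
    sp <- names(comp)
    ba_sp <- vapply(sp, function(s) sum(ba[idx & trees$species == s]), 0)
    live <- vapply(sp, function(s) {
      sum(idx & trees$species == s & as.logical(trees$alive) &
            as.logical(trees$in_sample))
    }, 0L)
    data.frame(experiment = p$experiment, block = p$block, plot_id = p$plot_id,
               species = sp, planted_count = as.numeric(comp),
               live_count = as.integer(live),
               productivity = ba_sp / p$sampled_fraction / p$area_ha / p$age_years,
               row.names = NULL)
  }))
  rownames(out) <- NULL
  out
}
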