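# Independent brute-force oracles and tiny hand-built fixtures.
# These deliberately avoid the package's own code paths.

# Pairwise-sum Gini (population denominator).
gini_brute <- function(x) {
  n <- length(x)
  s <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) s <- s + abs(x[i] - x[j])
  s / (2 * n^2 * mean(x))
}

# FDis by expanding species counts into individuals: per-individual mean
# Euclidean distance to the individual-level centroid.
fdis_brute <- function(counts, traits) {
  if (is.null(dim(traits))) traits <- matrix(traits, ncol = 1,
                                             dimnames = list(names(traits), "t"))
  idx <- rep(names(counts), counts)
  m <- traits[idx, , drop = FALSE]
  cen <- colMeans(m)
  mean(sqrt(rowSums(sweep(m, 2, cen)^2)))
}

cwm_brute <- function(counts, trait) {
  idx <- rep(names(counts), counts)
  mean(trait[idx])
}

# Hand-built inventory: one experiment, two species, two monocultures and
# one 50/50 mixture. Diameters chosen so per-plot basal areas are exact.
tiny_inventory <- function(ba_A_mono = 0.05, ba_B_mono = 0.01,
                           ba_A_mix = 0.03, ba_B_mix = 0.02,
                           area_ha = 0.01, age = 10, sampled = 1) {
  d_of_ba <- function(ba) 200 * sqrt(ba / pi)  # invert basal-area formula
  trees <- data.frame(
    tree_id = paste0("t", 1:4),
    plot_id = c("pA", "pB", "pM", "pM"),
    species = c("A", "B", "A", "B"),
    stems = sprintf("%.10f", d_of_ba(c(ba_A_mono, ba_B_mono, ba_A_mix, ba_B_mix))),
    height_m = c(6, 4, 7, 5),
    alive = TRUE, in_sample = TRUE,
    stringsAsFactors = FALSE
  )
  plots <- data.frame(
    plot_id = c("pA", "pB", "pM"),
    experiment = "E1", block = c("b1", "b1", "b1"),
    composition = c("A:10", "B:10", "A:5;B:5"),
    area_ha = area_ha, sampled_fraction = sampled, age_years = age,
    stringsAsFactors = FALSE
  )
  traits <- data.frame(
    species = c("A", "B"),
    WD = c(0.4, 0.7), LNC = c(2.5, 1.5), SLA = c(180, 110),
    class = c("angiosperm", "gymnosperm"), provenance = "measured",
    stringsAsFactors = FALSE
  )
  list(trees = trees, plots = plots, traits = traits)
}
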