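test_that("equivalent diameter conserves summed basal area", {
  expect_equal(equivalent_diameter(c(3, 4)), 5)
  expect_equal(equivalent_diameter(7.3), 7.3)
  expect_equal(equivalent_diameter(c(1, 1, 1, 1)), 2)
  set.seed(42)
  for (i in 1:50) {
    stems <- runif(sample(1:5, 1), 0.5, 40)
    D <- equivalent_diameter(stems)
    expect_equal(pi * (D / 2)^2, sum(pi * (stems / 2)^2), tolerance = 1e-12)
  }
  expect_error(equivalent_diameter(numeric()), "non-empty")
  expect_error(equivalent_diameter(c(3, -1)), "> 0")
  expect_error(equivalent_diameter(c(3, 0)), "> 0")
})

test_that("tree basal area follows pi (d/200)^2", {
  expect_equal(tree_basal_area(200), pi)
  expect_equal(tree_basal_area(20), pi * 0.1^2)
  expect_equal(tree_basal_area(c(200, 20)), c(pi, 0.0314159265))
  expect_error(tree_basal_area(0))
  expect_error(tree_basal_area(-5))
})

test_that("composition strings round-trip", {
  comp <- c(B = 12, A = 13)
  s <- format_composition(comp)
  expect_equal(s, "A:13;B:12")
  expect_equal(parse_composition(s), c(A = 13, B = 12))
  expect_error(parse_composition("A:3;B"), "malformed")
  expect_error(parse_composition("A:0"), "positive")
})

test_that("plot productivity scales by area, age and sampled fraction", {
  fx <- tiny_inventory(ba_A_mono = 0.05, area_ha = 0.01, age = 10)
  prod <- plot_productivity(fx$trees, fx$plots)
  expect_equal(prod$productivity[prod$plot_id == "pA"], 0.5)
  # half the plot sampled -> doubled estimate
  fx2 <- tiny_inventory(sampled = 0.5)
  prod2 <- plot_productivity(fx2$trees, fx2$plots)
  expect_equal(prod2$productivity[prod2$plot_id == "pA"], 1.0)
  # no live trees -> zero
  fx$trees$alive <- FALSE
  prod0 <- plot_productivity(fx$trees, fx$plots)
  expect_equal(prod0$productivity, rep(0, 3))
})

test_that("dead trees are excluded unless include_dead", {
  fx <- tiny_inventory()
  fx$trees$alive[fx$trees$tree_id == "t1"] <- FALSE
  p_excl <- plot_productivity(fx$trees, fx$plots)
  expect_equal(p_excl$productivity[p_excl$plot_id == "pA"], 0)
  p_incl <- plot_productivity(fx$trees, fx$plots, include_dead = TRUE)
  expect_equal(p_incl$productivity[p_incl$plot_id == "pA"], 0.5)
})

test_that("species productivity sums exactly to plot productivity", {
  fx <- tiny_inventory(ba_A_mix = 0.03, ba_B_mix = 0.02)
  spp <- species_productivity(fx$trees, fx$plots)
  prod <- plot_productivity(fx$trees, fx$plots)
  mix <- spp[spp$plot_id == "pM", ]
  expect_equal(sum(mix$productivity), prod$productivity[prod$plot_id == "pM"])
  expect_equal(mix$productivity[mix$species == "A"] /
                 mix$productivity[mix$species == "B"], 3 / 2)
  # species planted but fully dead contributes zero
  fx$trees$alive[fx$trees$species == "B"] <- FALSE
  spp2 <- species_productivity(fx$trees, fx$plots)
  expect_equal(spp2$productivity[spp2$plot_id == "pM" & spp2$species == "B"], 0)

  # generated data: additivity holds on every plot
  gen <- generate_experiments(generator_config(n_experiments = 2), seed = 3)
  spp3 <- species_productivity(gen$trees, gen$plots)
  prod3 <- plot_productivity(gen$trees, gen$plots)
  sums <- tapply(spp3$productivity, spp3$plot_id, sum)
  expect_equal(as.numeric(sums[prod3$plot_id]), prod3$productivity,
               tolerance = 1e-12)
})

test_that("productivity is invariant to tree order and linear in 1/age", {
  gen <- generate_experiments(generator_config(n_experiments = 1), seed = 5)
  p1 <- plot_productivity(gen$trees, gen$plots)
  set.seed(1)
  p2 <- plot_productivity(gen$trees[sample(nrow(gen$trees)), ], gen$plots)
  expect_equal(p1$productivity, p2$productivity)
  plots2 <- gen$plots
  plots2$age_years <- plots2$age_years * 3
  p3 <- plot_productivity(gen$trees, plots2)
  expect_equal(p3$productivity * 3, p1$productivity)
})

test_that("validation catches schema and consistency errors", {
  fx <- tiny_inventory()
  bad <- fx$trees
  bad$plot_id[1] <- "nonexistent"
  expect_error(validate_trees(bad, fx$plots), "unknown plots")
  badp <- fx$plots
  badp$sampled_fraction[1] <- 1.2
  expect_error(validate_plots(badp), "sampled_fraction")
  expect_error(validate_traits(fx$traits[-1, ], fx$plots), "without trait rows")
  expect_equal(validate_plots(fx$plots)$richness, c(1L, 1L, 2L))
})

test_that("CSV readers round-trip the inventory tables", {
  fx <- tiny_inventory()
  td <- withr::local_tempdir()
  write_table(fx$trees, file.path(td, "trees.csv"), comment = "seed 1")
  write_table(fx$plots, file.path(td, "plots.csv"))
  write_table(fx$traits, file.path(td, "traits.csv"))
  tr <- read_trees(file.path(td, "trees.csv"))
  expect_equal(tr$tree_id, fx$trees$tree_id)
  pl <- read_plots(file.path(td, "plots.csv"))
  expect_equal(pl$composition, fx$plots$composition)
  ta <- read_traits(file.path(td, "traits.csv"))
  expect_equal(ta$WD, fx$traits$WD)
})
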