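# Synthetic tree-diversity experiments with known ground truth.
#
# The generator emulates the design of networked planted biodiversity
# experiments: several experiments with their own species pools and site
# conditions, blocks, replicated monocultures and mixtures along a 1-6
# richness gradient, trait-linked species growth, a mixing response that
# can be tuned between selection- and complementarity-dominated regimes,
# mortality, multi-stemmed trees, and a height-diameter allometry.

#' Generator configuration
#'
#' All knobs of the synthetic experiment generator, with defaults chosen
#' to resemble a young (9-year) planted diversity trial network: 10 x 10 m
#' plots planted with 25 trees, species pools of 8, richness levels 1-6.
#'
#' The per-tree annual diameter increment is
#' `g_s * site * block * plot * mix_s(r) * lognormal-noise`, where the
#' species baseline `g_s = g0 * exp(gamma_LNC * z(LNC) - gamma_WD * z(WD))`
#' rises with leaf nitrogen and falls with wood density, and the mixing
#' multiplier
#' `mix_s(r) = 1 + (s * acq_s + k * FDis_plot) * (1 - exp(-(r - 1) / tau))`
#' saturates with richness `r` and vanishes in monocultures. The
#' acquisitiveness score `acq_s = z(LNC) - z(WD)` makes the selection term
#' `s` boost species that are already fast growers (a selection-effect
#' mechanism), while `k` lifts all species in functionally dispersed plots
#' (a complementarity mechanism).
#'
#' @param n_experiments Number of experiments (independent sites/pools).
#' @param pool_size Species-pool size per experiment.
#' @param richness_levels Richness levels planted (subset of 1-6; must
#'   include 1 so partitions have monoculture references).
#' @param mixtures_per_richness Distinct random compositions per mixture
#'   richness level.
#' @param blocks Blocks per experiment (every composition planted once per
#'   block).
#' @param trees_per_plot Planted trees per plot.
#' @param area_ha Plot area (ha).
#' @param age_years Years since establishment.
#' @param sampled_fraction Fraction of each plot that is inventoried.
#' @param trait_mean,trait_sd Means/SDs of WD (g cm^-3), LNC (%), SLA
#'   (cm^2 g^-1) in the species pool.
#' @param cor_sla_lnc,cor_wd_lnc,cor_wd_sla Trait correlations (the
#'   leaf-economics pair SLA-LNC strongly positive; WD a largely
#'   independent axis).
#' @param g0 Baseline annual diameter increment (cm yr^-1).
#' @param gamma_lnc,gamma_wd Log-scale trait effects on species growth.
#' @param species_sd,site_sd,block_sd,plot_sd,tree_sd Lognormal noise SDs
#'   of the growth multipliers at each level.
#' @param s Selection strength of the mixing response.
#' @param k Complementarity strength of the mixing response.
#' @param tau Richness-saturation scale of the mixing response.
#' @param disp_slope Slope of log plot-level residual variance on
#'   richness (negative: more diverse stands are more predictable).
#' @param mortality_p Per-tree death probability by the inventory.
#' @param multistem_p Probability a tree is multi-stemmed.
#' @param height_a,height_b,height_sd Height allometry `h = a * d^b` (d in
#'   cm, h in m) with lognormal noise.
#' @param gymnosperm_p Probability a species is a gymnosperm.
#' @return A `standiv_gen_config` list.
#' @export
generator_config <- function(n_experiments = 6,
                             pool_size = 8,
                             richness_levels = 1:6,
                             mixtures_per_richness = 2,
                             blocks = 2,
                             trees_per_plot = 25,
                             area_ha = 0.01,
                             age_years = 9,
                             sampled_fraction = 1,
                             trait_mean = c(WD = 0.55, LNC = 2.0, SLA = 150),
                             trait_sd = c(WD = 0.12, LNC = 0.5, SLA = 40),
                             cor_sla_lnc = 0.68,
                             cor_wd_lnc = -0.1,
                             cor_wd_sla = -0.1,
                             g0 = 0.9,
                             gamma_lnc = 0.25,
                             gamma_wd = 0.25,
                             species_sd = 0.1,
                             site_sd = 0.3,
                             block_sd = 0.08,
                             plot_sd = 0.1,
                             tree_sd = 0.25,
                             s = 0,
                             k = 0,
                             tau = 2,
                             disp_slope = 0,
                             mortality_p = 0.1,
                             multistem_p = 0.08,
                             height_a = 1.1,
                             height_b = 0.85,
                             height_sd = 0.12,
                             gymnosperm_p = 0.3) {
  cfg <- as.list(environment())
  if (!1 %in% cfg$richness_levels) {
    stop("richness_levels must include 1 (monocultures)", call. = FALSE)
  }
  if (max(cfg$richness_levels) > cfg$pool_size) {
    stop("infeasible design: richness exceeds the species pool", call. = FALSE)
  }
  R <- matrix(c(1, cor_wd_lnc, cor_wd_sla,
                cor_wd_lnc, 1, cor_sla_lnc,
                cor_wd_sla, cor_sla_lnc, 1), 3, 3)
  if (any(eigen(R, only.values = TRUE)$values <= 0)) {
    stop("trait correlations are not positive definite", call. = FALSE)
  }
  probs <- c(sampled_fraction, mortality_p, multistem_p, gymnosperm_p)
  if (any(probs < 0 | probs > 1) || sampled_fraction == 0) {
    stop("probabilities must lie in [0, 1] (sampled_fraction in (0, 1])", call. = FALSE)
  }
  structure(cfg, class = "standiv_gen_config")
}

#' Named generator scenarios
#'
#' Preset configurations with known mixing regimes:
#' * `"null"`: no mixing response (`s = k = 0`) -- diversity effects are
#'   zero in expectation;
#' * `"selection"`: pure selection regime (`s > 0`, `k = 0`) -- mixtures
#'   gain because acquisitive fast growers are boosted;
#' * `"complementarity"`: pure complementarity regime (`s = 0`, `k > 0`);
#' * `"paper_like"`: both mechanisms with a selection-dominated split
#'   (expected SE share of the net effect roughly 0.6-0.9), a saturating
#'   richness-productivity response, and residual variance shrinking with
#'   richness.
#'
#' @param name Scenario name.
#' @param ... Overrides passed to [generator_config()].
#' @return A `standiv_gen_config`.
#' @export
scenario_config <- function(name = c("null", "selection", "complementarity",
                                     "paper_like"), ...) {
  name <- match.arg(name)
  args <- switch(name,
    null = list(),
    selection = list(s = 0.35, k = 0),
    complementarity = list(s = 0, k = 0.3),
    paper_like = list(s = 0.3, k = 0.015, disp_slope = -0.03,
                      n_experiments = 12)
  )
  cfg <- do.call(generator_config, utils::modifyList(args, list(...)))
  attr(cfg, "scenario") <- name
  cfg
}

# Draw one species pool: traits (truncated multivariate normal on the
# WD/LNC/SLA syndrome), class labels, baseline growth and acquisitiveness.
.draw_pool <- function(cfg, experiment) {
  n <- cfg$pool_size
  R <- matrix(c(1, cfg$cor_wd_lnc, cfg$cor_wd_sla,
                cfg$cor_wd_lnc, 1, cfg$cor_sla_lnc,
                cfg$cor_wd_sla, cfg$cor_sla_lnc, 1), 3, 3)
  z <- matrix(rnorm(3 * n), n, 3) %*% chol(R)
  traits <- data.frame(
    species = sprintf("%s_sp%02d", experiment, seq_len(n)),
    WD = pmax(cfg$trait_mean["WD"] + cfg$trait_sd["WD"] * z[, 1], 0.15),
    LNC = pmax(cfg$trait_mean["LNC"] + cfg$trait_sd["LNC"] * z[, 2], 0.4),
    SLA = pmax(cfg$trait_mean["SLA"] + cfg$trait_sd["SLA"] * z[, 3], 30),
    class = ifelse(runif(n) < cfg$gymnosperm_p, "gymnosperm", "angiosperm"),
    provenance = "measured",
    stringsAsFactors = FALSE
  )
  zl <- as.numeric(scale(traits$LNC))
  zw <- as.numeric(scale(traits$WD))
  traits$g <- cfg$g0 * exp(cfg$gamma_lnc * zl - cfg$gamma_wd * zw +
                             rnorm(n, 0, cfg$species_sd))
  traits$acq <- zl - zw
  traits
}

# Equal-split planted counts for r species over n planting positions.
.split_counts <- function(n, r) {
  base <- rep(n %/% r, r)
  extra <- n %% r
  if (extra > 0) base[seq_len(extra)] <- base[seq_len(extra)] + 1L
  base
}

#' Generate a synthetic experiment network
#'
#' Draws trees, plots and traits tables conforming to the inventory
#' schemas, plus a ground-truth record. Each experiment consumes its own
#' random stream derived from the master seed, so adding experiments never
#' perturbs existing ones; the same config and seed always reproduce
#' byte-identical tables.
#'
#' The truth record contains the injected parameters and, per mixture
#' plot, the deterministic (noise- and mortality-free) expected
#' NBE/SE/CE under the generator's own growth model.
#'
#' @param config A `standiv_gen_config`.
#' @param seed Integer master seed (mandatory).
#' @return List with `trees`, `plots`, `traits` (validated data frames)
#'   and `truth` (list: `config`, `seed`, `species` with baseline growth
#'   and acquisitiveness, `plots` with expected effects, `se_share` --
#'   the expected selection share sum(SE)/sum(NBE) over mixture plots,
#'   or NA when the expected net effect is 0 -- and `se_share_band`, the
#'   scenario's tolerance band on the realized share).
#' @export
generate_experiments <- function(config, seed) {
  stopifnot(inherits(config, "standiv_gen_config"))
  if (missing(seed)) stop("a master seed is mandatory", call. = FALSE)
  cfg <- config
  trees <- list(); plots <- list(); traits <- list(); truth_plots <- list()
  species_truth <- list()
  for (e in seq_len(cfg$n_experiments)) {
    exp_id <- sprintf("E%02d", e)
    set.seed((seed * 1009L + e * 7919L) %% .Machine$integer.max)
    pool <- .draw_pool(cfg, exp_id)
    traits[[e]] <- pool[, c("species", "WD", "LNC", "SLA", "class", "provenance")]
    species_truth[[e]] <- data.frame(experiment = exp_id,
                                     species = pool$species,
                                     g = pool$g, acq = pool$acq)
    site <- exp(rnorm(1, 0, cfg$site_sd))
    zmat <- scale(as.matrix(pool[, c("WD", "LNC", "SLA")]))
    rownames(zmat) <- pool$species

    # design: all monocultures + random mixtures per richness level
    comps <- lapply(pool$species, function(s) setNames(cfg$trees_per_plot, s))
    for (r in setdiff(sort(cfg$richness_levels), 1)) {
      for (m in seq_len(cfg$mixtures_per_richness)) {
        sp <- sort(sample(pool$species, r))
        comps[[length(comps) + 1L]] <- setNames(.split_counts(cfg$trees_per_plot, r), sp)
      }
    }

    blocks_mult <- exp(rnorm(cfg$blocks, 0, cfg$block_sd))
    plot_i <- 0L
    for (ci in seq_along(comps)) {
      comp <- comps[[ci]]
      sp <- names(comp)
      r <- length(sp)
      fd <- if (r > 1) fdis(comp, zmat[sp, , drop = FALSE]) else 0
      sat <- 1 - exp(-(r - 1) / cfg$tau)
      # selection term centered within the plot: growth is reallocated
      # toward the more acquisitive members, so it moves the covariance
      # with monoculture performance but not the mean relative yield
      acq_p <- pool$acq[match(sp, pool$species)]
      mix <- pmax(1 + (cfg$s * (acq_p - mean(acq_p)) +
                         cfg$k * fd) * sat, 0.1)
      g_eff <- pool$g[match(sp, pool$species)] * site * mix
      for (b in seq_len(cfg$blocks)) {
        plot_i <- plot_i + 1L
        plot_id <- sprintf("%s_P%03d", exp_id, plot_i)
        plot_mult <- exp(rnorm(1, 0, cfg$plot_sd *
                                 exp(cfg$disp_slope * r / 2)))
        n_tree <- sum(comp)
        sp_tree <- rep(sp, comp)
        inc <- g_eff[match(sp_tree, sp)] * blocks_mult[b] * plot_mult *
          exp(rnorm(n_tree, 0, cfg$tree_sd))
        d <- inc * cfg$age_years
        alive <- runif(n_tree) >= cfg$mortality_p
        d[!alive] <- d[!alive] * runif(sum(!alive), 0.3, 0.7)
        fmt <- function(x) sprintf("%.3f", pmax(x, 0.001))
        stems <- vapply(seq_len(n_tree), function(t) {
          if (runif(1) < cfg$multistem_p) {
            ns <- 2L + rpois(1, 0.7)
            u <- runif(ns, 0.3, 1)
            paste(fmt(d[t] * sqrt(u^2 / sum(u^2))), collapse = ";")
          } else {
            fmt(d[t])
          }
        }, "")
        h <- cfg$height_a * d^cfg$height_b * exp(rnorm(n_tree, 0, cfg$height_sd))
        h[!alive] <- NA_real_
        in_sample <- if (cfg$sampled_fraction < 1) {
          runif(n_tree) < cfg$sampled_fraction
        } else rep(TRUE, n_tree)
        trees[[length(trees) + 1L]] <- data.frame(
          tree_id = sprintf("%s_T%03d", plot_id, seq_len(n_tree)),
          plot_id = plot_id, species = sp_tree, stems = stems,
          height_m = round(h, 3), alive = alive, in_sample = in_sample,
          stringsAsFactors = FALSE)
        plots[[length(plots) + 1L]] <- data.frame(
          plot_id = plot_id, experiment = exp_id,
          block = sprintf("%s_B%d", exp_id, b),
          composition = format_composition(comp),
          area_ha = cfg$area_ha, sampled_fraction = cfg$sampled_fraction,
          age_years = cfg$age_years, abiotic_treatment = "none",
          height_lag_years = 0, stringsAsFactors = FALSE)

        if (r > 1) {
          # deterministic expectation: no noise, no mortality, no block/plot
          # multipliers (they cancel in expectation across the design)
          n_ha <- cfg$trees_per_plot / cfg$area_ha
          M_det <- tree_basal_area(pool$g[match(sp, pool$species)] * site *
                                     cfg$age_years) * n_ha / cfg$age_years
          Y_det <- tree_basal_area(g_eff * cfg$age_years) *
            (comp / cfg$area_ha) / cfg$age_years
          pr <- partition_plot(as.numeric(Y_det), as.numeric(M_det),
                               as.numeric(comp / sum(comp)))
          truth_plots[[length(truth_plots) + 1L]] <- data.frame(
            experiment = exp_id, plot_id = plot_id, richness = r,
            NBE = pr$NBE, SE = pr$SE, CE = pr$CE, stringsAsFactors = FALSE)
        }
      }
    }
  }
  trees <- do.call(rbind, trees)
  plots <- do.call(rbind, plots)
  traits <- do.call(rbind, traits)
  truth_plots <- if (length(truth_plots)) do.call(rbind, truth_plots) else NULL
  se_share <- if (!is.null(truth_plots) && sum(truth_plots$NBE) != 0) {
    sum(truth_plots$SE) / sum(truth_plots$NBE)
  } else NA_real_
  # tolerance band on the realized selection share, part of each named
  # scenario's definition (fixed once at calibration)
  band <- switch(attr(config, "scenario") %||% "custom",
                 selection = c(0.5, 1.05),
                 complementarity = c(-0.3, 0.3),
                 paper_like = c(0.6, 0.9),
                 c(NA_real_, NA_real_))
  trees <- validate_trees(trees, plots)
  plots <- validate_plots(plots)
  traits <- validate_traits(traits, plots)
  list(trees = trees, plots = plots, traits = traits,
       truth = list(config = cfg, seed = seed,
                    scenario = attr(config, "scenario"),
                    species = do.call(rbind, species_truth),
                    plots = truth_plots, se_share = se_share,
                    se_share_band = band))
}

#' Simulate plot-level data from the quadratic richness model
#'
#' Direct plot-level simulator for parameter-recovery studies of
#' [fit_h1()]: standardized productivity follows
#' `beta0 + beta1 * r + beta2 * r^2` plus nested random intercepts for
#' composition and block within experiment and Gaussian noise whose log
#' variance is linear in richness.
#'
#' @param n_plots Total number of plots.
#' @param n_experiments Number of experiments (plots split evenly).
#' @param beta Fixed effects `c(beta0, beta1, beta2)`.
#' @param sd_comp,sd_block Random-intercept SDs.
#' @param delta Dispersion coefficients `c(delta0, delta1)` on the
#'   log-variance scale.
#' @param seed Integer seed.
#' @return Data frame with `experiment`, `block`, `composition`,
#'   `richness`, `productivity_std`.
#' @export
simulate_richness_data <- function(n_plots = 1500, n_experiments = 20,
                                   beta = c(0, 0.3, -0.03),
                                   sd_comp = 0.3, sd_block = 0.2,
                                   delta = c(-1, 0), seed = 1) {
  set.seed(seed)
  expt <- sprintf("E%02d", rep_len(seq_len(n_experiments), n_plots))
  richness <- sample(1:6, n_plots, replace = TRUE)
  comp <- paste0(expt, "_C", richness, "_", sample(1:5, n_plots, replace = TRUE))
  block <- paste0(expt, "_B", sample(1:4, n_plots, replace = TRUE))
  u_comp <- setNames(rnorm(length(unique(comp)), 0, sd_comp), unique(comp))
  u_block <- setNames(rnorm(length(unique(block)), 0, sd_block), unique(block))
  eps <- rnorm(n_plots, 0, sqrt(exp(delta[1] + delta[2] * richness)))
  y <- beta[1] + beta[2] * richness + beta[3] * richness^2 +
    u_comp[comp] + u_block[block] + eps
  data.frame(experiment = expt, block = block, composition = comp,
             richness = richness, productivity_std = as.numeric(y),
             stringsAsFactors = FALSE)
}

#' Simulate plot-level data from the SEM's own DAG
#'
#' Generates data consistent (or deliberately inconsistent) with the
#' richness -> {structural diversity, functional dispersion} ->
#' productivity DAG, for calibration and power studies of
#' [fit_piecewise()]. All variables are on arbitrary standardized scales.
#'
#' @param n_plots Total number of plots.
#' @param n_experiments Number of experiments.
#' @param paths Named vector of raw path coefficients:
#'   `r_s` (richness -> structural), `r_f` (richness -> fdis),
#'   `s_p`, `f_p`, `r_p` (structural, fdis, richness -> productivity).
#' @param dependence Coefficient of a latent variable loading on both
#'   structural diversity and functional dispersion; nonzero values
#'   violate the DAG's single independence claim.
#' @param sd_comp,sd_block Random-intercept SDs (applied to every
#'   endogenous variable with independent draws).
#' @param sd_resid Residual SD of each endogenous variable.
#' @param seed Integer seed.
#' @return Data frame with `experiment`, `block`, `composition`,
#'   `richness`, `gini_height_std`, `cv_height_std`, `fdis_all_std`,
#'   `productivity_std`.
#' @export
simulate_sem_data <- function(n_plots = 300, n_experiments = 8,
                              paths = c(r_s = 0.25, r_f = 0.35,
                                        s_p = -0.4, f_p = 0.3, r_p = 0.05),
                              dependence = 0,
                              sd_comp = 0.25, sd_block = 0.15,
                              sd_resid = 0.6, seed = 1) {
  set.seed(seed)
  expt <- sprintf("E%02d", rep_len(seq_len(n_experiments), n_plots))
  richness <- sample(1:6, n_plots, replace = TRUE)
  comp <- paste0(expt, "_C", richness, "_", sample(1:5, n_plots, replace = TRUE))
  block <- paste0(expt, "_B", sample(1:4, n_plots, replace = TRUE))
  re <- function(f, sd) setNames(rnorm(length(unique(f)), 0, sd), unique(f))[f]
  latent <- rnorm(n_plots)
  structural <- paths["r_s"] * richness + dependence * latent +
    re(comp, sd_comp) + re(block, sd_block) + rnorm(n_plots, 0, sd_resid)
  fd <- paths["r_f"] * richness + dependence * latent +
    re(comp, sd_comp) + re(block, sd_block) + rnorm(n_plots, 0, sd_resid)
  prod_ <- paths["r_p"] * richness + paths["s_p"] * structural +
    paths["f_p"] * fd + re(comp, sd_comp) + re(block, sd_block) +
    rnorm(n_plots, 0, sd_resid)
  data.frame(experiment = expt, block = block, composition = comp,
             richness = richness,
             gini_height_std = as.numeric(structural),
             cv_height_std = as.numeric(structural),
             fdis_all_std = as.numeric(fd),
             productivity_std = as.numeric(prod_),
             stringsAsFactors = FALSE)
}
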