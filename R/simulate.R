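#' Synthetic cross-infection data generator
#'
#' Cells of the infection matrix follow a logistic latent-trait model:
#' strain i resists or succumbs to phage j with
#' `P(1) = plogis(mu + a_j - b_i + delta * same_site + gamma * same_block)`,
#' where `a_j ~ N(0, sigma_phage^2)` is phage infectivity (generalism),
#' `b_i ~ N(0, sigma_strain^2)` is strain resistance, `delta` is the
#' sympatric infection advantage (logit scale; per-site vector allowed for
#' asymmetric local adaptation) and `gamma` an optional within-block bonus
#' that plants modular structure.  Independent heavy-tailed generalism and
#' resistance generate nestedness; `delta` generates local adaptation; and
#' `gamma` modularity — the three phenomena the downstream statistics
#' measure.
#'
#' @name synthetic-data
#' @keywords internal
NULL

#' Simulation configuration
#'
#' Defaults emulate the field design the pipeline targets: 4 bean-field
#' sites in 2 regions, 196 phages and 229 strains, overall fill near 0.43,
#' and a sympatric advantage whose implied marginal rate difference is close
#' to the sympatric-allopatric gap seen in cross-infection surveys
#' (about 0.55 vs 0.39).
#'
#' @param sites character vector of site codes.
#' @param site_region named character vector mapping site -> region.
#' @param phages_per_site,strains_per_site integer counts, recycled over
#'   sites.
#' @param mu logit-scale intercept; `NULL` (default) calibrates it
#'   numerically so the expected fill equals `target_fill`.
#' @param target_fill expected connectance used when `mu` is `NULL`.
#' @param sigma_phage,sigma_strain latent trait standard deviations.
#' @param delta sympatric advantage (logit scale); scalar or named per-site
#'   vector (names = sites) for asymmetric adaptation.
#' @param n_blocks,gamma number of planted modules and the within-block
#'   logit bonus (`n_blocks = 1` disables modular structure).
#' @return list of class `"sim_config"`.
#' @export
sim_config <- function(sites = c("T", "Y", "S", "C"),
                       site_region = c(T = "Mexico", Y = "Mexico",
                                       S = "Argentina", C = "Argentina"),
                       phages_per_site = 49,
                       strains_per_site = c(58, 57, 57, 57),
                       mu = NULL, target_fill = 0.43,
                       sigma_phage = 1.2, sigma_strain = 0.8,
                       delta = 0.9, n_blocks = 1, gamma = 0) {
  if (!all(sites %in% names(site_region)))
    stop("every site needs a region in site_region")
  phages_per_site <- rep_len(as.integer(phages_per_site), length(sites))
  strains_per_site <- rep_len(as.integer(strains_per_site), length(sites))
  if (any(c(phages_per_site, strains_per_site) < 1)) stop("counts must be >= 1")
  if (sigma_phage < 0 || sigma_strain < 0) stop("trait sds must be >= 0")
  if (length(delta) > 1 && !all(sites %in% names(delta)))
    stop("per-site delta must be named by site")
  if (!all(is.finite(c(delta, gamma)))) stop("delta and gamma must be finite")
  if (n_blocks < 1) stop("n_blocks must be >= 1")
  structure(list(sites = sites, site_region = site_region,
                 phages_per_site = phages_per_site,
                 strains_per_site = strains_per_site,
                 mu = mu, target_fill = target_fill,
                 sigma_phage = sigma_phage, sigma_strain = sigma_strain,
                 delta = delta, n_blocks = n_blocks, gamma = gamma),
            class = "sim_config")
}

delta_by_site <- function(config) {
  if (length(config$delta) == 1L)
    stats::setNames(rep(config$delta, length(config$sites)), config$sites)
  else config$delta[config$sites]
}

# E[plogis(mu + shift + Z)], Z ~ N(0, sd^2); exact numeric integration
mean_logistic <- function(mu, shift, sd) {
  if (sd == 0) return(stats::plogis(mu + shift))
  stats::integrate(function(z) stats::plogis(mu + shift + z) *
                     stats::dnorm(z, sd = sd),
                   -Inf, Inf, rel.tol = 1e-10)$value
}

# cell categories with weights: sympatric yes/no x same-block yes/no
cell_categories <- function(config) {
  dlt <- delta_by_site(config)
  np <- config$phages_per_site; ns <- config$strains_per_site
  total <- sum(np) * sum(ns)
  w_symp <- stats::setNames(np * ns / total, config$sites)
  p_same_block <- if (config$n_blocks > 1) 1 / config$n_blocks else 1
  cats <- data.frame(shift = numeric(0), w = numeric(0))
  add <- function(shift, w) rbind(cats, data.frame(shift = shift, w = w))
  for (s in config$sites) {
    if (config$n_blocks > 1) {
      cats <- add(dlt[s] + config$gamma, w_symp[s] * p_same_block)
      cats <- add(dlt[s], w_symp[s] * (1 - p_same_block))
    } else cats <- add(dlt[s] + config$gamma, w_symp[s])
  }
  w_allo <- 1 - sum(w_symp)
  if (config$n_blocks > 1) {
    cats <- add(config$gamma, w_allo * p_same_block)
    cats <- add(0, w_allo * (1 - p_same_block))
  } else cats <- add(config$gamma, w_allo)
  cats
}

#' Expected fill of the simulation model
#'
#' Exact (numerically integrated) expected connectance for a configuration
#' at a given intercept.
#'
#' @param config a [sim_config()].
#' @param mu intercept; defaults to the configured/calibrated one.
#' @return expected fill in (0, 1).
#' @export
expected_fill <- function(config, mu = NULL) {
  if (is.null(mu)) mu <- if (is.null(config$mu)) calibrate_intercept(config) else config$mu
  sd <- sqrt(config$sigma_phage^2 + config$sigma_strain^2)
  cats <- cell_categories(config)
  sum(cats$w * vapply(cats$shift, function(s) mean_logistic(mu, s, sd),
                      numeric(1)))
}

#' Calibrate the intercept to the target fill
#'
#' Solves for the logit-scale intercept at which the model's expected fill
#' equals `config$target_fill`, by numeric integration over the latent
#' traits.
#'
#' @param config a [sim_config()].
#' @return intercept `mu`.
#' @export
calibrate_intercept <- function(config) {
  stats::uniroot(function(mu) expected_fill(config, mu) - config$target_fill,
                 c(-20, 20), tol = 1e-9)$root
}

#' Marginal sympatric-allopatric rate difference implied by the model
#'
#' The population value the estimated local-adaptation index targets:
#' the phage-weighted mean over sites of
#' `E[p | sympatric, site] - E[p | allopatric]`.
#'
#' @param config a [sim_config()].
#' @return implied index in (-1, 1).
#' @export
implied_la <- function(config) {
  mu <- if (is.null(config$mu)) calibrate_intercept(config) else config$mu
  sd <- sqrt(config$sigma_phage^2 + config$sigma_strain^2)
  dlt <- delta_by_site(config)
  p_same_block <- if (config$n_blocks > 1) 1 / config$n_blocks else 1
  block_mean <- function(shift) {
    if (config$n_blocks > 1)
      p_same_block * mean_logistic(mu, shift + config$gamma, sd) +
        (1 - p_same_block) * mean_logistic(mu, shift, sd)
    else mean_logistic(mu, shift + config$gamma, sd)
  }
  w_phage <- config$phages_per_site / sum(config$phages_per_site)
  e_allo <- block_mean(0)
  sum(w_phage * (vapply(dlt, block_mean, numeric(1)) - e_allo))
}

#' Simulate an infection matrix with metadata and ground truth
#'
#' @param config a [sim_config()].
#' @param seed integer seed; a fixed seed gives identical output across runs
#'   (base R Mersenne-Twister stream).
#' @return list of class `"sim_dataset"`: `matrix` (an
#'   [infection_matrix()]), `metadata`, `truth` (latent traits, realized
#'   `mu`, `delta`, `gamma`, block labels), `config`.
#' @export
simulate_matrix <- function(config = sim_config(), seed = NULL) {
  run <- function() {
    mu <- if (is.null(config$mu)) calibrate_intercept(config) else config$mu
    phage_site <- rep(config$sites, config$phages_per_site)
    strain_site <- rep(config$sites, config$strains_per_site)
    np <- length(phage_site); ns <- length(strain_site)
    a <- stats::rnorm(np, 0, config$sigma_phage)
    b <- stats::rnorm(ns, 0, config$sigma_strain)
    dlt <- delta_by_site(config)[phage_site]
    blk_p <- if (config$n_blocks > 1) sample.int(config$n_blocks, np, TRUE) else rep(1L, np)
    blk_s <- if (config$n_blocks > 1) sample.int(config$n_blocks, ns, TRUE) else rep(1L, ns)
    eta <- mu + outer(-b, a, "+") # strain x phage base
    symp <- outer(strain_site, phage_site, "==")
    eta <- eta + symp * rep(as.numeric(dlt), each = ns)
    if (config$gamma != 0)
      eta <- eta + config$gamma * outer(blk_s, blk_p, "==")
    cells <- matrix(stats::rbinom(ns * np, 1L, stats::plogis(eta)), ns, np)
    strain_ids <- sprintf("STR_%s_%03d", strain_site,
                          stats::ave(seq_len(ns), strain_site, FUN = seq_along))
    phage_ids <- sprintf("PHG_%s_%03d", phage_site,
                         stats::ave(seq_len(np), phage_site, FUN = seq_along))
    mat <- infection_matrix(cells, strain_ids, phage_ids)
    region_p <- unname(config$site_region[phage_site])
    region_s <- unname(config$site_region[strain_site])
    # species mix and collection proportions mirror the field survey design:
    # one species dominates each region
    first_region <- unname(config$site_region[[config$sites[1]]])
    taxon_s <- ifelse(stats::runif(ns) < ifelse(region_s == first_region, 0.75, 0.2),
                      "R. etli", "R. phaseoli")
    families <- c("Podoviridae", "Siphoviridae", "Myoviridae", "Microviridae")
    taxon_p <- sample(families, np, TRUE, prob = c(12, 8, 6, 3) / 29)
    coll_p <- sample(c("LC", "SC"), np, TRUE, prob = c(110, 86) / 196)
    metadata <- rbind(
      data.frame(id = strain_ids, entity_class = "strain", site = strain_site,
                 region = region_s, taxon = taxon_s, genotype = NA_character_,
                 collection = "LC", stringsAsFactors = FALSE),
      data.frame(id = phage_ids, entity_class = "phage", site = phage_site,
                 region = region_p, taxon = taxon_p, genotype = NA_character_,
                 collection = coll_p, stringsAsFactors = FALSE))
    truth <- list(mu = mu, a = stats::setNames(a, phage_ids),
                  b = stats::setNames(b, strain_ids),
                  delta = config$delta, gamma = config$gamma,
                  phage_blocks = stats::setNames(blk_p, phage_ids),
                  strain_blocks = stats::setNames(blk_s, strain_ids))
    structure(list(matrix = mat, metadata = metadata, truth = truth,
                   config = config), class = "sim_dataset")
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Simulate per-sample community count tables
#'
#' Each region has a pool of type labels, a `shared_fraction` of which is
#' common to all regions; each site perturbs its region's base frequencies
#' on the log scale (`site_sd` controls the among-site effect size), and
#' each of `samples_per_site` soil samples draws `depth` individuals
#' multinomially from its site's frequencies.
#'
#' @param config a [sim_config()] (only sites/regions are used).
#' @param n_types_per_region pool size per region.
#' @param shared_fraction fraction of each pool shared across regions.
#' @param samples_per_site soil samples per site (default 3).
#' @param depth individuals classified per sample.
#' @param site_sd log-scale sd of the site-level frequency perturbation.
#' @param seed integer seed.
#' @return list of class `"sim_communities"`: `counts` (samples x types),
#'   `sample_meta` (`sample_id`, `site`, `region`), `truth` (site frequency
#'   vectors).
#' @export
simulate_communities <- function(config = sim_config(), n_types_per_region = 20,
                                 shared_fraction = 0.3, samples_per_site = 3,
                                 depth = 100, site_sd = 0.5, seed = NULL) {
  if (n_types_per_region < 1) stop("empty type pool")
  if (shared_fraction < 0 || shared_fraction > 1)
    stop("shared_fraction must lie in [0, 1]")
  run <- function() {
    regions <- unique(unname(config$site_region[config$sites]))
    n_shared <- round(shared_fraction * n_types_per_region)
    shared <- if (n_shared) paste0("type_shared_", seq_len(n_shared)) else character()
    pools <- lapply(regions, function(r) {
      own <- n_types_per_region - n_shared
      c(shared, if (own) paste0("type_", r, "_", seq_len(own)) else character())
    })
    names(pools) <- regions
    all_types <- unique(unlist(pools))
    site_freq <- list()
    for (s in config$sites) {
      pool <- pools[[config$site_region[[s]]]]
      base <- stats::rgamma(length(pool), 1)
      f <- base * exp(stats::rnorm(length(pool), 0, site_sd))
      site_freq[[s]] <- stats::setNames(f / sum(f), pool)
    }
    n_samples <- length(config$sites) * samples_per_site
    counts <- matrix(0L, n_samples, length(all_types),
                     dimnames = list(NULL, all_types))
    meta <- data.frame(sample_id = character(n_samples), site = "", region = "",
                       stringsAsFactors = FALSE)
    k <- 0L
    for (s in config$sites) for (j in seq_len(samples_per_site)) {
      k <- k + 1L
      draw <- stats::rmultinom(1, depth, site_freq[[s]])[, 1]
      counts[k, names(draw)] <- as.integer(draw)
      meta$sample_id[k] <- sprintf("%s_sample%d", s, j)
      meta$site[k] <- s
      meta$region[k] <- config$site_region[[s]]
    }
    rownames(counts) <- meta$sample_id
    structure(list(counts = counts, sample_meta = meta,
                   truth = list(site_freq = site_freq, pools = pools)),
              class = "sim_communities")
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Simulate a pairwise ANI/coverage table with planted genomic types
#'
#' Within-cluster pairs draw ANI and coverage inside the qualifying region
#' (ANI >= 80, coverage >= 60; defaults span the ranges typical of
#' conspecific phage genomes), between-cluster pairs fall below the ANI
#' threshold, so [cluster_pgts()] recovers the planted partition exactly.
#'
#' @param cluster_sizes integer sizes of the planted clusters.
#' @param seed integer seed.
#' @param ani_within,cov_within,ani_between ranges (min, max) for the
#'   uniform draws.
#' @return list of class `"sim_ani"`: `table` (`id_a`, `id_b`, `ani`,
#'   `coverage`) over all unordered pairs, `truth` (id -> planted cluster).
#' @export
simulate_ani_table <- function(cluster_sizes = c(4, 3, 2, 1, 1), seed = NULL,
                               ani_within = c(85.8, 99.7),
                               cov_within = c(64.1, 100),
                               ani_between = c(40, 75)) {
  run <- function() {
    labels <- rep(seq_along(cluster_sizes), cluster_sizes)
    ids <- sprintf("G%03d", seq_along(labels))
    pairs <- utils::combn(length(ids), 2)
    same <- labels[pairs[1, ]] == labels[pairs[2, ]]
    n <- ncol(pairs)
    ani <- ifelse(same, stats::runif(n, ani_within[1], ani_within[2]),
                  stats::runif(n, ani_between[1], ani_between[2]))
    cov <- ifelse(same, stats::runif(n, cov_within[1], cov_within[2]),
                  stats::runif(n, 30, 100))
    tab <- data.frame(id_a = ids[pairs[1, ]], id_b = ids[pairs[2, ]],
                      ani = ani, coverage = cov, stringsAsFactors = FALSE)
    structure(list(table = tab, truth = stats::setNames(labels, ids)),
              class = "sim_ani")
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Parameter-recovery harness for the local-adaptation analysis
#'
#' For each sympatric advantage on the grid, simulates `reps` matrices,
#' estimates the local-adaptation index (phage perspective) and the
#' quasi-binomial GLM p-value, and aggregates.  The mean estimated index
#' should be approximately 0 at `delta = 0`, increase with `delta`, and the
#' GLM rejection rate at `delta = 0` should approximate the nominal level.
#'
#' @param delta_grid sympatric advantages to simulate.
#' @param reps replicate simulations per grid point.
#' @param config base [sim_config()]; the default uses a reduced design
#'   (10 phages and 12 strains per site) so the harness stays fast.
#' @param seed integer base seed; replicate seeds are a deterministic
#'   function of (grid point, replicate), so extending `reps` keeps earlier
#'   replicates identical.
#' @param alpha nominal test level for the rejection rate.
#' @return data frame of class `"recovery_result"`: one row per `delta` with
#'   `mean_la`, `se_la`, `implied_la`, `rejection_rate`, `reps`; per-replicate
#'   values are attached as the `"replicates"` attribute.
#' @export
recovery_experiment <- function(delta_grid = c(0, 0.5, 1, 2), reps = 50,
                                config = NULL, seed = 1L, alpha = 0.05) {
  if (reps < 2) stop("reps must be >= 2")
  if (is.null(config))
    config <- sim_config(phages_per_site = 10, strains_per_site = 12)
  out <- lapply(seq_along(delta_grid), function(di) {
    cfg <- config
    cfg$delta <- delta_grid[di]
    la <- numeric(reps); pval <- numeric(reps)
    for (r in seq_len(reps)) {
      sim <- simulate_matrix(cfg, seed = seed + 100003L * di + r)
      rates <- entity_rates(sim$matrix, sim$metadata, "phage")
      la[r] <- local_adaptation(rates)$la_index
      pval[r] <- quasibinomial_f_test(rates)$p_value
    }
    list(summary = data.frame(delta = delta_grid[di], mean_la = mean(la),
                              se_la = stats::sd(la) / sqrt(reps),
                              implied_la = implied_la(cfg),
                              rejection_rate = mean(pval < alpha), reps = reps),
         detail = data.frame(delta = delta_grid[di], rep = seq_len(reps),
                             la = la, p_value = pval))
  })
  res <- do.call(rbind, lapply(out, `[[`, "summary"))
  attr(res, "replicates") <- do.call(rbind, lapply(out, `[[`, "detail"))
  class(res) <- c("recovery_result", class(res))
  res
}
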