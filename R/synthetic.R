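# Synthetic paired-population experiments with known ground truth.
#
# The generator emulates the statistical structure the analyses assume:
# paired near/far populations replicated over sites x years x seed sources;
# nine correlated floral traits; seed-predator attack counts whose rates
# are linked to traits on the logit scale and elevated far from the crop;
# pollen deposition linked to floral traits and depressed far from the
# crop; and fitness generated log-linearly from the standardized derived
# traits with known direct-selection gradients, realized as overdispersed
# (negative binomial) seed counts.

default_trait_corr <- function() {
  traits <- trait_sets()$all[1:9]
  R <- diag(9)
  dimnames(R) <- list(traits, traits)
  infl <- trait_sets()$inflorescence
  flow <- trait_sets()$flower
  R[infl, infl] <- 0.4
  R[flow, flow] <- 0.4
  R[infl, flow] <- 0.2
  R[flow, infl] <- 0.2
  diag(R) <- 1
  R
}

#' Configuration for the synthetic experiment generator
#'
#' Defaults describe the emulated field design: paired near/far populations
#' for every site x year x seed-source combination, 80-155 plants per
#' population, ~80 seeds examined per plant for seed-predator damage, and
#' far-arm attack rates elevated relative to near (with pollinator activity
#' depressed far from the crop).
#'
#' @param n_sites,n_years,seed_sources design dimensions (defaults 2, 2, 2:
#'   8 population-pairs).
#' @param n_plants_range integer interval for plants per population.
#' @param trait_corr 9x9 positive-definite correlation matrix for the nine
#'   floral traits (unit diagonal).
#' @param beta_true named ground-truth direct-selection gradients on the
#'   standardized floral traits (log-fitness scale).
#' @param beta_volume gradient on standardized log stem volume.
#' @param penalty_iso,penalty_neo log-fitness penalty per unit attack
#'   proportion for the two seed predators.
#' @param attack_base named near-arm attack rates `c(iso=, neo=)`.
#' @param proximity_shift multipliers applied in the far arm:
#'   `iso_rate`, `neo_rate` (> 1: more attack far) and `pollinator_rate`
#'   (< 1: less pollen far).
#' @param attack_coef_iso,attack_coef_neo named logit-scale loadings of
#'   standardized traits on attack rates.
#' @param attack_phi Dirichlet precision of the seed-fate overdispersion.
#' @param pollen_coef named log-scale loadings of traits on pollen arrival.
#' @param pollen_base mean pollen grains per stigma in the near arm.
#' @param pollen_sites sites where pollen deposition is measured (the
#'   study measured it at a subset of focal sites).
#' @param base_seeds expected whole-plant seed production at trait means.
#' @param noise_sd SD of the log-scale environmental fitness noise.
#' @param nb_size negative-binomial dispersion of realized seed counts.
#' @param mean_inflorescences mean inflorescence count (>= 1 enforced).
#' @param seeds_examined seeds sub-sampled per plant for damage scoring.
#' @param n_flowers flowers collected per plant for floral measurements.
#' @param rng_seed master seed; per-population sub-streams are derived by
#'   stable hashing of the population id.
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_sites = 2, n_years = 2, seed_sources = 2,
                             n_plants_range = c(80L, 155L),
                             trait_corr = default_trait_corr(),
                             beta_true = c(DD = 0.3, RL = 0.2, RW = 0.1,
                                           NR = 0.2, CS = 0, DTW = 0,
                                           DTL = 0, PTS = 0.1, TS = 0),
                             beta_volume = 0.3,
                             penalty_iso = 2.5, penalty_neo = 1.5,
                             attack_base = c(iso = 0.10, neo = 0.05),
                             proximity_shift = c(iso_rate = 2,
                                                 neo_rate = 2,
                                                 pollinator_rate = 0.6),
                             attack_coef_iso = c(DD = 0.2, NR = 0.1),
                             attack_coef_neo = c(DD = 0.2, RL = 0.1),
                             attack_phi = 50,
                             pollen_coef = c(CS = 0.3, DD = 0.2),
                             pollen_base = 3,
                             pollen_sites = 1L,
                             base_seeds = 500,
                             noise_sd = 0.3,
                             nb_size = 5,
                             mean_inflorescences = 25,
                             seeds_examined = 80L,
                             n_flowers = 5L,
                             rng_seed = 1L) {
  traits9 <- trait_sets()$all[1:9]
  stopifnot(
    n_sites >= 1, n_years >= 1, seed_sources >= 1,
    length(n_plants_range) == 2, n_plants_range[1] >= 2,
    n_plants_range[1] <= n_plants_range[2],
    is.matrix(trait_corr), nrow(trait_corr) == 9, ncol(trait_corr) == 9,
    all(abs(diag(trait_corr) - 1) < 1e-12),
    isTRUE(all.equal(trait_corr, t(trait_corr))),
    all(names(beta_true) %in% traits9), length(beta_true) == 9,
    all(attack_base > 0 & attack_base < 1),
    all(proximity_shift > 0),
    noise_sd >= 0, nb_size > 0, attack_phi > 0,
    seeds_examined >= 1, n_flowers >= 1, base_seeds > 0
  )
  ev <- eigen(trait_corr, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10) stop("trait_corr must be positive definite")
  if (any(attack_base * pmax(proximity_shift[c("iso_rate", "neo_rate")], 1) >=
          0.5)) {
    stop("shifted attack rates must stay below 0.5 so seed fates remain valid")
  }
  structure(as.list(environment())[names(formals(synthetic_config))],
            class = "synthetic_config")
}

# trait raw-scale means and SDs (mm / counts; realistic field magnitudes)
TRAIT_SCALES <- data.frame(
  trait = c("DD", "RL", "RW", "NR", "CS", "DTW", "DTL", "PTS", "TS"),
  mean = c(25, 18, 6, 13, 6, 1.2, 2.5, 1.5, 1.0),
  sd = c(3, 2.5, 1, 2, 1.2, 0.15, 0.3, 0.25, 0.15),
  stringsAsFactors = FALSE
)

# split per-flower product values into length x width with a random aspect
# ratio; per-flower products average exactly to the plant-level target
split_product <- function(target, n_flowers, aspect_mean) {
  u <- stats::rlnorm(n_flowers, 0, 0.15)
  u <- u / mean(u)                      # weights with mean exactly 1
  p <- target * u
  a <- stats::rlnorm(n_flowers, log(aspect_mean), 0.1)
  list(L = sqrt(p * a), W = sqrt(p / a))
}

generate_population <- function(pop_meta, cfg) {
  sizes <- seq(cfg$n_plants_range[1], cfg$n_plants_range[2])
  n <- sizes[sample.int(length(sizes), 1L)]
  traits9 <- TRAIT_SCALES$trait
  far <- pop_meta$proximity == "far"

  Z <- MASS::mvrnorm(n, mu = rep(0, 9), Sigma = cfg$trait_corr)
  colnames(Z) <- traits9
  raw <- sapply(traits9, function(tr) {
    i <- match(tr, TRAIT_SCALES$trait)
    pmax(TRAIT_SCALES$mean[i] + TRAIT_SCALES$sd[i] * Z[, tr],
         TRAIT_SCALES$mean[i] * 0.05)
  })
  raw[, "NR"] <- pmax(round(raw[, "NR"]), 1)

  plant_id <- sprintf("P%03d", seq_len(n))

  # flowers: products split into measured lengths/widths so that the
  # mean-of-products derivation recovers the plant-level value exactly
  flowers <- do.call(rbind, lapply(seq_len(n), function(i) {
    cs <- split_product(raw[i, "CS"], cfg$n_flowers, 1.6)
    pts <- split_product(raw[i, "PTS"], cfg$n_flowers, 1.3)
    ts <- split_product(raw[i, "TS"], cfg$n_flowers, 2.0)
    dtw <- raw[i, "DTW"] + stats::rnorm(cfg$n_flowers, 0, 0.03)
    dtw <- pmax(dtw - mean(dtw) + raw[i, "DTW"], 1e-3)
    dtl <- raw[i, "DTL"] + stats::rnorm(cfg$n_flowers, 0, 0.05)
    dtl <- pmax(dtl - mean(dtl) + raw[i, "DTL"], 1e-3)
    data.frame(
      population_id = pop_meta$population_id, plant_id = plant_id[i],
      flower = seq_len(cfg$n_flowers),
      CL = cs$L, CW = cs$W, DTL = dtl, DTW = dtw,
      PTL = pts$L, PTW = pts$W, TL = ts$L, TW = ts$W,
      stringsAsFactors = FALSE
    )
  }))

  height <- pmax(stats::rnorm(n, 150, 30), 30)            # cm
  basal_diameter <- pmax(stats::rnorm(n, 15, 3), 3)       # mm
  volume <- stem_volume(basal_diameter, height)
  n_infl <- 1L + stats::rnbinom(n, size = 5,
                                mu = cfg$mean_inflorescences - 1)

  # realized plant-level derived traits (what the analysis will see),
  # standardized within the population; fitness and attack are linked to
  # these so downstream estimates are unbiased for the stored truth
  # flower-table derivation reproduces these plant-level values exactly
  z_real <- scale(raw[, traits9])

  logit <- function(p) log(p / (1 - p))
  lin <- function(coefs) {
    if (!length(coefs)) return(rep(0, n))
    as.vector(z_real[, names(coefs), drop = FALSE] %*% coefs)
  }
  r_iso <- stats::plogis(
    logit(cfg$attack_base[["iso"]] *
            (if (far) cfg$proximity_shift[["iso_rate"]] else 1)) +
      lin(cfg$attack_coef_iso))
  r_neo <- stats::plogis(
    logit(cfg$attack_base[["neo"]] *
            (if (far) cfg$proximity_shift[["neo_rate"]] else 1)) +
      lin(cfg$attack_coef_neo))
  r_iso <- pmin(pmax(r_iso, 1e-4), 0.45)
  r_neo <- pmin(pmax(r_neo, 1e-4), 0.45)

  # Dirichlet-multinomial seed fates (iso-damaged, neo-damaged, intact)
  counts <- t(vapply(seq_len(n), function(i) {
    a <- cfg$attack_phi * c(r_iso[i], r_neo[i], 1 - r_iso[i] - r_neo[i])
    g <- stats::rgamma(3, shape = a)
    stats::rmultinom(1, cfg$seeds_examined, g / sum(g))[, 1]
  }, numeric(3)))
  iso_prop <- counts[, 1] / cfg$seeds_examined
  neo_prop <- counts[, 2] / cfg$seeds_examined

  z_vol <- as.vector(scale(log(volume)))
  beta <- cfg$beta_true[traits9]
  log_mu <- log(cfg$base_seeds) +
    as.vector(z_real %*% beta) +
    cfg$beta_volume * z_vol -
    cfg$penalty_iso * iso_prop -
    cfg$penalty_neo * neo_prop +
    stats::rnorm(n, 0, cfg$noise_sd)
  W <- stats::rnbinom(n, size = cfg$nb_size, mu = exp(log_mu))

  plants <- data.frame(
    population_id = pop_meta$population_id, plant_id = plant_id,
    seeds_per_infl_mean = W / n_infl,
    n_inflorescences = n_infl,
    height = height, basal_diameter = basal_diameter,
    DD = raw[, "DD"], RL = raw[, "RL"], RW = raw[, "RW"], NR = raw[, "NR"],
    iso_damaged = counts[, 1], neo_damaged = counts[, 2],
    seeds_examined = cfg$seeds_examined,
    stringsAsFactors = FALSE
  )

  stigmas <- NULL
  if (pop_meta$site %in% paste0("S", cfg$pollen_sites)) {
    lambda <- cfg$pollen_base *
      (if (far) cfg$proximity_shift[["pollinator_rate"]] else 1) *
      exp(lin(cfg$pollen_coef))
    stigmas <- do.call(rbind, lapply(seq_len(n), function(i) {
      k <- min(1L + stats::rpois(1, 5), 21L)
      data.frame(population_id = pop_meta$population_id,
                 plant_id = plant_id[i], stigma = seq_len(k),
                 grains = stats::rpois(k, lambda[i]),
                 stringsAsFactors = FALSE)
    }))
  }

  truth <- data.frame(
    population_id = pop_meta$population_id, plant_id = plant_id,
    log_mu = log_mu, W = W, r_iso = r_iso, r_neo = r_neo,
    stringsAsFactors = FALSE
  )
  list(plants = plants, flowers = flowers, stigmas = stigmas, truth = truth)
}

#' Generate a synthetic paired-population experiment
#'
#' For every site x year x seed-source combination, one near and one far
#' population are generated under the configured design. The ground truth
#' (gradients, penalties, per-plant expected fitness and attack rates) is
#' returned alongside. Regeneration with the same `rng_seed` is
#' bit-identical, and populations are drawn from independent sub-streams
#' keyed by population id, so they do not depend on generation order.
#'
#' @param config [synthetic_config()].
#' @return list: `experiment` (`psa_experiment`) and `truth` (list with
#'   `beta_true`, `beta_volume`, `penalties`, `config`, and the per-plant
#'   `plants` truth table).
#' @export
generate_experiment <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  design <- expand.grid(
    site = paste0("S", seq_len(config$n_sites)),
    year = paste0("Y", seq_len(config$n_years)),
    seed_source = LETTERS[2:(1 + config$seed_sources)],
    proximity = c("near", "far"),
    stringsAsFactors = FALSE
  )
  design$population_id <- with(design,
                               paste(site, year, seed_source, proximity,
                                     sep = "_"))
  parts <- lapply(seq_len(nrow(design)), function(i) {
    meta <- design[i, , drop = FALSE]
    seed <- ((config$rng_seed %% 2147483647) * 1103 +
               hash_string(meta$population_id)) %% 2147483647
    with_seed(seed, generate_population(meta, config))
  })
  plants <- do.call(rbind, lapply(parts, `[[`, "plants"))
  flowers <- do.call(rbind, lapply(parts, `[[`, "flowers"))
  stigma_parts <- Filter(Negate(is.null), lapply(parts, `[[`, "stigmas"))
  stigmas <- if (length(stigma_parts)) do.call(rbind, stigma_parts) else NULL
  truth_plants <- do.call(rbind, lapply(parts, `[[`, "truth"))
  experiment <- new_experiment(
    design[c("population_id", "site", "year", "seed_source", "proximity")],
    plants, flowers, stigmas
  )
  truth <- list(
    beta_true = config$beta_true,
    beta_volume = config$beta_volume,
    penalties = c(iso = config$penalty_iso, neo = config$penalty_neo),
    plants = truth_plants,
    config = config
  )
  list(experiment = experiment, truth = truth)
}

#' Simulate data consistent with a DAG by ancestral sampling
#'
#' Each node is the stated linear combination of its parents plus
#' unit-variance Gaussian noise, sampled in topological order, so every
#' basis-set claim of the DAG holds in the generating process.
#'
#' @param dag `dag_spec`.
#' @param coeffs data frame `from`, `to`, `coef`; every DAG edge needs a row.
#' @param n sample size.
#' @param rng_seed integer seed.
#' @return data frame with one column per node.
#' @export
generate_dag_consistent <- function(dag, coeffs, n, rng_seed = 1L) {
  stopifnot(inherits(dag, "dag_spec"))
  key_have <- paste(coeffs$from, coeffs$to)
  key_need <- paste(dag$edges$from, dag$edges$to)
  miss <- setdiff(key_need, key_have)
  if (length(miss)) stop("missing coefficient for edge(s): ",
                         paste(miss, collapse = ", "))
  with_seed(rng_seed, {
    data <- as.data.frame(matrix(NA_real_, n, length(dag$nodes),
                                 dimnames = list(NULL, dag$nodes)))
    for (node in dag$nodes) {
      parents <- dag_parents(dag, node)
      mu <- rep(0, n)
      for (p in parents) {
        cf <- coeffs$coef[coeffs$from == p & coeffs$to == node]
        mu <- mu + cf * data[[p]]
      }
      data[[node]] <- mu + stats::rnorm(n)
    }
    data
  })
}

#' Deterministic 12-plant worked example
#'
#' A hand-checkable fixture: two populations (one near, one far) of six
#' plants each, with simple round-number measurements, used in the test
#' suite to pin selection differentials and gradients to closed-form
#' values.
#'
#' @return `psa_experiment`.
#' @export
worked_fixture <- function() {
  pops <- data.frame(
    population_id = c("FIX_near", "FIX_far"),
    site = "S1", year = "Y1", seed_source = "B",
    proximity = c("near", "far"),
    stringsAsFactors = FALSE
  )
  plant <- function(pop, i, spi, ninf, dd, rl) {
    data.frame(
      population_id = pop, plant_id = sprintf("P%02d", i),
      seeds_per_infl_mean = spi, n_inflorescences = ninf,
      height = 100 + 10 * i, basal_diameter = 10 + i,
      DD = dd, RL = rl, RW = 5 + 0.5 * i, NR = 10 + i,
      iso_damaged = i, neo_damaged = 2 * i, seeds_examined = 80,
      stringsAsFactors = FALSE
    )
  }
  plants <- rbind(
    plant("FIX_near", 1, 10, 10, 20, 15), plant("FIX_near", 2, 12, 12, 22, 16),
    plant("FIX_near", 3, 14, 11, 24, 18), plant("FIX_near", 4, 16, 13, 26, 17),
    plant("FIX_near", 5, 18, 14, 28, 20), plant("FIX_near", 6, 20, 15, 30, 19),
    plant("FIX_far", 1, 20, 15, 21, 15), plant("FIX_far", 2, 18, 13, 23, 17),
    plant("FIX_far", 3, 16, 14, 25, 16), plant("FIX_far", 4, 14, 12, 27, 19),
    plant("FIX_far", 5, 12, 11, 29, 18), plant("FIX_far", 6, 10, 10, 31, 20)
  )
  flowers <- do.call(rbind, lapply(seq_len(nrow(plants)), function(i) {
    p <- plants[i, ]
    data.frame(
      population_id = p$population_id, plant_id = p$plant_id,
      flower = 1:2,
      CL = c(2, 2.5), CW = c(3, 3.1),
      DTL = c(2.4, 2.6), DTW = c(1.1, 1.3),
      PTL = c(1.5, 1.6), PTW = c(1.0, 1.1),
      TL = c(2.0, 2.1), TW = c(0.5, 0.6),
      stringsAsFactors = FALSE
    )
  }))
  new_experiment(pops, plants, flowers)
}
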