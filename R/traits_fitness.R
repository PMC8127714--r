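# Per-plant derived analysis variables: fitness, stem volume, composite
# flower traits, attack proportions, pollen deposition; plus within-population
# transformation and standardization.

#' Whole-plant seed production
#'
#' Mean seed production per (bagged) inflorescence multiplied by the total
#' number of inflorescences on the plant — the lifetime fitness estimate for
#' an annual.
#'
#' @param seeds_per_infl_mean mean seeds per inflorescence (nonnegative).
#' @param n_inflorescences inflorescence count (nonnegative).
#' @return estimated whole-plant seed production (vectorized; NA propagates).
#' @export
whole_plant_seeds <- function(seeds_per_infl_mean, n_inflorescences) {
  if (any(seeds_per_infl_mean < 0, na.rm = TRUE) ||
      any(n_inflorescences < 0, na.rm = TRUE)) {
    stop("seed and inflorescence counts must be nonnegative")
  }
  seeds_per_infl_mean * n_inflorescences
}

#' Stem volume
#'
#' Cylinder volume pi * r^2 * h from the basal stem diameter (mm) and plant
#' height (cm); height is converted to mm so the result is in mm^3.
#'
#' @param basal_diameter basal stem diameter in mm (> 0).
#' @param height height to the tallest inflorescence in cm (> 0).
#' @return stem volume in mm^3 (vectorized).
#' @export
stem_volume <- function(basal_diameter, height) {
  if (any(basal_diameter <= 0, na.rm = TRUE) || any(height <= 0, na.rm = TRUE)) {
    stop("basal_diameter and height must be positive")
  }
  pi * (basal_diameter / 2)^2 * (height * 10)
}

#' Composite disk-flower traits per plant
#'
#' From the long per-flower measurement table, computes per flower the
#' products CS = CL x CW (corolla lobe size), PTS = PTL x PTW (proximal
#' throat size) and TS = TL x TW (corolla tube size), keeps DTW and DTL as
#' measured, then averages across a plant's flowers. Products are taken
#' before averaging (mean of products, not product of means).
#'
#' @param flowers data frame with columns `population_id`, `plant_id`,
#'   `CL`, `CW`, `DTL`, `DTW`, `PTL`, `PTW`, `TL`, `TW`.
#' @return data frame with one row per plant: `population_id`, `plant_id`,
#'   `CS`, `DTW`, `DTL`, `PTS`, `TS`, and `n_flowers`. Plants with no
#'   flowers are simply absent (missing, not zero).
#' @export
derive_flower_traits <- function(flowers) {
  check_columns(flowers, FLOWER_COLUMNS[-3], "flowers")
  per_flower <- data.frame(
    population_id = flowers$population_id,
    plant_id = flowers$plant_id,
    CS = flowers$CL * flowers$CW,
    DTW = flowers$DTW,
    DTL = flowers$DTL,
    PTS = flowers$PTL * flowers$PTW,
    TS = flowers$TL * flowers$TW,
    stringsAsFactors = FALSE
  )
  key <- interaction(per_flower$population_id, per_flower$plant_id, drop = TRUE)
  agg <- stats::aggregate(per_flower[c("CS", "DTW", "DTL", "PTS", "TS")],
                          by = list(key = key), FUN = mean)
  counts <- as.vector(table(key)[as.character(agg$key)])
  first <- !duplicated(key)
  lut <- data.frame(
    key = as.character(key[first]),
    population_id = per_flower$population_id[first],
    plant_id = per_flower$plant_id[first],
    stringsAsFactors = FALSE
  )
  out <- merge(lut, cbind(agg, n_flowers = counts), by = "key", sort = FALSE)
  out$key <- NULL
  out[order(out$population_id, out$plant_id), , drop = FALSE]
}

#' Seed-predator attack proportion
#'
#' @param damaged number of damaged seeds (0 <= damaged <= examined).
#' @param examined number of seeds examined.
#' @return damaged / examined; `examined = 0` yields NA with a warning.
#' @export
attack_proportion <- function(damaged, examined) {
  if (any(damaged < 0, na.rm = TRUE) || any(damaged > examined, na.rm = TRUE)) {
    stop("damaged must lie in [0, examined]")
  }
  zero <- !is.na(examined) & examined == 0
  if (any(zero)) warning("seeds_examined = 0: attack proportion set to NA")
  out <- damaged / examined
  out[zero] <- NA_real_
  out
}

#' Pollen deposition per plant
#'
#' Scales mean pollen grains per stigma up to the whole plant assuming a
#' constant 100 flowers per inflorescence:
#' mean(grains) x 100 x n_inflorescences.
#'
#' @param grain_counts numeric vector of pollen grains per collected stigma.
#' @param n_inflorescences inflorescence count for the plant.
#' @return estimated pollen grains deposited on the plant; NA when no
#'   stigmas were collected.
#' @export
pollen_deposition <- function(grain_counts, n_inflorescences) {
  grain_counts <- grain_counts[!is.na(grain_counts)]
  if (!length(grain_counts)) return(NA_real_)
  if (any(grain_counts < 0)) stop("grain counts must be nonnegative")
  mean(grain_counts) * 100 * n_inflorescences
}

#' Relative fitness and its log transform for one population
#'
#' Relative fitness is each plant's seed production divided by the
#' population mean; its population mean is exactly 1. The log version is
#' ln(w_rel + offset); the default offset 1 keeps zero-fitness plants in
#' the analysis (a zero-seed plant has w_rel = 0 and log fitness ln(1) = 0).
#'
#' @param W whole-plant seed production for every plant of one population.
#' @param offset offset c in ln(w_rel + c); see [experiment_config()].
#' @return list with `w_rel` and `log_w` (NAs in `W` propagate).
#' @export
relativize_and_log <- function(W, offset = 1) {
  if (sum(!is.na(W)) < 2) stop("need at least two plants with fitness")
  m <- mean(W, na.rm = TRUE)
  if (!is.finite(m) || m <= 0) {
    stop("population mean fitness is zero: no fitness variation to analyze")
  }
  w_rel <- W / m
  list(w_rel = w_rel, log_w = log(w_rel + offset))
}

#' Transform (optionally) and z-score variables within one population
#'
#' With `policy = "auto"`, a variable with |skewness| > 1 is ln(x+1)
#' transformed first (arcsine-square-root for proportion-valued variables);
#' with `"none"` values are standardized as-is. Each returned column has
#' mean 0 and SD 1 over its non-missing entries. Zero-variance variables
#' are excluded with a warning.
#'
#' @param x data frame or matrix of numeric variables for one population.
#' @param policy `"none"` or `"auto"`.
#' @return list: `z` (matrix, possibly fewer columns), `transforms` (named
#'   character record of what was applied), `dropped` (zero-variance
#'   variables).
#' @export
standardize_traits <- function(x, policy = c("none", "auto")) {
  policy <- match.arg(policy)
  x <- as.data.frame(x)
  stopifnot(nrow(x) >= 3)
  transforms <- setNames(rep("identity", ncol(x)), names(x))
  out <- list()
  dropped <- character(0)
  for (nm in names(x)) {
    v <- as.numeric(x[[nm]])
    if (policy == "auto") {
      is_prop <- all(v >= 0 & v <= 1, na.rm = TRUE)
      sk <- sample_skewness(v)
      if (is_prop && isTRUE(abs(sk) > 1)) {
        v <- asin(sqrt(v)); transforms[nm] <- "asin_sqrt"
      } else if (isTRUE(abs(sk) > 1)) {
        if (any(v < -1, na.rm = TRUE)) {
          transforms[nm] <- "identity"  # log1p undefined; leave as-is
        } else {
          v <- log1p(v); transforms[nm] <- "log1p"
        }
      }
    }
    s <- stats::sd(v, na.rm = TRUE)
    if (!is.finite(s) || s == 0) {
      dropped <- c(dropped, nm)
      next
    }
    out[[nm]] <- (v - mean(v, na.rm = TRUE)) / s
  }
  if (length(dropped)) {
    warning("zero-variance variable(s) excluded: ", paste(dropped, collapse = ", "))
    transforms <- transforms[setdiff(names(transforms), dropped)]
  }
  list(z = do.call(cbind, out), transforms = transforms, dropped = dropped)
}

#' Derive the per-plant analysis table for a whole experiment
#'
#' Assembles, for every plant: whole-plant seed production W, relative and
#' log-relative fitness (computed within population), stem volume, the four
#' inflorescence traits, the five composite disk-flower traits, the two
#' attack proportions and (where stigmas were collected) pollen deposition.
#'
#' @param experiment `psa_experiment`.
#' @param config [experiment_config()]; `missing_fitness` and `log_offset`
#'   are honored here.
#' @return data frame, one row per plant, with population metadata attached.
#' @export
derive_plants <- function(experiment, config = experiment_config()) {
  stopifnot(inherits(experiment, "psa_experiment"))
  p <- experiment$plants
  W <- whole_plant_seeds(p$seeds_per_infl_mean, p$n_inflorescences)
  if (config$missing_fitness == "zero") W[is.na(W)] <- 0

  d <- data.frame(
    population_id = p$population_id, plant_id = p$plant_id,
    W = W,
    volume = stem_volume(p$basal_diameter, p$height),
    DD = p$DD, RL = p$RL, RW = p$RW, NR = p$NR,
    n_inflorescences = p$n_inflorescences,
    ISO = attack_proportion(p$iso_damaged, p$seeds_examined),
    NEO = attack_proportion(p$neo_damaged, p$seeds_examined),
    stringsAsFactors = FALSE
  )
  fl <- derive_flower_traits(experiment$flowers)
  d <- merge(d, fl[c("population_id", "plant_id", "CS", "DTW", "DTL", "PTS", "TS")],
             by = c("population_id", "plant_id"), all.x = TRUE, sort = FALSE)

  # pollen deposition where stigma counts exist
  d$pollen <- NA_real_
  st <- experiment$stigmas
  if (nrow(st)) {
    key_d <- paste(d$population_id, d$plant_id)
    key_s <- paste(st$population_id, st$plant_id)
    for (k in unique(key_s)) {
      i <- match(k, key_d)
      if (!is.na(i)) {
        d$pollen[i] <- pollen_deposition(st$grains[key_s == k],
                                         d$n_inflorescences[i])
      }
    }
  }

  # relative fitness within population
  d$w_rel <- NA_real_
  d$log_w <- NA_real_
  for (pop in unique(d$population_id)) {
    i <- d$population_id == pop
    rl <- relativize_and_log(d$W[i], offset = config$log_offset)
    d$w_rel[i] <- rl$w_rel
    if (config$log_offset > 0) {
      d$log_w[i] <- rl$log_w
    } else {
      # offset 0: defined only for positive relative fitness
      d$log_w[i] <- ifelse(rl$w_rel > 0, log(rl$w_rel), NA_real_)
    }
  }

  d <- merge(d, experiment$populations, by = "population_id", sort = FALSE)
  d[order(d$population_id, d$plant_id), , drop = FALSE]
}

# the fitness column named by the config
fitness_column <- function(config) {
  switch(config$fitness, log_rel = "log_w", rel = "w_rel")
}
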