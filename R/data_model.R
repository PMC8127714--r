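# Tabular data model: an experiment is four plain-CSV tables.
#
#   populations: population_id, site, year, seed_source, proximity
#   plants:      one row per plant; fitness components, inflorescence traits,
#                seed-predator counts
#   flowers:     long format, one row per collected disk flower (up to 5/plant)
#   stigmas:     long format, one row per collected stigma (optional)

PLANT_COLUMNS <- c(
  "population_id", "plant_id", "seeds_per_infl_mean", "n_inflorescences",
  "height", "basal_diameter", "DD", "RL", "RW", "NR",
  "iso_damaged", "neo_damaged", "seeds_examined"
)
FLOWER_COLUMNS <- c(
  "population_id", "plant_id", "flower",
  "CL", "CW", "DTL", "DTW", "PTL", "PTW", "TL", "TW"
)
STIGMA_COLUMNS <- c("population_id", "plant_id", "stigma", "grains")
POPULATION_COLUMNS <- c("population_id", "site", "year", "seed_source", "proximity")

new_experiment <- function(populations, plants, flowers,
                           stigmas = NULL, validation = NULL) {
  if (is.null(stigmas)) {
    stigmas <- as.data.frame(setNames(
      rep(list(vector(length = 0)), length(STIGMA_COLUMNS)), STIGMA_COLUMNS
    ))
  }
  ord <- order(populations$population_id)
  populations <- populations[ord, , drop = FALSE]
  plants <- plants[order(plants$population_id, plants$plant_id), , drop = FALSE]
  rownames(populations) <- rownames(plants) <- NULL
  structure(
    list(populations = populations, plants = plants,
         flowers = flowers, stigmas = stigmas),
    validation = validation,
    class = "psa_experiment"
  )
}

#' @export
print.psa_experiment <- function(x, ...) {
  cat(sprintf(
    "<psa_experiment> %d populations, %d plants, %d flower rows, %d stigma rows\n",
    nrow(x$populations), nrow(x$plants), nrow(x$flowers), nrow(x$stigmas)
  ))
  v <- attr(x, "validation")
  if (!is.null(v) && nrow(v)) cat(sprintf("  %d row(s) rejected on read\n", nrow(v)))
  invisible(x)
}

check_columns <- function(df, required, table) {
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop(sprintf("table '%s' is missing mandatory column(s): %s",
                 table, paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(TRUE)
}

# row-level invariants; returns character reasons ("" = accept)
plant_row_problems <- function(p) {
  reason <- rep("", nrow(p))
  bad <- function(cond, msg) {
    cond[is.na(cond)] <- FALSE
    reason[cond & reason == ""] <<- msg
  }
  bad(p$iso_damaged + p$neo_damaged > p$seeds_examined,
      "iso_damaged + neo_damaged exceeds seeds_examined")
  bad(p$iso_damaged < 0 | p$neo_damaged < 0 | p$seeds_examined < 0,
      "negative seed-predation count")
  bad(p$n_inflorescences < 0, "negative inflorescence count")
  bad(p$seeds_per_infl_mean < 0, "negative seeds per inflorescence")
  bad(p$height <= 0 | p$basal_diameter <= 0, "nonpositive stem measurement")
  bad(p$DD <= 0 | p$RL <= 0 | p$RW <= 0, "nonpositive inflorescence trait")
  bad(p$NR < 0, "negative ray count")
  reason
}

#' Read an experiment from a directory of CSV files
#'
#' Expects `populations.csv`, `plants.csv`, `flowers.csv` and optionally
#' `stigmas.csv` (schemas in the package data-model documentation). Rows
#' violating the plant-level invariants (e.g. more damaged seeds than seeds
#' examined, nonpositive lengths) are rejected with a per-row diagnostic;
#' the accepted data are returned in stable order (population then plant).
#'
#' @param path directory containing the CSV tables.
#' @param config a [experiment_config()] (reserved for read policies).
#' @return `psa_experiment`; rejected rows are reported via warning and
#'   recorded in `attr(x, "validation")`.
#' @export
read_experiment <- function(path, config = experiment_config()) {
  read1 <- function(name) {
    f <- file.path(path, paste0(name, ".csv"))
    if (!file.exists(f)) return(NULL)
    utils::read.csv(f, stringsAsFactors = FALSE)
  }
  populations <- read1("populations")
  plants <- read1("plants")
  flowers <- read1("flowers")
  stigmas <- read1("stigmas")
  if (is.null(populations) || is.null(plants) || is.null(flowers)) {
    stop("expected populations.csv, plants.csv and flowers.csv under ", path)
  }
  check_columns(populations, POPULATION_COLUMNS, "populations")
  check_columns(plants, PLANT_COLUMNS, "plants")
  check_columns(flowers, FLOWER_COLUMNS, "flowers")
  if (!is.null(stigmas)) check_columns(stigmas, STIGMA_COLUMNS, "stigmas")

  if (anyDuplicated(populations$population_id)) {
    stop("duplicate population_id in populations table")
  }
  if (!all(populations$proximity %in% c("near", "far"))) {
    stop("proximity must be 'near' or 'far'")
  }
  key <- paste(plants$population_id, plants$plant_id)
  if (anyDuplicated(key)) {
    stop("duplicate plant_id within a population: ",
         paste(unique(key[duplicated(key)]), collapse = ", "))
  }
  unknown <- setdiff(plants$population_id, populations$population_id)
  if (length(unknown)) {
    stop("plants reference unknown population_id: ",
         paste(unknown, collapse = ", "))
  }

  reason <- plant_row_problems(plants)
  validation <- data.frame(
    population_id = plants$population_id[reason != ""],
    plant_id = plants$plant_id[reason != ""],
    reason = reason[reason != ""],
    stringsAsFactors = FALSE
  )
  if (nrow(validation)) {
    warning(sprintf("rejected %d plant row(s); see attr(, 'validation')",
                    nrow(validation)))
    plants <- plants[reason == "", , drop = FALSE]
  }
  keep <- paste(flowers$population_id, flowers$plant_id) %in%
    paste(plants$population_id, plants$plant_id)
  flowers <- flowers[keep, , drop = FALSE]
  if (!is.null(stigmas)) {
    keep <- paste(stigmas$population_id, stigmas$plant_id) %in%
      paste(plants$population_id, plants$plant_id)
    stigmas <- stigmas[keep, , drop = FALSE]
  }
  new_experiment(populations, plants, flowers, stigmas, validation)
}

#' Write an experiment to a directory of CSV files
#'
#' Inverse of [read_experiment()]; numeric fields round-trip at full double
#' precision of the CSV text representation.
#'
#' @param experiment `psa_experiment`.
#' @param path output directory (created if needed).
#' @return `path`, invisibly.
#' @export
write_experiment <- function(experiment, path) {
  stopifnot(inherits(experiment, "psa_experiment"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  for (nm in c("populations", "plants", "flowers", "stigmas")) {
    utils::write.csv(experiment[[nm]], file.path(path, paste0(nm, ".csv")),
                     row.names = FALSE)
  }
  invisible(path)
}

#' Write named result tables with a JSON manifest
#'
#' Each table becomes one CSV; the manifest records the stage name, table
#' names and row counts, a configuration fingerprint and the RNG seed, so a
#' rerun with identical inputs reproduces byte-identical CSVs and an
#' identical manifest (timestamps are deliberately excluded).
#'
#' @param tables named list of data frames (may be empty).
#' @param path output directory.
#' @param stage short stage label recorded in the manifest.
#' @param config optional `psa_config`, fingerprinted into the manifest.
#' @param rng_seed optional integer recorded in the manifest.
#' @return the manifest (a list), invisibly.
#' @export
write_results <- function(tables, path, stage = "results",
                          config = NULL, rng_seed = NULL) {
  stopifnot(is.list(tables))
  if (length(tables) && is.null(names(tables))) stop("tables must be named")
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  entries <- lapply(names(tables), function(nm) {
    f <- file.path(path, paste0(nm, ".csv"))
    utils::write.csv(tables[[nm]], f, row.names = FALSE)
    list(table = nm, file = basename(f), rows = nrow(tables[[nm]]))
  })
  manifest <- list(
    stage = stage,
    config_hash = if (is.null(config)) NA else object_hash(unclass(config)),
    rng_seed = if (is.null(rng_seed)) NA else as.integer(rng_seed),
    tables = entries
  )
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
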