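#' Analysis configuration
#'
#' Collects the tunable knobs shared by the selection analyses: the
#' significance level, collinearity thresholds, transform policy, which
#' fitness variable selection is measured on, and how plants with no seed
#' sample are treated.
#'
#' @param alpha significance level for all tests (default 0.05).
#' @param vif_warn variance-inflation-factor level above which a
#'   drop-highest-VIF refit check is run (default 5).
#' @param vif_max VIF level above which collinearity is flagged as a failure
#'   (default 10).
#' @param cond_index_max condition-index failure threshold (default 30).
#' @param transform_policy `"none"` (standardize as-is) or `"auto"`
#'   (ln(x+1) when |skewness| > 1; arcsine-square-root for proportions).
#' @param fitness fitness variable used for differentials and gradients:
#'   `"log_rel"` (log-transformed relative fitness, the default) or
#'   `"rel"` (raw relative fitness, the classical definition).
#' @param log_offset offset c in log(w_rel + c); default 1 so zero-fitness
#'   plants remain in the analysis, `log(1) = 0`.
#' @param missing_fitness how plants without a seed sample are treated:
#'   `"exclude"` (default; fitness missing, plant dropped from fitness
#'   analyses only) or `"zero"` (treated as zero seeds).
#' @param recenter_scope homogeneity-test recentering: `"pooled"` (trait
#'   means taken across all populations, the default) or `"per_arm"`.
#' @param f_sided sidedness of variance-ratio tests: `"two"` (default) or
#'   `"one"`.
#' @param ddf_method denominator df for mixed-model ANCOVA:
#'   `"satterthwaite"` (default) or `"containment"`.
#' @param rng_seed integer seed recorded in output manifests.
#' @return object of class `psa_config` (a validated list).
#' @export
experiment_config <- function(alpha = 0.05,
                              vif_warn = 5,
                              vif_max = 10,
                              cond_index_max = 30,
                              transform_policy = c("none", "auto"),
                              fitness = c("log_rel", "rel"),
                              log_offset = 1,
                              missing_fitness = c("exclude", "zero"),
                              recenter_scope = c("pooled", "per_arm"),
                              f_sided = c("two", "one"),
                              ddf_method = c("satterthwaite", "containment"),
                              rng_seed = 1L) {
  transform_policy <- match.arg(transform_policy)
  fitness <- match.arg(fitness)
  missing_fitness <- match.arg(missing_fitness)
  recenter_scope <- match.arg(recenter_scope)
  f_sided <- match.arg(f_sided)
  ddf_method <- match.arg(ddf_method)
  stopifnot(
    is.numeric(alpha), length(alpha) == 1L, alpha > 0, alpha < 1,
    is.numeric(vif_warn), is.numeric(vif_max), vif_warn <= vif_max,
    vif_warn > 0, cond_index_max > 0,
    is.numeric(log_offset), log_offset >= 0,
    is.numeric(rng_seed), length(rng_seed) == 1L
  )
  structure(
    list(
      alpha = alpha, vif_warn = vif_warn, vif_max = vif_max,
      cond_index_max = cond_index_max, transform_policy = transform_policy,
      fitness = fitness, log_offset = log_offset,
      missing_fitness = missing_fitness, recenter_scope = recenter_scope,
      f_sided = f_sided, ddf_method = ddf_method,
      rng_seed = as.integer(rng_seed)
    ),
    class = "psa_config"
  )
}

#' Read an analysis configuration from a YAML file
#'
#' Keys mirror the arguments of [experiment_config()]; absent keys keep
#' their defaults.
#'
#' @param path YAML file.
#' @return `psa_config`.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(experiment_config))
  extra <- setdiff(names(vals), known)
  if (length(extra)) {
    stop("unknown configuration key(s): ", paste(extra, collapse = ", "))
  }
  do.call(experiment_config, vals)
}

#' @export
print.psa_config <- function(x, ...) {
  cat("<psa_config>\n")
  for (nm in names(x)) cat(sprintf("  %-17s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
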