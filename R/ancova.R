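# Proximity ANCOVA: does total or direct selection differ near vs far from
# the crop? Linear mixed models with log-relative fitness as response,
# site x proximity (x year) factorial fixed effects interacting with the
# trait covariate(s), and a random intercept per population. A significant
# trait x proximity interaction indicates consistently different selection
# by proximity; higher-order interactions with proximity indicate
# context-dependent differences.

sum_contrasts <- function(data, factors) {
  out <- list()
  for (f in factors) {
    data[[f]] <- factor(data[[f]])
    if (nlevels(data[[f]]) > 1) out[[f]] <- "contr.sum"
  }
  list(data = data, contrasts = out)
}

check_ancova_data <- function(data, covariates) {
  need <- c("site", "proximity", "population", "log_w", covariates)
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  arms <- unique(data$proximity)
  for (arm in c("near", "far")) {
    if (!(arm %in% arms)) stop("no data for proximity arm '", arm, "'")
  }
  for (cv in covariates) {
    if (stats::sd(data[[cv]], na.rm = TRUE) == 0) {
      stop("covariate '", cv, "' is constant; its terms are undefined")
    }
  }
  invisible(TRUE)
}

# containment-style denominator df: terms composed solely of the design
# factors are tested against the population stratum; terms involving a
# plant-level covariate against the residual stratum
containment_ddf <- function(data, terms, ndf) {
  n_pop <- length(unique(data$population))
  n_obs <- nrow(data)
  factors <- c("site", "proximity", "year")
  is_between <- vapply(strsplit(terms, ":", fixed = TRUE),
                       function(p) all(p %in% factors), logical(1))
  between_rank <- 1 + sum(ndf[is_between])
  resid_df <- n_obs - n_pop - sum(ndf[!is_between])
  ifelse(is_between, max(n_pop - between_rank, 1), max(resid_df, 1))
}

fit_mixed_ancova <- function(data, fixed_rhs, config, random = "population") {
  sc <- sum_contrasts(data, intersect(c("site", "proximity", "year"), names(data)))
  data <- sc$data
  data$population <- factor(data$population)
  if (random == "population") {
    form <- stats::as.formula(paste("log_w ~", fixed_rhs, "+ (1 | population)"))
    fit <- tryCatch(
      suppressMessages(lmerTest::lmer(form, data = data, contrasts = sc$contrasts)),
      error = function(e) NULL
    )
    singular <- is.null(fit) || lme4::isSingular(fit, tol = 1e-5)
    if (singular) {
      warning("random-effect fit singular; falling back to fixed-effects ANCOVA")
    }
  } else {
    fit <- NULL
    singular <- TRUE
  }
  if (!singular) {
    an <- stats::anova(fit, type = 3, ddf = "Satterthwaite")
    terms <- data.frame(
      term = rownames(an), ndf = an$NumDF, ddf = an$DenDF,
      F = an$`F value`, p = an$`Pr(>F)`, stringsAsFactors = FALSE
    )
    if (config$ddf_method == "containment") {
      terms$ddf <- containment_ddf(data, terms$term, terms$ndf)
      terms$p <- stats::pf(terms$F, terms$ndf, terms$ddf, lower.tail = FALSE)
    }
    meta <- list(converged = TRUE, singular = FALSE,
                 n_obs = nrow(fit@frame),
                 n_pop = nlevels(data$population),
                 random = "population intercept",
                 ddf_method = config$ddf_method,
                 formula = deparse(form))
  } else {
    # singular (or failed, or disabled) random effect: pooled fixed-effects
    # ANCOVA with Type III tests
    lm_form <- stats::as.formula(paste("log_w ~", fixed_rhs))
    lfit <- stats::lm(lm_form, data = data, contrasts = sc$contrasts)
    an <- car::Anova(lfit, type = 3)
    keep <- !(rownames(an) %in% c("(Intercept)", "Residuals"))
    terms <- data.frame(
      term = rownames(an)[keep], ndf = an$Df[keep],
      ddf = lfit$df.residual,
      F = an$`F value`[keep], p = an$`Pr(>F)`[keep],
      stringsAsFactors = FALSE
    )
    meta <- list(converged = TRUE, singular = TRUE,
                 n_obs = stats::nobs(lfit),
                 n_pop = nlevels(data$population),
                 random = "none (singular fallback)",
                 ddf_method = "residual",
                 formula = deparse(lm_form))
  }
  structure(list(terms = terms, meta = meta), class = "psa_ancova")
}

#' @export
print.psa_ancova <- function(x, ...) {
  cat(sprintf("<psa_ancova> %s; n = %d obs, %d populations (%s ddf)\n",
              x$meta$formula, x$meta$n_obs, x$meta$n_pop, x$meta$ddf_method))
  print(x$terms, digits = 4)
  invisible(x)
}

#' ANCOVA for total selection on one trait
#'
#' Mixed model: log-relative fitness ~ site * proximity * trait
#' (all interactions; plus year and its interactions when
#' `include_year = TRUE`), random intercept per population. The trait enters
#' as its within-population standardized value, so the trait x proximity
#' interaction tests whether the selection differential differs between
#' arms.
#'
#' @param data per-plant analysis table with columns `site`, `proximity`,
#'   (`year`,) `population`, `log_w` and the standardized trait column.
#' @param trait name of the standardized trait column.
#' @param include_year include year and its interactions.
#' @param config [experiment_config()].
#' @param random `"population"` (random intercept, the default) or `"none"`
#'   (ordinary pooled ANCOVA; the zero-random-variance limit).
#' @return `psa_ancova`: `terms` (term, ndf, ddf, F, p) and `meta`.
#' @export
ancova_total <- function(data, trait, include_year = FALSE,
                         config = experiment_config(),
                         random = c("population", "none")) {
  random <- match.arg(random)
  check_ancova_data(data, trait)
  data <- data[stats::complete.cases(data[c("log_w", trait)]), , drop = FALSE]
  data$z__ <- data[[trait]]
  rhs <- if (include_year) "site * proximity * year * z__"
         else "site * proximity * z__"
  res <- fit_mixed_ancova(data, rhs, config, random)
  res$terms$term <- gsub("z__", trait, res$terms$term)
  res$meta$trait <- trait
  res
}

#' ANCOVA for direct selection (all covariates in one model)
#'
#' One mixed model containing all nine floral traits, the two seed-damage
#' traits and stem volume, each interacting with site and proximity (and
#' year when requested), with a random intercept per population. Each
#' covariate x proximity term tests whether that trait's selection gradient
#' differs between arms.
#'
#' @param data per-plant analysis table with standardized covariate columns.
#' @param include_year include year and its interactions.
#' @param covariates covariate columns (default: the eleven analysis traits
#'   plus `volume`).
#' @param config [experiment_config()].
#' @param random `"population"` or `"none"`; see [ancova_total()].
#' @return `psa_ancova`.
#' @export
ancova_direct <- function(data, include_year = FALSE,
                          covariates = trait_sets()$gradient_covariates,
                          config = experiment_config(),
                          random = c("population", "none")) {
  random <- match.arg(random)
  check_ancova_data(data, covariates)
  data <- data[stats::complete.cases(data[c("log_w", covariates)]), , drop = FALSE]
  covs <- paste(covariates, collapse = " + ")
  rhs <- if (include_year) {
    sprintf("site * proximity * year * (%s)", covs)
  } else {
    sprintf("site * proximity * (%s)", covs)
  }
  fit_mixed_ancova(data, rhs, config, random)
}

#' Classify proximity effects from ANCOVA terms
#'
#' For each covariate: `"consistent-proximity"` when its trait x proximity
#' interaction is significant; `"context-dependent"` when only a
#' higher-order interaction involving both the trait and proximity (with
#' site and/or year) is significant; `"no-proximity-effect"` otherwise.
#'
#' @param result `psa_ancova`.
#' @param alpha significance level.
#' @param covariates covariates to classify; default: every covariate that
#'   appears in an interaction with proximity.
#' @return data frame `trait`, `class`.
#' @export
classify_effects <- function(result, alpha = 0.05, covariates = NULL) {
  terms <- result$terms
  parts <- strsplit(terms$term, ":", fixed = TRUE)
  factors <- c("site", "proximity", "year")
  trait_of <- vapply(parts, function(p) {
    tr <- setdiff(p, factors)
    if (length(tr) == 1) tr else NA_character_
  }, character(1))
  has_prox <- vapply(parts, function(p) "proximity" %in% p, logical(1))
  order_n <- lengths(parts)
  if (is.null(covariates)) {
    covariates <- unique(trait_of[!is.na(trait_of) & has_prox])
  }
  cls <- vapply(covariates, function(tr) {
    direct <- terms$p[!is.na(trait_of) & trait_of == tr & has_prox & order_n == 2]
    higher <- terms$p[!is.na(trait_of) & trait_of == tr & has_prox & order_n > 2]
    if (length(direct) && any(direct < alpha, na.rm = TRUE)) {
      "consistent-proximity"
    } else if (length(higher) && any(higher < alpha, na.rm = TRUE)) {
      "context-dependent"
    } else "no-proximity-effect"
  }, character(1))
  data.frame(trait = covariates, class = unname(cls), stringsAsFactors = FALSE)
}
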