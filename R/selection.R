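# Lande-Arnold phenotypic selection analysis per population:
# selection differentials s' (total selection: covariance between each
# standardized trait and relative fitness) and selection gradients beta
# (direct selection: partial regression coefficients from one multiple
# regression of fitness on all covariates), with collinearity diagnostics.

#' Selection differentials for one population
#'
#' s'(trait) = cov(z_trait, fitness) with the n-1 denominator; significance
#' from the p-value of the Pearson correlation test of trait against
#' fitness. No multiple-testing correction is applied. A fitness vector
#' with zero variance yields s' = 0, p = 1 by convention (no evidence of
#' selection).
#'
#' @param z matrix or data frame of within-population standardized traits.
#' @param fitness fitness vector (log-relative by default upstream).
#' @return data frame: `trait`, `s_prime`, `p_s`, `n`. Traits with fewer
#'   than 3 paired observations get NA estimates.
#' @export
selection_differentials <- function(z, fitness) {
  z <- as.data.frame(z)
  stopifnot(nrow(z) == length(fitness))
  rows <- lapply(names(z), function(nm) {
    ok <- stats::complete.cases(z[[nm]], fitness)
    n <- sum(ok)
    if (n < 3) {
      return(data.frame(trait = nm, s_prime = NA_real_, p_s = NA_real_, n = n))
    }
    zt <- z[[nm]][ok]; w <- fitness[ok]
    if (stats::sd(w) == 0 || stats::sd(zt) == 0) {
      return(data.frame(trait = nm, s_prime = 0, p_s = 1, n = n))
    }
    ct <- stats::cor.test(zt, w)
    data.frame(trait = nm, s_prime = stats::cov(zt, w),
               p_s = ct$p.value, n = n)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Collinearity diagnostics for a design matrix
#'
#' Variance inflation factors VIF_j = 1 / (1 - R^2_j), where R^2_j comes
#' from regressing covariate j on the others, and condition indices
#' sqrt(lambda_max / lambda_i) of the column-scaled cross-product matrix
#' (intercept included, columns scaled to unit length). The report fails
#' when any VIF exceeds `vif_max` or any condition index exceeds
#' `cond_index_max`, and warns when any VIF exceeds `vif_warn`.
#'
#' @param X numeric matrix/data frame of covariates (no intercept column).
#' @param config [experiment_config()] supplying the thresholds.
#' @return list of class `psa_diagnostics`: `vif` (named), `condition_indices`
#'   (sorted descending), `flag` (`"pass"`, `"warn"` or `"fail"`).
#' @export
diagnose_collinearity <- function(X, config = experiment_config()) {
  X <- as.matrix(X)
  stopifnot(ncol(X) >= 2)
  vif <- vapply(seq_len(ncol(X)), function(j) {
    fit <- stats::lm.fit(cbind(1, X[, -j, drop = FALSE]), X[, j])
    res <- fit$residuals
    tot <- sum((X[, j] - mean(X[, j]))^2)
    if (tot == 0) return(Inf)
    r2 <- 1 - sum(res^2) / tot
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  names(vif) <- colnames(X)

  Xi <- cbind(`(Intercept)` = 1, X)
  norms <- sqrt(colSums(Xi^2))
  norms[norms == 0] <- 1
  Xs <- sweep(Xi, 2, norms, "/")
  ev <- eigen(crossprod(Xs), symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev, 0)
  ci <- if (min(ev) <= .Machine$double.eps * max(ev)) {
    rep(Inf, length(ev))
  } else {
    sort(sqrt(max(ev) / ev), decreasing = TRUE)
  }
  flag <- if (any(!is.finite(vif)) || any(vif > config$vif_max) ||
              any(!is.finite(ci)) || any(ci > config$cond_index_max)) {
    "fail"
  } else if (any(vif > config$vif_warn)) "warn" else "pass"
  structure(list(vif = vif, condition_indices = ci, flag = flag),
            class = "psa_diagnostics")
}

#' Selection gradients for one population
#'
#' Ordinary least squares of fitness on all covariates simultaneously;
#' beta are the partial regression coefficients with their SEs and t-test
#' p-values. Collinearity diagnostics are attached, and when any VIF
#' exceeds `vif_warn` an additional model dropping the highest-VIF
#' covariate is fit, recording whether each remaining gradient stays
#' inside its original 95% confidence interval.
#'
#' @param z matrix/data frame of standardized covariates (traits + volume).
#' @param fitness fitness vector.
#' @param config [experiment_config()].
#' @return list of class `psa_gradients`: `estimates` (data frame `trait`,
#'   `beta`, `se_beta`, `p_beta`, `n`), `diagnostics`
#'   ([diagnose_collinearity()] report), and `refit_check` (named logical,
#'   NULL unless triggered).
#' @export
selection_gradients <- function(z, fitness, config = experiment_config()) {
  z <- as.data.frame(z)
  ok <- stats::complete.cases(z, fitness)
  zc <- as.matrix(z[ok, , drop = FALSE])
  w <- fitness[ok]
  n <- length(w)
  if (n < ncol(zc) + 2) {
    stop(sprintf("need at least %d complete plants for %d covariates, got %d",
                 ncol(zc) + 2, ncol(zc), n))
  }
  if (qr(cbind(1, zc))$rank < ncol(zc) + 1) {
    return(structure(list(
      estimates = NULL,
      diagnostics = structure(
        list(vif = setNames(rep(Inf, ncol(zc)), colnames(zc)),
             condition_indices = Inf, flag = "fail"),
        class = "psa_diagnostics"),
      refit_check = NULL
    ), class = "psa_gradients"))
  }
  fit <- stats::lm(w ~ ., data = data.frame(w = w, zc, check.names = FALSE))
  sm <- stats::summary.lm(fit)$coefficients
  est <- data.frame(
    trait = colnames(zc),
    beta = sm[-1, 1], se_beta = sm[-1, 2], p_beta = sm[-1, 4],
    n = n, stringsAsFactors = FALSE
  )
  rownames(est) <- NULL
  diagnostics <- diagnose_collinearity(zc, config)

  refit_check <- NULL
  if (any(diagnostics$vif > config$vif_warn)) {
    worst <- names(which.max(diagnostics$vif))
    keep <- setdiff(colnames(zc), worst)
    fit2 <- stats::lm(w ~ ., data = data.frame(w = w, zc[, keep, drop = FALSE],
                                               check.names = FALSE))
    sm2 <- stats::summary.lm(fit2)$coefficients
    crit <- stats::qt(0.975, df = fit$df.residual)
    lo <- est$beta - crit * est$se_beta
    hi <- est$beta + crit * est$se_beta
    i <- match(keep, est$trait)
    refit_check <- setNames(sm2[-1, 1] >= lo[i] & sm2[-1, 1] <= hi[i], keep)
  }
  structure(list(estimates = est, diagnostics = diagnostics,
                 refit_check = refit_check),
            class = "psa_gradients")
}

#' Run the full phenotypic selection analysis across populations
#'
#' For every population: standardizes the eleven analysis traits plus stem
#' volume within the population (per the configured transform policy),
#' computes selection differentials for the eleven traits and selection
#' gradients from the single multiple regression on all twelve covariates,
#' and collects collinearity diagnostics.
#'
#' @param derived per-plant table from [derive_plants()].
#' @param config [experiment_config()].
#' @return list of class `psa_result`: `estimates` (one row per population
#'   x trait: `population_id`, `proximity`, `trait`, `s_prime`, `p_s`,
#'   `n_s`, `beta`, `se_beta`, `p_beta`, `n_beta`, `flag`), and
#'   `diagnostics` (per-population list).
#' @export
run_psa <- function(derived, config = experiment_config()) {
  traits <- trait_sets()
  fit_col <- fitness_column(config)
  all_est <- list()
  diags <- list()
  for (pop in unique(derived$population_id)) {
    d <- derived[derived$population_id == pop, , drop = FALSE]
    std <- standardize_traits(d[traits$gradient_covariates],
                              policy = config$transform_policy)
    z <- as.data.frame(std$z)
    w <- d[[fit_col]]

    s_tab <- selection_differentials(
      z[intersect(traits$all, names(z))], w
    )
    grad <- tryCatch(
      selection_gradients(z, w, config),
      error = function(e) {
        warning(sprintf("population %s: gradients not estimated (%s)",
                        pop, conditionMessage(e)))
        NULL
      }
    )
    b_tab <- if (!is.null(grad) && !is.null(grad$estimates)) {
      grad$estimates
    } else {
      data.frame(trait = names(z), beta = NA_real_, se_beta = NA_real_,
                 p_beta = NA_real_, n = NA_integer_)
    }
    names(b_tab)[names(b_tab) == "n"] <- "n_beta"
    names(s_tab)[names(s_tab) == "n"] <- "n_s"
    est <- merge(s_tab, b_tab, by = "trait", all = TRUE, sort = FALSE)
    est <- cbind(
      population_id = pop,
      proximity = d$proximity[1],
      est,
      flag = if (is.null(grad)) "error" else grad$diagnostics$flag,
      stringsAsFactors = FALSE
    )
    all_est[[pop]] <- est
    diags[[pop]] <- if (is.null(grad)) NULL else grad[c("diagnostics", "refit_check")]
  }
  estimates <- do.call(rbind, all_est)
  rownames(estimates) <- NULL
  structure(list(estimates = estimates, diagnostics = diags, config = config),
            class = "psa_result")
}

#' Summarize significance rates of selection across populations
#'
#' Counts and integer percentages of population x trait cases with
#' significant total selection (s') and direct selection (beta), overall
#' and by trait class (inflorescence, disk flower, antagonist), together
#' with the count expected by chance, round(alpha x n_cases).
#'
#' @param estimates the `estimates` table of a [run_psa()] result (or any
#'   table with `trait`, `p_s`, `p_beta`).
#' @param alpha significance level (default 0.05).
#' @return list with data frames `overall` and `by_class`.
#' @export
summarize_selection <- function(estimates, alpha = 0.05) {
  traits <- trait_sets()
  class_of <- function(tr) {
    ifelse(tr %in% traits$inflorescence, "inflorescence",
           ifelse(tr %in% traits$flower, "flower",
                  ifelse(tr %in% traits$antagonist, "antagonist", "other")))
  }
  tally <- function(p) {
    ok <- !is.na(p)
    n <- sum(ok)
    sig <- sum(p[ok] < alpha)
    c(n_cases = n, n_significant = sig,
      pct_significant = if (n) round(100 * sig / n) else 0,
      expected_by_chance = round(alpha * n))
  }
  est <- estimates[estimates$trait %in% traits$all, , drop = FALSE]
  overall <- rbind(
    data.frame(coefficient = "s_prime", t(tally(est$p_s))),
    data.frame(coefficient = "beta", t(tally(est$p_beta)))
  )
  by_class <- do.call(rbind, lapply(c("inflorescence", "flower", "antagonist"),
    function(cl) {
      sub <- est[class_of(est$trait) == cl, , drop = FALSE]
      rbind(
        data.frame(coefficient = "s_prime", class = cl, t(tally(sub$p_s))),
        data.frame(coefficient = "beta", class = cl, t(tally(sub$p_beta)))
      )
    }))
  rownames(overall) <- rownames(by_class) <- NULL
  list(overall = overall, by_class = by_class)
}
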