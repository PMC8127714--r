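# Homogeneity of selection near vs far: recentering of per-population
# selection coefficients and variance-ratio F tests, pooled across traits
# and per trait.

#' Recenter a population x trait coefficient table to zero trait means
#'
#' Subtracts each trait's mean (across populations) from that trait's
#' coefficients so that differences among traits in the typical direction
#' of selection do not inflate the pooled variance comparison. Recentering
#' is pooled across both proximity arms by default; `scope = "per_arm"`
#' recenters within each arm instead.
#'
#' @param tbl data frame with columns `trait`, `value` and (for per-arm
#'   scope) `proximity`.
#' @param scope `"pooled"` or `"per_arm"`.
#' @return `tbl` with `value` recentered; traits with a single observation
#'   are dropped with a warning.
#' @export
recenter_by_trait <- function(tbl, scope = c("pooled", "per_arm")) {
  scope <- match.arg(scope)
  stopifnot(all(c("trait", "value") %in% names(tbl)))
  tbl <- tbl[!is.na(tbl$value), , drop = FALSE]
  counts <- table(tbl$trait)
  singles <- names(counts)[counts < 2]
  if (length(singles)) {
    warning("trait(s) with a single observation dropped: ",
            paste(singles, collapse = ", "))
    tbl <- tbl[!(tbl$trait %in% singles), , drop = FALSE]
  }
  group <- if (scope == "pooled") tbl$trait else paste(tbl$trait, tbl$proximity)
  tbl$value <- tbl$value - stats::ave(tbl$value, group, FUN = mean)
  tbl
}

#' Two-sided (or one-sided) p-value for a variance-ratio F statistic
#'
#' Exact central-F tail computation: two-sided p is
#' 2 * min(P(F <= f), P(F >= f)), capped at 1; one-sided is the upper
#' tail P(F >= f).
#'
#' @param f observed variance ratio (> 0).
#' @param df1,df2 numerator and denominator degrees of freedom (>= 1).
#' @param sided `"two"` or `"one"`.
#' @return p-value in [0, 1].
#' @export
f_two_sided_p <- function(f, df1, df2, sided = c("two", "one")) {
  sided <- match.arg(sided)
  if (!is.finite(f) || f <= 0) stop("F must be a positive finite number")
  if (df1 < 1 || df2 < 1) stop("degrees of freedom must be >= 1")
  upper <- stats::pf(f, df1, df2, lower.tail = FALSE)
  if (sided == "one") return(upper)
  min(1, 2 * min(stats::pf(f, df1, df2), upper))
}

#' Variance-ratio test between the far and near arms
#'
#' F = s^2_far / s^2_near with sample variances (n - 1 denominators) and
#' df (n_far - 1, n_near - 1).
#'
#' @param far,near numeric vectors of coefficients (>= 2 values each).
#' @param sided `"two"` (default) or `"one"` (tests far variance greater).
#' @return list of class `psa_varcomp`: `ratio` (= F), `F`, `df_far`,
#'   `df_near`, `p`, `sided`, `n_far`, `n_near`.
#' @export
variance_ratio_test <- function(far, near, sided = c("two", "one")) {
  sided <- match.arg(sided)
  far <- far[!is.na(far)]; near <- near[!is.na(near)]
  if (length(far) < 2 || length(near) < 2) {
    stop("need at least two values per arm")
  }
  v_far <- stats::var(far); v_near <- stats::var(near)
  if (v_far == 0 || v_near == 0) stop("zero variance in one arm")
  f <- v_far / v_near
  structure(list(
    ratio = f, F = f,
    df_far = length(far) - 1L, df_near = length(near) - 1L,
    p = f_two_sided_p(f, length(far) - 1L, length(near) - 1L, sided),
    sided = sided, n_far = length(far), n_near = length(near)
  ), class = "psa_varcomp")
}

#' @export
print.psa_varcomp <- function(x, ...) {
  cat(sprintf("F(%d, %d) = %.3f, %s-sided p = %.4g\n",
              x$df_far, x$df_near, x$F, x$sided, x$p))
  invisible(x)
}

#' Full homogeneity-of-selection suite
#'
#' Pooled tests on recentered selection differentials and gradients (all
#' traits stacked, equally weighted), plus per-trait tests on the raw
#' coefficients (no recentering), and the count of traits whose far-arm
#' variance exceeds the near-arm variance.
#'
#' @param estimates the `estimates` table from [run_psa()] (needs columns
#'   `proximity`, `trait`, `s_prime`, `beta`).
#' @param config [experiment_config()]; `recenter_scope` and `f_sided`
#'   are honored.
#' @return list: `pooled` (data frame, rows `differentials` / `gradients`),
#'   `per_trait` (data frame, one row per coefficient x trait),
#'   `far_greater` (data frame of counts per coefficient).
#' @export
homogeneity_suite <- function(estimates, config = experiment_config()) {
  stopifnot(all(c("proximity", "trait", "s_prime", "beta") %in% names(estimates)))
  one_pooled <- function(col, label) {
    tbl <- data.frame(trait = estimates$trait, value = estimates[[col]],
                      proximity = estimates$proximity)
    rec <- recenter_by_trait(tbl, scope = config$recenter_scope)
    vt <- variance_ratio_test(rec$value[rec$proximity == "far"],
                              rec$value[rec$proximity == "near"],
                              sided = config$f_sided)
    data.frame(scope = label, ratio = vt$ratio, F = vt$F,
               df_far = vt$df_far, df_near = vt$df_near, p = vt$p,
               stringsAsFactors = FALSE)
  }
  pooled <- rbind(one_pooled("s_prime", "pooled-differentials"),
                  one_pooled("beta", "pooled-gradients"))

  per_trait <- list()
  for (col in c("s_prime", "beta")) {
    for (tr in unique(estimates$trait)) {
      far <- estimates[[col]][estimates$trait == tr & estimates$proximity == "far"]
      near <- estimates[[col]][estimates$trait == tr & estimates$proximity == "near"]
      row <- tryCatch({
        vt <- variance_ratio_test(far, near, sided = config$f_sided)
        data.frame(coefficient = col, trait = tr, ratio = vt$ratio, F = vt$F,
                   df_far = vt$df_far, df_near = vt$df_near, p = vt$p)
      }, error = function(e) {
        data.frame(coefficient = col, trait = tr, ratio = NA_real_, F = NA_real_,
                   df_far = NA_integer_, df_near = NA_integer_, p = NA_real_)
      })
      per_trait[[paste(col, tr)]] <- row
    }
  }
  per_trait <- do.call(rbind, per_trait)
  rownames(per_trait) <- NULL

  far_greater <- do.call(rbind, lapply(c("s_prime", "beta"), function(col) {
    sub <- per_trait[per_trait$coefficient == col & !is.na(per_trait$ratio), ]
    data.frame(coefficient = col,
               n_traits = nrow(sub),
               n_far_greater = sum(sub$ratio > 1),
               pct_far_greater = if (nrow(sub)) round(100 * mean(sub$ratio > 1)) else NA)
  }))
  list(pooled = pooled, per_trait = per_trait, far_greater = far_greater)
}

#' Binned recentered coefficients for a distribution figure
#'
#' Histogram counts of recentered coefficients by arm, for plotting the
#' near/far distributions whose variances the pooled tests compare.
#'
#' @param estimates `estimates` table from [run_psa()].
#' @param col `"s_prime"` or `"beta"`.
#' @param breaks number of bins (pretty breaks over the pooled range).
#' @param config [experiment_config()].
#' @return data frame: `proximity`, `bin_mid`, `count`.
#' @export
homogeneity_histogram <- function(estimates, col = c("s_prime", "beta"),
                                  breaks = 20, config = experiment_config()) {
  col <- match.arg(col)
  tbl <- data.frame(trait = estimates$trait, value = estimates[[col]],
                    proximity = estimates$proximity)
  rec <- recenter_by_trait(tbl, scope = config$recenter_scope)
  brk <- pretty(range(rec$value), n = breaks)
  out <- lapply(c("far", "near"), function(arm) {
    h <- graphics::hist(rec$value[rec$proximity == arm], breaks = brk,
                        plot = FALSE)
    data.frame(proximity = arm, bin_mid = h$mids, count = h$counts)
  })
  do.call(rbind, out)
}
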