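# Piecewise structural equation modeling with local estimation:
# a directed acyclic graph over composite traits, interactor activity and
# fitness; Shipley's d-separation basis set; Fisher's C goodness of fit;
# standardized path coefficients; and multigroup near/far constraint
# testing (each path either constrained to a common coefficient or freed
# to differ between arms).

#' Specify a directed acyclic graph for piecewise SEM
#'
#' Edges can be given as text lines of the form `"A -> B"` or as a
#' data frame with columns `from`, `to`. Acyclicity is enforced.
#'
#' @param edges character vector of `"A -> B"` lines, or a data frame.
#' @param group_variable optional grouping variable name (e.g. proximity)
#'   carried along for multigroup fits.
#' @return object of class `dag_spec`: `nodes` (in topological order),
#'   `edges` (data frame `from`, `to`), `group_variable`.
#' @export
dag_spec <- function(edges, group_variable = NULL) {
  if (is.character(edges)) {
    lines <- trimws(edges[nzchar(trimws(edges))])
    parts <- strsplit(lines, "->", fixed = TRUE)
    bad <- lengths(parts) != 2
    if (any(bad)) stop("cannot parse edge line(s): ",
                       paste(lines[bad], collapse = "; "))
    edges <- data.frame(from = trimws(vapply(parts, `[`, "", 1)),
                        to = trimws(vapply(parts, `[`, "", 2)),
                        stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(edges), all(c("from", "to") %in% names(edges)))
  edges <- unique(edges[c("from", "to")])
  if (any(edges$from == edges$to)) stop("self-loops are not allowed")
  nodes <- sort(unique(c(edges$from, edges$to)))
  topo <- topological_order(nodes, edges)
  if (is.null(topo)) stop("graph is cyclic; a DAG is required")
  structure(list(nodes = topo, edges = edges, group_variable = group_variable),
            class = "dag_spec")
}

# Kahn's algorithm; lexicographic tie-break for a deterministic order.
# NULL when cyclic.
topological_order <- function(nodes, edges) {
  order <- character(0)
  remaining <- sort(nodes)
  e <- edges
  while (length(remaining)) {
    indeg0 <- remaining[!(remaining %in% e$to)]
    if (!length(indeg0)) return(NULL)
    nxt <- indeg0[1]
    order <- c(order, nxt)
    remaining <- setdiff(remaining, nxt)
    e <- e[e$from != nxt, , drop = FALSE]
  }
  order
}

dag_parents <- function(dag, node) sort(dag$edges$from[dag$edges$to == node])

dag_ancestors <- function(dag, node) {
  anc <- character(0)
  frontier <- dag_parents(dag, node)
  while (length(frontier)) {
    anc <- union(anc, frontier)
    frontier <- unique(unlist(lapply(frontier, dag_parents, dag = dag)))
    frontier <- setdiff(frontier, anc)
  }
  anc
}

#' @export
print.dag_spec <- function(x, ...) {
  cat(sprintf("<dag_spec> %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  for (i in seq_len(nrow(x$edges))) {
    cat("  ", x$edges$from[i], "->", x$edges$to[i], "\n")
  }
  invisible(x)
}

#' d-separation basis set of a DAG
#'
#' One independence claim per non-adjacent pair of nodes, conditioned on
#' the union of both nodes' parents. Each claim is ordered so that the
#' regression response `b` is not an ancestor of `a` (later node in the
#' topological order); claims are returned in a deterministic canonical
#' order (topological position of `b`, then of `a`).
#'
#' @param dag `dag_spec`.
#' @return data frame of class `basis_set`: `a`, `b`, `cond`
#'   (comma-separated conditioning set, possibly empty).
#' @export
basis_set <- function(dag) {
  stopifnot(inherits(dag, "dag_spec"))
  nodes <- dag$nodes  # topological order
  adjacent <- paste(dag$edges$from, dag$edges$to)
  claims <- list()
  n <- length(nodes)
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      for (j in seq((i + 1), n)) {
        a <- nodes[i]; b <- nodes[j]  # b later: never an ancestor of a
        if (paste(a, b) %in% adjacent || paste(b, a) %in% adjacent) next
        cond <- sort(setdiff(union(dag_parents(dag, a), dag_parents(dag, b)),
                             c(a, b)))
        claims[[length(claims) + 1L]] <-
          data.frame(a = a, b = b, cond = paste(cond, collapse = ","),
                     stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(claims)) do.call(rbind, claims) else {
    data.frame(a = character(0), b = character(0), cond = character(0))
  }
  # canonical order: topological position of response, then of predictor
  out <- out[order(match(out$b, nodes), match(out$a, nodes)), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("basis_set", "data.frame")
  out
}

#' Test the independence claims of a basis set on data
#'
#' Each claim (a, b | cond) is tested by the linear regression of `b` on
#' `a` plus the conditioning set; the claim's p-value is the two-sided
#' t-test of `a`'s coefficient. With `group` given, each claim is tested
#' within each group level and one row per group is returned.
#'
#' @param claims [basis_set()] output.
#' @param data data frame containing all claim variables.
#' @param group optional name of a grouping column in `data`.
#' @return data frame `a`, `b`, `cond`, (`group`,) `estimate`, `p`, `n`,
#'   `testable` (FALSE when n is too small or the conditioning set is
#'   collinear).
#' @export
test_claims <- function(claims, data, group = NULL) {
  vars <- unique(c(claims$a, claims$b,
                   unlist(strsplit(claims$cond[nzchar(claims$cond)], ","))))
  miss <- setdiff(vars, names(data))
  if (length(miss)) stop("claim variable(s) absent from data: ",
                         paste(miss, collapse = ", "))
  groups <- if (is.null(group)) list(`__all__` = data) else
    split(data, data[[group]])
  one <- function(a, b, cond, d, gname) {
    cond_vars <- if (nzchar(cond)) strsplit(cond, ",")[[1]] else character(0)
    cols <- c(b, a, cond_vars)
    d <- d[stats::complete.cases(d[cols]), cols, drop = FALSE]
    n <- nrow(d)
    res <- data.frame(a = a, b = b, cond = cond, group = gname,
                      estimate = NA_real_, p = NA_real_, n = n,
                      testable = FALSE, stringsAsFactors = FALSE)
    if (n < length(cond_vars) + 3) return(res)
    X <- cbind(1, as.matrix(d[c(a, cond_vars)]))
    if (qr(X)$rank < ncol(X)) return(res)
    fit <- stats::lm(stats::reformulate(c(a, cond_vars), response = b),
                     data = d)
    sm <- stats::summary.lm(fit)$coefficients
    res$estimate <- sm[a, 1]
    res$p <- sm[a, 4]
    res$testable <- TRUE
    res
  }
  rows <- list()
  for (g in names(groups)) {
    for (i in seq_len(nrow(claims))) {
      rows[[length(rows) + 1L]] <-
        one(claims$a[i], claims$b[i], claims$cond[i], groups[[g]], g)
    }
  }
  out <- do.call(rbind, rows) %||%
    data.frame(a = character(0), b = character(0), cond = character(0),
               group = character(0), estimate = numeric(0), p = numeric(0),
               n = integer(0), testable = logical(0))
  if (is.null(group)) out$group <- NULL
  rownames(out) <- NULL
  out
}

#' Fisher's C statistic
#'
#' C = -2 * sum(ln p_i) over the k basis-set p-values, compared with a
#' chi-square distribution on 2k degrees of freedom; a model-wide p above
#' 0.05 indicates good fit. An empty claim list gives C = 0, p = 1 by
#' convention; any p_i = 0 gives C = Inf, p = 0 (flagged).
#'
#' @param p_values numeric vector of basis-set p-values in [0, 1].
#' @return list: `C`, `df` (= 2k), `p_model`, `good_fit` (p > 0.05),
#'   `degenerate` (TRUE when some p_i was 0).
#' @export
fisher_c <- function(p_values) {
  p_values <- p_values[!is.na(p_values)]
  if (any(p_values < 0 | p_values > 1)) stop("p-values must lie in [0, 1]")
  k <- length(p_values)
  if (k == 0) {
    return(list(C = 0, df = 0L, p_model = 1, good_fit = TRUE,
                degenerate = FALSE))
  }
  if (any(p_values == 0)) {
    return(list(C = Inf, df = 2L * k, p_model = 0, good_fit = FALSE,
                degenerate = TRUE))
  }
  C <- -2 * sum(log(p_values))
  p_model <- stats::pchisq(C, df = 2 * k, lower.tail = FALSE)
  list(C = C, df = 2L * k, p_model = p_model, good_fit = p_model > 0.05,
       degenerate = FALSE)
}

#' Standardized path coefficients by local estimation
#'
#' Each endogenous node is regressed on its parents; with standardized
#' data the coefficients are standardized path coefficients.
#'
#' @param dag `dag_spec`.
#' @param data data frame of (standardized) node values.
#' @return data frame `from`, `to`, `coef`, `se`, `p`, `n`.
#' @export
fit_paths <- function(dag, data) {
  rows <- list()
  for (node in dag$nodes) {
    parents <- dag_parents(dag, node)
    if (!length(parents)) next
    cols <- c(node, parents)
    d <- data[stats::complete.cases(data[cols]), cols, drop = FALSE]
    X <- cbind(1, as.matrix(d[parents]))
    if (qr(X)$rank < ncol(X)) {
      stop("singular parent set for node '", node, "'")
    }
    fit <- stats::lm(stats::reformulate(parents, response = node), data = d)
    sm <- stats::summary.lm(fit)$coefficients
    rows[[node]] <- data.frame(
      from = parents, to = node,
      coef = sm[parents, 1], se = sm[parents, 2], p = sm[parents, 4],
      n = nrow(d), stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows) %||%
    data.frame(from = character(0), to = character(0), coef = numeric(0),
               se = numeric(0), p = numeric(0), n = integer(0))
  rownames(out) <- NULL
  out
}

# canonical path order: child's topological position, then parent's
canonical_paths <- function(dag) {
  e <- dag$edges
  e[order(match(e$to, dag$nodes), match(e$from, dag$nodes)), , drop = FALSE]
}

#' Multigroup piecewise SEM fit
#'
#' Determines, path by path, whether the path coefficient differs between
#' the two groups (near vs far). Paths are visited in canonical order
#' (topological by child, then by parent); for each focal path the child is
#' regressed on all its parents plus the group main effect, interactions
#' for paths already freed, and the focal parent x group interaction. An
#' interaction p-value below `alpha` frees the path (per-group coefficients
#' reported); otherwise it stays constrained (pooled coefficient,
#' controlling for the group intercept). Fisher's C is computed from the
#' basis set, testing a claim within each group when any freed path shares
#' the claim's response, and pooled otherwise (`fisher_groups` overrides).
#'
#' @param dag `dag_spec`.
#' @param data data frame with node columns and the grouping column.
#' @param group name of the grouping column (exactly 2 levels).
#' @param alpha freeing criterion (default 0.05).
#' @param min_n minimum group size (default 7).
#' @param fisher_groups `"auto"` (default rule above), `"pooled"`, or
#'   `"per_group"`.
#' @return list of class `sem_fit`: `paths` (one row per path x group for
#'   free paths, one pooled row for constrained ones, with `status`),
#'   `interaction_tests`, `fisher_C`, `df`, `p_model`, `good_fit`,
#'   `claims`, `alpha`, `groups`.
#' @export
multigroup_fit <- function(dag, data, group, alpha = 0.05, min_n = 7,
                           fisher_groups = c("auto", "pooled", "per_group")) {
  fisher_groups <- match.arg(fisher_groups)
  stopifnot(inherits(dag, "dag_spec"))
  if (!group %in% names(data)) stop("grouping column '", group, "' not found")
  data[[group]] <- factor(data[[group]])
  levels_g <- levels(droplevels(data[[group]]))
  if (length(levels_g) != 2) {
    stop("need exactly 2 groups, got ", length(levels_g))
  }
  sizes <- table(droplevels(data[[group]]))
  if (any(sizes < min_n)) {
    stop("group below minimum size (", min_n, "): ",
         paste(names(sizes)[sizes < min_n], collapse = ", "))
  }

  paths <- canonical_paths(dag)
  paths$status <- "constrained"
  inter <- data.frame(from = paths$from, to = paths$to,
                      p_interaction = NA_real_, stringsAsFactors = FALSE)

  # iterate: refit the child model with the current constraint pattern,
  # adding the focal interaction, and test it
  for (i in seq_len(nrow(paths))) {
    child <- paths$to[i]; focal <- paths$from[i]
    parents <- dag_parents(dag, child)
    freed <- paths$from[paths$to == child & paths$status == "free"]
    inter_terms <- unique(c(freed, focal))
    rhs <- c(parents, group, paste0(inter_terms, ":", group))
    cols <- c(child, parents, group)
    d <- data[stats::complete.cases(data[cols]), cols, drop = FALSE]
    fit <- stats::lm(stats::reformulate(rhs, response = child), data = d)
    cf <- stats::summary.lm(fit)$coefficients
    nm <- rownames(cf)
    hit <- grepl(paste0("^", focal, ":", group), nm) |
      grepl(paste0("^", group, ".*:", focal, "$"), nm)
    p_int <- if (any(hit)) cf[hit, 4][1] else NA_real_
    inter$p_interaction[i] <- p_int
    if (isTRUE(p_int < alpha)) paths$status[i] <- "free"
  }

  # final per-path coefficients
  rows <- list()
  for (child in unique(paths$to)) {
    parents <- dag_parents(dag, child)
    sub <- paths[paths$to == child, , drop = FALSE]
    freed <- sub$from[sub$status == "free"]
    cols <- c(child, parents, group)
    d <- data[stats::complete.cases(data[cols]), cols, drop = FALSE]
    # pooled model with group intercept + freed interactions
    rhs <- c(parents, group, if (length(freed)) paste0(freed, ":", group))
    fit <- stats::lm(stats::reformulate(rhs, response = child), data = d)
    smp <- stats::summary.lm(fit)$coefficients
    for (j in seq_len(nrow(sub))) {
      pr <- sub$from[j]
      if (sub$status[j] == "constrained") {
        rows[[length(rows) + 1L]] <- data.frame(
          from = pr, to = child, status = "constrained", group = "pooled",
          coef = smp[pr, 1], se = smp[pr, 2], p = smp[pr, 4],
          n = nrow(d), stringsAsFactors = FALSE
        )
      } else {
        # per-group coefficients from separate within-group regressions
        for (g in levels_g) {
          dg <- d[d[[group]] == g, , drop = FALSE]
          fg <- stats::lm(stats::reformulate(parents, response = child),
                          data = dg)
          smg <- stats::summary.lm(fg)$coefficients
          rows[[length(rows) + 1L]] <- data.frame(
            from = pr, to = child, status = "free", group = g,
            coef = smg[pr, 1], se = smg[pr, 2], p = smg[pr, 4],
            n = nrow(dg), stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  path_table <- do.call(rbind, rows)
  rownames(path_table) <- NULL

  # goodness of fit
  claims <- basis_set(dag)
  if (nrow(claims)) {
    freed_children <- unique(paths$to[paths$status == "free"])
    per_group_claim <- switch(
      fisher_groups,
      auto = claims$b %in% freed_children,
      pooled = rep(FALSE, nrow(claims)),
      per_group = rep(TRUE, nrow(claims))
    )
    pvals <- numeric(0)
    if (any(!per_group_claim)) {
      tc <- test_claims(claims[!per_group_claim, , drop = FALSE], data)
      pvals <- c(pvals, tc$p[tc$testable])
    }
    if (any(per_group_claim)) {
      tc <- test_claims(claims[per_group_claim, , drop = FALSE], data,
                        group = group)
      pvals <- c(pvals, tc$p[tc$testable])
    }
    fc <- fisher_c(pvals)
  } else {
    fc <- fisher_c(numeric(0))
  }

  structure(list(
    paths = path_table, interaction_tests = inter,
    fisher_C = fc$C, df = fc$df, p_model = fc$p_model,
    good_fit = fc$good_fit, claims = claims,
    alpha = alpha, groups = levels_g
  ), class = "sem_fit")
}

#' @export
print.sem_fit <- function(x, ...) {
  cat(sprintf("<sem_fit> Fisher's C = %.3f, df = %d, p = %.4g (%s fit)\n",
              x$fisher_C, x$df, x$p_model,
              if (x$good_fit) "good" else "poor"))
  cat(sprintf("  %d free, %d constrained path(s) at alpha = %g\n",
              sum(x$interaction_tests$p_interaction < x$alpha, na.rm = TRUE),
              sum(!(x$interaction_tests$p_interaction < x$alpha), na.rm = TRUE),
              x$alpha))
  print(x$paths, digits = 3)
  invisible(x)
}

#' First-principal-component composite trait with sign alignment
#'
#' First principal component of the correlation matrix of the given traits.
#' Input columns whose PC1 loading is negative are recorded as sign-flipped
#' so that every (flipped) constituent trait correlates nonnegatively with
#' the returned scores; scores are standardized to SD 1 and are invariant
#' (up to the recorded flips) to negating any input column.
#'
#' @param x data frame/matrix of trait columns (>= 2 traits, >= 3 rows).
#' @return list of class `composite_trait`: `scores` (length n, SD 1, NA
#'   where any constituent is missing), `loadings` (aligned, all >= 0),
#'   `flips` (named +1/-1), `variance_explained`, `dropped` (constant
#'   columns excluded with a warning).
#' @export
pca_composite <- function(x) {
  x <- as.data.frame(x)
  stopifnot(ncol(x) >= 2, nrow(x) >= 3)
  sds <- vapply(x, stats::sd, numeric(1), na.rm = TRUE)
  dropped <- names(x)[!is.finite(sds) | sds == 0]
  if (length(dropped)) {
    warning("constant trait(s) excluded from composite: ",
            paste(dropped, collapse = ", "))
    x <- x[setdiff(names(x), dropped)]
    if (ncol(x) < 2) stop("fewer than two non-constant traits remain")
  }
  ok <- stats::complete.cases(x)
  Z <- scale(as.matrix(x[ok, , drop = FALSE]))
  R <- stats::cor(Z)
  ev <- eigen(R, symmetric = TRUE)
  v <- ev$vectors[, 1]
  # canonical sign: largest-|loading| component positive (first on ties)
  pivot <- which.max(abs(v))
  if (v[pivot] < 0) v <- -v
  flips <- ifelse(v < 0, -1, 1)
  scores_ok <- as.vector(Z %*% v)
  scores <- rep(NA_real_, nrow(x))
  scores[ok] <- scores_ok / stats::sd(scores_ok)
  structure(list(
    scores = scores,
    loadings = setNames(abs(v), colnames(Z)),
    flips = setNames(flips, colnames(Z)),
    variance_explained = ev$values[1] / sum(ev$values),
    dropped = dropped
  ), class = "composite_trait")
}

#' Default causal model for the interactor-mediated selection analysis
#'
#' Composite inflorescence and disk-flower traits drive seed-predator
#' attack (and, when measured, pollen deposition); attack and pollen
#' deposition drive relative fitness; stem volume and inflorescence number
#' load directly on fitness.
#'
#' @param pollen include the pollen-deposition node.
#' @return `dag_spec`.
#' @export
default_sem_dag <- function(pollen = FALSE) {
  edges <- c(
    "inflorescence_PC -> ISO",
    "inflorescence_PC -> NEO",
    "flower_PC -> ISO",
    "flower_PC -> NEO",
    "ISO -> w_rel",
    "NEO -> w_rel",
    "volume -> w_rel",
    "n_inflorescences -> w_rel"
  )
  if (pollen) {
    edges <- c(edges,
               "inflorescence_PC -> pollen",
               "flower_PC -> pollen",
               "pollen -> w_rel")
  }
  dag_spec(edges, group_variable = "proximity")
}

#' Prepare per-plant data for the SEM stage
#'
#' Builds the two composite floral traits by PCA within each site x year
#' combination (sign-aligned), then standardizes every SEM variable within
#' population, returning one analysis-ready table.
#'
#' @param derived table from [derive_plants()].
#' @param config [experiment_config()].
#' @return `derived` with columns `inflorescence_PC`, `flower_PC` added and
#'   SEM variables (`ISO`, `NEO`, `pollen`, `volume`,
#'   `n_inflorescences`, `w_rel`, the composites) standardized within
#'   population.
#' @export
prepare_sem_data <- function(derived, config = experiment_config()) {
  traits <- trait_sets()
  d <- derived
  d$inflorescence_PC <- NA_real_
  d$flower_PC <- NA_real_
  for (sy in unique(paste(d$site, d$year))) {
    i <- paste(d$site, d$year) == sy
    pc_i <- pca_composite(d[i, traits$inflorescence])
    pc_f <- pca_composite(d[i, traits$flower])
    d$inflorescence_PC[i] <- pc_i$scores
    d$flower_PC[i] <- pc_f$scores
  }
  vars <- c("inflorescence_PC", "flower_PC", "ISO", "NEO", "volume",
            "n_inflorescences", "w_rel", "pollen")
  for (pop in unique(d$population_id)) {
    i <- d$population_id == pop
    for (v in vars) {
      vals <- d[[v]][i]
      s <- stats::sd(vals, na.rm = TRUE)
      if (isTRUE(is.finite(s) && s > 0)) {
        d[[v]][i] <- (vals - mean(vals, na.rm = TRUE)) / s
      }
    }
  }
  d
}
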