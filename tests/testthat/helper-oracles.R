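# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: d-separation by brute-force path enumeration,
# OLS by the normal equations, VIF by direct R^2 computation.

# ---- brute-force d-separation ------------------------------------------

# all undirected paths between a and b (sequences of distinct nodes where
# consecutive nodes are adjacent in the DAG)
enumerate_paths <- function(edges, a, b) {
  nodes <- unique(c(edges$from, edges$to))
  adj <- lapply(setNames(nodes, nodes), function(v) {
    unique(c(edges$to[edges$from == v], edges$from[edges$to == v]))
  })
  paths <- list()
  walk <- function(path) {
    last <- path[length(path)]
    if (last == b) {
      paths[[length(paths) + 1L]] <<- path
      return(invisible())
    }
    for (nxt in adj[[last]]) {
      if (!(nxt %in% path)) walk(c(path, nxt))
    }
  }
  walk(a)
  paths
}

oracle_descendants <- function(edges, v) {
  out <- character(0)
  frontier <- edges$to[edges$from == v]
  while (length(frontier)) {
    out <- union(out, frontier)
    frontier <- setdiff(unique(unlist(
      lapply(frontier, function(x) edges$to[edges$from == x])
    )), out)
  }
  out
}

# is the path blocked given conditioning set z? (standard collider rules)
path_blocked <- function(edges, path, z) {
  if (length(path) == 2) return(FALSE)
  is_edge <- function(x, y) any(edges$from == x & edges$to == y)
  for (k in 2:(length(path) - 1)) {
    prev <- path[k - 1]; mid <- path[k]; nxt <- path[k + 1]
    collider <- is_edge(prev, mid) && is_edge(nxt, mid)
    if (collider) {
      opened <- mid %in% z || any(oracle_descendants(edges, mid) %in% z)
      if (!opened) return(TRUE)
    } else {
      if (mid %in% z) return(TRUE)
    }
  }
  FALSE
}

oracle_dseparated <- function(edges, a, b, z) {
  paths <- enumerate_paths(edges, a, b)
  if (!length(paths)) return(TRUE)
  all(vapply(paths, function(p) path_blocked(edges, p, z), logical(1)))
}

# all DAGs on the given node labels with edges respecting a fixed ordering
# (every DAG is isomorphic to one of these; labels are permuted by callers
# that care about label asymmetry)
enumerate_dags <- function(labels) {
  n <- length(labels)
  pairs <- which(upper.tri(matrix(TRUE, n, n)), arr.ind = TRUE)
  out <- list()
  for (mask in 0:(2^nrow(pairs) - 1)) {
    sel <- which(bitwAnd(mask, 2^(seq_len(nrow(pairs)) - 1)) > 0)
    if (!length(sel)) next
    out[[length(out) + 1L]] <- data.frame(
      from = labels[pairs[sel, 1]],
      to = labels[pairs[sel, 2]],
      stringsAsFactors = FALSE
    )
  }
  out
}

random_dag <- function(n_nodes, p_edge = 0.4) {
  labels <- sample(paste0("V", seq_len(n_nodes)))  # shuffled labels
  keep <- stats::runif(n_nodes * (n_nodes - 1) / 2) < p_edge
  pairs <- which(upper.tri(matrix(TRUE, n_nodes, n_nodes)), arr.ind = TRUE)
  pairs <- pairs[keep, , drop = FALSE]
  if (!nrow(pairs)) return(NULL)
  data.frame(from = labels[pairs[, 1]], to = labels[pairs[, 2]],
             stringsAsFactors = FALSE)
}

# ---- linear algebra oracles --------------------------------------------

ols_normal_equations <- function(X, y) {
  Xi <- cbind(1, as.matrix(X))
  solve(crossprod(Xi), crossprod(Xi, y))[-1]
}

vif_direct <- function(X, j) {
  fit <- stats::lm(X[, j] ~ X[, -j, drop = FALSE])
  1 / (1 - summary(fit)$r.squared)
}

# columns exactly orthogonal in-sample, each mean 0 and SD exactly 1
orthogonal_design <- function(n, p) {
  M <- matrix(stats::rnorm(n * p), n, p)
  M <- scale(M, center = TRUE, scale = FALSE)
  Q <- qr.Q(qr(M))
  Q <- scale(Q, center = TRUE, scale = FALSE)  # re-center after QR
  Q <- qr.Q(qr(Q))                             # re-orthogonalize
  Z <- sweep(Q, 2, apply(Q, 2, stats::sd), "/")
  colnames(Z) <- paste0("t", seq_len(p))
  Z
}

# ---- misc ---------------------------------------------------------------

# per-population standardization of listed columns, in place
standardize_columns <- function(d, cols) {
  for (pop in unique(d$population_id)) {
    i <- d$population_id == pop
    for (v in cols) d[[v]][i] <- as.vector(scale(d[[v]][i]))
  }
  d
}

null_shift <- c(iso_rate = 1, neo_rate = 1, pollinator_rate = 1)
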