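test_that("basis sets match textbook cases", {
  chain <- dag_spec(c("X -> Y", "Y -> Z"))
  bs <- basis_set(chain)
  expect_equal(nrow(bs), 1)
  expect_equal(bs$a, "X"); expect_equal(bs$b, "Z"); expect_equal(bs$cond, "Y")

  complete3 <- dag_spec(c("A -> B", "A -> C", "B -> C"))
  expect_equal(nrow(basis_set(complete3)), 0)
  fc <- fisher_c(numeric(0))
  expect_equal(fc$C, 0); expect_equal(fc$p_model, 1)
})

test_that("every claim is d-separated and no non-adjacent pair is missed", {
  # exhaustive on 4 nodes (all DAGs over a fixed topological labelling),
  # then random shuffled-label DAGs on 5 and 6 nodes
  dags <- enumerate_dags(c("A", "B", "C", "D"))
  set.seed(71)
  extra <- Filter(Negate(is.null),
                  lapply(1:30, function(i) random_dag(sample(5:6, 1))))
  for (edges in c(dags, extra)) {
    dag <- dag_spec(edges)
    bs <- basis_set(dag)
    pairs_seen <- character(0)
    for (i in seq_len(nrow(bs))) {
      z <- if (nzchar(bs$cond[i])) strsplit(bs$cond[i], ",")[[1]] else character(0)
      expect_true(oracle_dseparated(edges, bs$a[i], bs$b[i], z),
                  info = paste(bs$a[i], bs$b[i], bs$cond[i]))
      pairs_seen <- c(pairs_seen, paste(sort(c(bs$a[i], bs$b[i])), collapse = "|"))
    }
    # completeness: every non-adjacent pair appears exactly once
    nodes <- dag$nodes
    adjacent <- c(paste(edges$from, edges$to), paste(edges$to, edges$from))
    expected <- character(0)
    if (length(nodes) >= 2) {
      cmb <- utils::combn(nodes, 2)
      for (k in seq_len(ncol(cmb))) {
        if (!(paste(cmb[1, k], cmb[2, k]) %in% adjacent)) {
          expected <- c(expected, paste(sort(cmb[, k]), collapse = "|"))
        }
      }
    }
    expect_setequal(pairs_seen, expected)
    expect_equal(anyDuplicated(pairs_seen), 0)
  }
})

test_that("claim ordering puts the response later in the causal order", {
  dag <- dag_spec(c("A -> B", "B -> C", "C -> D"))
  bs <- basis_set(dag)
  for (i in seq_len(nrow(bs))) {
    expect_false(bs$b[i] %in% selmosaic:::dag_ancestors(dag, bs$a[i]))
  }
})

test_that("Fisher's C matches the closed form and a gamma-tail oracle", {
  p <- c(0.5, 0.1)
  fc <- fisher_c(p)
  expect_equal(fc$C, -2 * sum(log(p)), tolerance = 1e-12)
  expect_equal(fc$df, 4)
  # independent tail computation through the gamma distribution
  expect_equal(fc$p_model, pgamma(fc$C / 2, shape = 2, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(fisher_c(rep(1, 3))$C, 0)
  expect_equal(fisher_c(rep(1, 3))$p_model, 1)
  # permutation invariance and monotonicity
  set.seed(72)
  ps <- runif(6)
  expect_equal(fisher_c(ps)$C, fisher_c(rev(ps))$C, tolerance = 1e-12)
  lower <- ps; lower[3] <- lower[3] / 2
  expect_gt(fisher_c(lower)$C, fisher_c(ps)$C)
  deg <- fisher_c(c(0.4, 0))
  expect_true(deg$degenerate)
  expect_equal(deg$p_model, 0)
})

test_that("claim tests are null-calibrated and detect violations", {
  dag <- dag_spec(c("X -> Y", "Y -> Z"))
  coeffs <- data.frame(from = c("X", "Y"), to = c("Y", "Z"), coef = 0.6)
  ps <- vapply(1:120, function(r) {
    d <- generate_dag_consistent(dag, coeffs, n = 60, rng_seed = 8000 + r)
    test_claims(basis_set(dag), d)$p
  }, numeric(1))
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
  # add a direct X -> Z effect: the claim must collapse
  ps2 <- vapply(1:40, function(r) {
    d <- generate_dag_consistent(dag, coeffs, n = 200, rng_seed = 9000 + r)
    d$Z <- d$Z + 0.6 * d$X
    test_claims(basis_set(dag), d)$p
  }, numeric(1))
  expect_gt(mean(ps2 < 0.05), 0.9)
  # too few rows for the conditioning set: untestable
  tiny <- generate_dag_consistent(dag, coeffs, n = 3, rng_seed = 1)
  tc <- test_claims(basis_set(dag), tiny)
  expect_false(tc$testable)
})

test_that("path fitting recovers generating coefficients", {
  dag <- dag_spec(c("A -> C", "B -> C", "C -> D"))
  coeffs <- data.frame(from = c("A", "B", "C"), to = c("C", "C", "D"),
                       coef = c(0.5, -0.3, 0.7))
  d <- generate_dag_consistent(dag, coeffs, n = 800, rng_seed = 73)
  paths <- fit_paths(dag, d)
  expect_equal(nrow(paths), 3)
  for (i in seq_len(nrow(coeffs))) {
    row <- paths[paths$from == coeffs$from[i] & paths$to == coeffs$to[i], ]
    expect_lt(abs(row$coef - coeffs$coef[i]), 2 * row$se + 1e-9)
  }
  # single parent: standardized coefficient equals the Pearson correlation
  single <- dag_spec(data.frame(from = "A", to = "B"))
  ds <- data.frame(A = as.vector(scale(rnorm(100))))
  ds$B <- as.vector(scale(0.5 * ds$A + rnorm(100)))
  p1 <- fit_paths(single, ds)
  expect_equal(p1$coef, cor(ds$A, ds$B), tolerance = 1e-10)
  # edgeless graph: nothing to fit
  none <- dag_spec(data.frame(from = "A", to = "B"))
  none$edges <- none$edges[0, ]
  expect_equal(nrow(fit_paths(none, ds)), 0)
})

test_that("composite traits align signs and ignore input polarity", {
  set.seed(74)
  n <- 50
  latent <- rnorm(n)
  X <- data.frame(a = latent + rnorm(n, 0, 0.4),
                  b = latent + rnorm(n, 0, 0.4),
                  c = -latent + rnorm(n, 0, 0.4),
                  d = latent + rnorm(n, 0, 0.4))
  pc <- pca_composite(X)
  # every (flipped) constituent correlates nonnegatively with the scores
  for (nm in names(X)) {
    expect_gte(cor(X[[nm]] * pc$flips[nm], pc$scores), 0)
  }
  expect_equal(sd(pc$scores), 1, tolerance = 1e-10)
  expect_equal(unname(pc$flips["c"]), -1)
  # negating an input column leaves the scores unchanged
  X2 <- X; X2$b <- -X2$b
  pc2 <- pca_composite(X2)
  expect_equal(pc2$scores, pc$scores, tolerance = 1e-10)
  # oracle: loadings equal the leading eigenvector up to sign
  ev <- eigen(cor(scale(X)))$vectors[, 1]
  expect_equal(abs(unname(pc$loadings)), abs(ev), tolerance = 1e-8)
  expect_equal(pc$variance_explained,
               eigen(cor(X))$values[1] / 4, tolerance = 1e-10)
  # perfectly correlated pair
  Y <- data.frame(u = latent, v = 2 * latent)
  pcy <- pca_composite(Y)
  expect_equal(pcy$variance_explained, 1, tolerance = 1e-12)
  expect_equal(unname(pcy$loadings[1]), unname(pcy$loadings[2]),
               tolerance = 1e-10)
  # constant column excluded
  expect_warning(pcz <- pca_composite(cbind(X, k = 1)), "constant")
  expect_equal(length(pcz$loadings), 4)
})

test_that("vegan agrees with the composite extraction", {
  skip_if_not_installed("vegan")
  set.seed(75)
  X <- matrix(rnorm(200), 50, 4) %*% matrix(runif(16, -1, 1), 4, 4)
  colnames(X) <- letters[1:4]
  pc <- pca_composite(as.data.frame(X))
  rda <- vegan::rda(scale(X))
  sc <- vegan::scores(rda, display = "sites", choices = 1)[, 1]
  expect_equal(abs(cor(pc$scores, sc)), 1, tolerance = 1e-8)
})

test_that("multigroup fitting frees differing paths and constrains equal ones", {
  dag <- dag_spec(c("X -> M", "M -> Y", "X -> Y"))
  cf <- function(xy) data.frame(from = c("X", "M", "X"),
                                to = c("M", "Y", "Y"), coef = c(0.5, 0.5, xy))
  free_null <- 0L; free_focal <- 0L; free_other <- 0L
  nrep <- 40
  for (r in 1:nrep) {
    near <- generate_dag_consistent(dag, cf(0.2), 100, rng_seed = 300 + r)
    far_same <- generate_dag_consistent(dag, cf(0.2), 100, rng_seed = 600 + r)
    far_diff <- generate_dag_consistent(dag, cf(0.7), 100, rng_seed = 900 + r)
    near$proximity <- "near"; far_same$proximity <- "far"
    far_diff$proximity <- "far"
    f0 <- multigroup_fit(dag, rbind(near, far_same), "proximity")
    fa <- multigroup_fit(dag, rbind(near, far_diff), "proximity")
    free_null <- free_null + sum(f0$interaction_tests$p_interaction < 0.05)
    ia <- fa$interaction_tests
    focal <- ia$from == "X" & ia$to == "Y"
    free_focal <- free_focal + (ia$p_interaction[focal] < 0.05)
    free_other <- free_other + sum(ia$p_interaction[!focal] < 0.05)
  }
  expect_gte(1 - free_null / (nrep * 3), 0.90)   # null paths stay constrained
  expect_gte(free_focal / nrep, 0.80)            # the differing path is freed
  expect_gte(1 - free_other / (nrep * 2), 0.90)
})

test_that("multigroup output reports per-group coefficients only for free paths", {
  dag <- dag_spec(c("X -> Y"))
  cf1 <- data.frame(from = "X", to = "Y", coef = 0.1)
  cf2 <- data.frame(from = "X", to = "Y", coef = 0.9)
  a <- generate_dag_consistent(dag, cf1, 150, rng_seed = 77)
  b <- generate_dag_consistent(dag, cf2, 150, rng_seed = 78)
  a$g <- "near"; b$g <- "far"
  fit <- multigroup_fit(dag, rbind(a, b), "g")
  expect_equal(unique(fit$paths$status), "free")
  expect_setequal(fit$paths$group, c("near", "far"))
  expect_gt(fit$paths$coef[fit$paths$group == "far"],
            fit$paths$coef[fit$paths$group == "near"])
  # degenerate groupings rejected
  a$g <- "near"
  expect_error(multigroup_fit(dag, a, "g"), "2 groups")
})

test_that("the SEM stage runs end to end on a synthetic population-pair", {
  gen <- generate_experiment(synthetic_config(
    n_sites = 1, n_years = 1, seed_sources = 1,
    n_plants_range = c(60L, 60L), rng_seed = 79
  ))
  d <- prepare_sem_data(derive_plants(gen$experiment))
  expect_true(all(c("inflorescence_PC", "flower_PC") %in% names(d)))
  fit <- multigroup_fit(default_sem_dag(), d, "proximity")
  expect_s3_class(fit, "sem_fit")
  expect_equal(fit$df, 2L * nrow(fit$claims))
  expect_true(is.finite(fit$fisher_C))
  # pollen variant has the three extra paths
  dagp <- default_sem_dag(pollen = TRUE)
  expect_equal(nrow(dagp$edges), 11)
})
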