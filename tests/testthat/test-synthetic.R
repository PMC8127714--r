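test_that("the generated design has one near and one far population per cell", {
  gen <- generate_experiment(synthetic_config(
    n_sites = 2, n_years = 1, seed_sources = 2,
    n_plants_range = c(80L, 155L), rng_seed = 31
  ))
  pops <- gen$experiment$populations
  expect_equal(nrow(pops), 8)
  expect_equal(sum(pops$proximity == "near"), 4)
  counts <- table(gen$experiment$plants$population_id)
  expect_true(all(counts >= 80 & counts <= 155))
  # every site x source cell is paired
  cell <- paste(pops$site, pops$seed_source)
  expect_true(all(table(cell) == 2))
})

test_that("generation is deterministic and independent of design order", {
  cfg <- synthetic_config(n_sites = 2, n_years = 1, seed_sources = 1,
                          n_plants_range = c(20L, 30L), rng_seed = 33)
  g1 <- generate_experiment(cfg)
  g2 <- generate_experiment(cfg)
  expect_identical(g1$experiment$plants, g2$experiment$plants)
  expect_identical(g1$experiment$flowers, g2$experiment$flowers)
  # populations are keyed by id: a 1-site design reproduces the same S1
  # populations as the 2-site design
  cfg1 <- synthetic_config(n_sites = 1, n_years = 1, seed_sources = 1,
                           n_plants_range = c(20L, 30L), rng_seed = 33)
  g3 <- generate_experiment(cfg1)
  s1 <- g1$experiment$plants[g1$experiment$plants$population_id %in%
                               g3$experiment$plants$population_id, ]
  rownames(s1) <- NULL
  expect_identical(s1, g3$experiment$plants)
})

test_that("far populations suffer more seed-predator attack when shifted", {
  gen <- generate_experiment(synthetic_config(
    n_sites = 2, n_years = 1, seed_sources = 2,
    n_plants_range = c(60L, 60L), rng_seed = 35
  ))
  d <- derive_plants(gen$experiment)
  iso <- tapply(d$ISO, d$proximity, mean)
  neo <- tapply(d$NEO, d$proximity, mean)
  expect_gt(iso[["far"]], iso[["near"]])
  expect_gt(neo[["far"]], neo[["near"]])
})

test_that("with zero true gradients and tiny noise, estimates are null", {
  traits9 <- trait_sets()$all[1:9]
  beta0 <- setNames(rep(0, 9), traits9)
  cfgp <- experiment_config(fitness = "log_rel", log_offset = 0)
  hits <- c()
  for (r in 1:40) {
    gen <- generate_experiment(synthetic_config(
      n_sites = 1, n_years = 1, seed_sources = 1,
      n_plants_range = c(100L, 100L), beta_true = beta0, beta_volume = 0,
      penalty_iso = 0, penalty_neo = 0, noise_sd = 0.01,
      attack_coef_iso = c(DD = 0), attack_coef_neo = c(DD = 0),
      rng_seed = 4000 + r
    ))
    res <- run_psa(derive_plants(gen$experiment, cfgp), cfgp)
    est <- res$estimates[res$estimates$trait %in% traits9 &
                           res$estimates$population_id == "S1_Y1_B_near", ]
    hits <- c(hits, abs(est$beta) < 3 * est$se_beta)
  }
  expect_gte(mean(hits), 0.95)
})

test_that("DAG-consistent simulation satisfies its independence structure", {
  chain <- dag_spec(c("X -> Y", "Y -> Z"))
  coeffs <- data.frame(from = c("X", "Y"), to = c("Y", "Z"), coef = 0.5)
  d <- generate_dag_consistent(chain, coeffs, n = 10000, rng_seed = 41)
  # partial correlation of X and Z given Y vanishes
  rx <- resid(lm(X ~ Y, d)); rz <- resid(lm(Z ~ Y, d))
  expect_lt(abs(cor(rx, rz)), 0.03)

  lonely <- dag_spec(data.frame(from = "A", to = "B"))
  d2 <- generate_dag_consistent(lonely, data.frame(from = "A", to = "B", coef = 0),
                                n = 8000, rng_seed = 42)
  expect_lt(abs(cor(d2$A, d2$B)), 0.04)

  # coefficient recovery within 2 SE
  d3 <- generate_dag_consistent(chain, coeffs, n = 500, rng_seed = 43)
  fit <- summary(lm(Z ~ Y, d3))$coefficients
  expect_lt(abs(fit["Y", 1] - 0.5), 2 * fit["Y", 2])
})

test_that("cyclic graphs and incomplete coefficient tables are rejected", {
  expect_error(dag_spec(c("A -> B", "B -> A")), "cyclic")
  chain <- dag_spec(c("X -> Y", "Y -> Z"))
  expect_error(
    generate_dag_consistent(chain, data.frame(from = "X", to = "Y", coef = 1),
                            n = 10),
    "missing coefficient"
  )
})

test_that("the worked fixture is stable and flows through the pipeline", {
  fx <- worked_fixture()
  expect_equal(nrow(fx$plants), 12)
  expect_equal(nrow(fx$populations), 2)
  d <- derive_plants(fx)
  expect_equal(nrow(d), 12)
  expect_equal(as.numeric(tapply(d$w_rel, d$population_id, mean)), c(1, 1),
               tolerance = 1e-12)
})
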