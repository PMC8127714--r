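test_that("whole-plant seed production is the product of its components", {
  expect_equal(whole_plant_seeds(12.5, 10), 125)
  expect_equal(whole_plant_seeds(runif(20, 0, 50), 0), rep(0, 20))
  set.seed(1)
  s <- runif(50, 0, 40); k <- rpois(50, 20)
  expect_equal(whole_plant_seeds(s, k), s * k)
  expect_error(whole_plant_seeds(-1, 3), "nonnegative")
})

test_that("stem volume is a cylinder in mm^3 with height converted from cm", {
  expect_equal(stem_volume(2, 0.1), pi)          # r = 1 mm, h = 1 mm
  d <- runif(30, 1, 30); h <- runif(30, 10, 200)
  expect_equal(stem_volume(2 * d, h) / stem_volume(d, h), rep(4, 30))
  expect_equal(stem_volume(d, h), pi * (d / 2)^2 * (h * 10),
               tolerance = 1e-12)
  expect_error(stem_volume(0, 10), "positive")
})

test_that("flower composites are means of per-flower products", {
  fl <- data.frame(
    population_id = "P", plant_id = c("a", "b", "b"), flower = c(1, 1, 2),
    CL = c(2, 1, 3), CW = c(3, 4, 2),
    DTL = c(2, 2, 4), DTW = c(1, 1, 3),
    PTL = c(1, 2, 2), PTW = c(1, 1, 3),
    TL = c(2, 2, 2), TW = c(1, 1, 2)
  )
  out <- derive_flower_traits(fl)
  a <- out[out$plant_id == "a", ]; b <- out[out$plant_id == "b", ]
  expect_equal(a$CS, 6)
  expect_equal(b$CS, mean(c(1 * 4, 3 * 2)))        # mean of products = 5
  # product of means would be mean(CL)*mean(CW) = 2*3 = 6: must differ
  expect_false(isTRUE(all.equal(b$CS, mean(c(1, 3)) * mean(c(4, 2)))))
  expect_equal(b$PTS, mean(c(2, 6)))
  expect_equal(b$DTW, 2); expect_equal(b$DTL, 3)
  expect_equal(out$n_flowers, c(1, 2))

  set.seed(7)  # random fixtures against the direct formula
  fl2 <- data.frame(
    population_id = "P", plant_id = rep(sprintf("p%d", 1:8), each = 5),
    flower = rep(1:5, 8),
    CL = runif(40, 1, 3), CW = runif(40, 2, 4),
    DTL = runif(40, 2, 3), DTW = runif(40, 1, 2),
    PTL = runif(40, 1, 2), PTW = runif(40, 1, 2),
    TL = runif(40, 1, 3), TW = runif(40, 0.4, 0.8)
  )
  out2 <- derive_flower_traits(fl2)
  for (p in unique(fl2$plant_id)) {
    sub <- fl2[fl2$plant_id == p, ]
    expect_equal(out2$TS[out2$plant_id == p], mean(sub$TL * sub$TW),
                 tolerance = 1e-12)
  }
})

test_that("attack proportions handle boundaries and empty samples", {
  expect_equal(attack_proportion(4, 80), 0.05)
  expect_equal(attack_proportion(0, 80), 0)
  expect_equal(attack_proportion(80, 80), 1)
  expect_warning(p <- attack_proportion(0, 0), "NA")
  expect_true(is.na(p))
  expect_error(attack_proportion(5, 4), "damaged")
})

test_that("pollen deposition scales stigma means by 100 flowers per inflorescence", {
  expect_equal(pollen_deposition(c(2, 4), 3), 900)
  expect_equal(pollen_deposition(0, 17), 0)
  expect_true(is.na(pollen_deposition(numeric(0), 5)))
  set.seed(2)
  counts <- rpois(9, 4)
  expect_equal(pollen_deposition(counts, 7), mean(counts) * 100 * 7)
})

test_that("relative fitness is mean-normalized and log handles zeros", {
  rl <- relativize_and_log(c(0, 10, 20))
  expect_equal(rl$w_rel, c(0, 1, 2))
  expect_equal(rl$log_w[1], 0)                      # ln(0 + 1)
  set.seed(3)
  W <- rpois(40, 200)
  expect_equal(mean(relativize_and_log(W)$w_rel), 1, tolerance = 1e-12)
  expect_error(relativize_and_log(c(0, 0, 0)), "zero")
})

test_that("standardization yields exact z-scores and drops constants", {
  set.seed(4)
  x <- data.frame(a = rnorm(30, 5, 2), b = rexp(30), c = rep(1, 30))
  expect_warning(std <- standardize_traits(x), "zero-variance.*c")
  expect_equal(colnames(std$z), c("a", "b"))
  expect_equal(unname(colMeans(std$z)), c(0, 0), tolerance = 1e-12)
  expect_equal(unname(apply(std$z, 2, sd)), c(1, 1), tolerance = 1e-12)
  expect_equal(std$z[, "a"], (x$a - mean(x$a)) / sd(x$a), tolerance = 1e-12)
  # idempotence under the identity policy
  std2 <- standardize_traits(as.data.frame(std$z), policy = "none")
  expect_equal(std2$z, std$z, tolerance = 1e-12)
})

test_that("the auto policy log-transforms skewed variables and records it", {
  set.seed(5)
  x <- data.frame(sym = rnorm(200), skew = rlnorm(200, 0, 1.5),
                  prop = rbeta(200, 0.2, 4))
  std <- standardize_traits(x, policy = "auto")
  expect_equal(unname(std$transforms["sym"]), "identity")
  expect_equal(unname(std$transforms["skew"]), "log1p")
  expect_equal(unname(std$transforms["prop"]), "asin_sqrt")
  expect_equal(std$z[, "skew"],
               as.vector(scale(log1p(x$skew))), tolerance = 1e-12)
})

test_that("derived traits do not depend on plant ordering", {
  gen <- generate_experiment(synthetic_config(
    n_sites = 1, n_years = 1, seed_sources = 1,
    n_plants_range = c(12L, 12L), rng_seed = 9
  ))$experiment
  d1 <- derive_plants(gen)
  gen2 <- gen
  perm <- sample(nrow(gen2$plants))
  gen2$plants <- gen2$plants[perm, ]
  d2 <- derive_plants(gen2)
  d2 <- d2[match(paste(d1$population_id, d1$plant_id),
                 paste(d2$population_id, d2$plant_id)), ]
  expect_equal(d1$w_rel, d2$w_rel, tolerance = 1e-12)
  expect_equal(d1$CS, d2$CS, tolerance = 1e-12)
})

test_that("plants without a seed sample follow the configured policy", {
  fx <- worked_fixture()
  i <- which(fx$plants$population_id == "FIX_near" & fx$plants$plant_id == "P01")
  fx$plants$seeds_per_infl_mean[i] <- NA
  d_ex <- derive_plants(fx, experiment_config(missing_fitness = "exclude"))
  expect_true(is.na(d_ex$W[d_ex$plant_id == "P01" &
                             d_ex$population_id == "FIX_near"]))
  d_z <- derive_plants(fx, experiment_config(missing_fitness = "zero"))
  expect_equal(d_z$W[d_z$plant_id == "P01" & d_z$population_id == "FIX_near"], 0)
})
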