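test_that("composite fitness follows the survival x ln(1+biomass) definition", {
  tt <- transplant_table(data.frame(
    plant_id = c("a", "b", "c"), phenotype = "P1", habitat = "desert",
    water = "ambient", survived = c(0, 1, 1),
    biomass = c(10, 0, exp(1) - 1),
    death_cause = c("other", "alive", "alive")))
  expect_equal(composite_fitness(tt), c(0, 0, 1))
})

test_that("selection coefficients match hand arithmetic and invariants", {
  # two phenotypes with cell means 2.0 and 0.5: s = (0, 0.75)
  tt <- transplant_table(data.frame(
    plant_id = paste0("p", 1:4), phenotype = c("P1", "P1", "P2", "P2"),
    habitat = "desert", water = "ambient", survived = 1,
    biomass = c(exp(2) - 1, exp(2) - 1, exp(0.5) - 1, exp(0.5) - 1),
    death_cause = "alive"))
  fs <- selection_coefficients(tt, B = 0)
  expect_equal(fs$s[fs$phenotype == "P1"], 0)
  expect_equal(fs$s[fs$phenotype == "P2"], 0.75)

  # identical cells: all s = 0 and degenerate bootstrap CIs of width 0
  fx <- make_transplant_fixture()
  same <- fx; same$biomass <- 2
  fs2 <- selection_coefficients(transplant_table(as.data.frame(same)),
                                B = 50, seed = 1)
  expect_true(all(fs2$s == 0))
  expect_true(all(fs2$ci_hi - fs2$ci_lo == 0))
})

test_that("per habitat exactly one phenotype has s = 0 and all s in [0,1]", {
  for (sd in 1:5) {
    tt <- simulate_transplant(sim_config(seed = sd))
    fs <- selection_coefficients(tt, B = 0)
    expect_true(all(fs$s >= 0 & fs$s <= 1))
    zeros <- tapply(fs$s, fs$habitat, function(s) sum(s == 0))
    expect_true(all(zeros == 1))
  }
})

test_that("bootstrap is reproducible, truncated, and respects resampling scope", {
  tt <- simulate_transplant(sim_config(seed = 11))
  a <- selection_coefficients(tt, B = 100, seed = 5)
  b <- selection_coefficients(tt, B = 100, seed = 5)
  expect_identical(a, b)
  expect_true(all(a$ci_lo >= 0 & a$ci_hi <= 1))
  expect_true(all(a$ci_lo <= a$ci_hi))
  h <- selection_coefficients(tt, B = 50, seed = 5, resample = "habitat")
  expect_true(all(h$ci_lo >= 0 & h$ci_hi <= 1))
  expect_error(selection_coefficients(tt, B = 10), "seed")
  one <- tt[tt$phenotype == "P1" & tt$habitat == "desert", ]
  expect_error(selection_coefficients(
    transplant_table(as.data.frame(one)), B = 0), "fewer than 2 phenotypes")
})

test_that("NB GLM: intercept-only fitted mean equals the sample mean", {
  set.seed(2)
  d <- data.frame(y = rnbinom(300, size = 2, mu = 6))
  m <- fit_nb_glm(y ~ 1, d)
  expect_equal(exp(m$coefficients[1, 1]), mean(d$y), tolerance = 1e-6)
})

test_that("NB GLM recovers cell means and dispersion from simulated counts", {
  set.seed(3)
  n <- 1000
  d <- expand.grid(habitat = c("desert", "dune"), phenotype = c("P1", "P2"),
                   i = seq_len(n))
  mu <- with(d, exp(1 + 0.6 * (habitat == "dune") + 0.8 * (phenotype == "P2")))
  d$y <- rnbinom(nrow(d), size = 2, mu = mu)
  m <- fit_nb_glm(y ~ habitat + phenotype, d)
  pred <- exp(m$coefficients[, 1])
  expect_lt(abs(pred[1] - exp(1)) / exp(1), 0.05)
  expect_lt(abs(m$coefficients[2, 1] - 0.6), 0.05)
  expect_lt(abs(m$coefficients[3, 1] - 0.8), 0.05)
  expect_lt(abs(m$theta - 2) / 2, 0.2)
})

test_that("large-dispersion limit matches an independent Poisson oracle", {
  set.seed(4)
  d <- expand.grid(g = c("a", "b"), i = 1:400)
  d$y <- rpois(nrow(d), lambda = exp(1.2 + 0.5 * (d$g == "b")))
  m <- fit_nb_glm(y ~ g, d)
  oracle <- glm(y ~ g, data = d, family = poisson)
  expect_lt(max(abs(m$coefficients[, 1] - coef(oracle))), 1e-4)
})

test_that("NB GLM accepts continuous ln(1+x) responses and flags zero cells", {
  tt <- simulate_transplant(sim_config(seed = 6))
  d <- data.frame(tt, fitness = composite_fitness(tt))
  m <- suppressWarnings(fit_nb_glm(fitness ~ habitat * phenotype, d))
  expect_true(is.finite(m$loglik))
  expect_gte(m$deviance, 0)
  expect_error(fit_nb_glm(I(fitness - 100) ~ habitat, d), "non-negative")

  # an all-zero design cell is flagged
  cells <- default_transplant_cells()
  cells$p_surv[cells$habitat == "dune" & cells$phenotype == "P1"] <- 0
  tt0 <- simulate_transplant(sim_config(
    transplant = list(n_per_cell = 20, cells = cells,
                      biomass_model = "lognormal"), seed = 8))
  d0 <- data.frame(tt0, fitness = composite_fitness(tt0))
  expect_warning(fit_nb_glm(fitness ~ habitat * phenotype, d0), "all-zero")
})

test_that("LR test contracts: identical models, nesting, power", {
  set.seed(5)
  d <- expand.grid(h = c("a", "b"), p = c("x", "y"), i = 1:50)
  d$y <- rnbinom(nrow(d), size = 2, mu = exp(1 + 0.4 * (d$h == "b")))
  full <- fit_nb_glm(y ~ h + p, d)
  expect_equal(lr_interaction_test(full, full)$p_value, 1)
  red <- fit_nb_glm(y ~ h, d)
  lt <- lr_interaction_test(full, red)
  expect_equal(lt$df, 1)
  expect_gte(lt$lr, 0)
  expect_error(lr_interaction_test(red, fit_nb_glm(y ~ p, d)), "nested")

  # power: a strong interaction (1.0 on the log scale) is detected
  reject <- logical(100)
  for (r in seq_len(100)) {
    d$y <- rnbinom(nrow(d), size = 2,
                   mu = exp(1 + 0.3 * (d$h == "b") + 0.3 * (d$p == "y") +
                              1.0 * (d$h == "b") * (d$p == "y")))
    f <- fit_nb_glm(y ~ h * p, d)
    g <- fit_nb_glm(y ~ h + p, d)
    reject[r] <- lr_interaction_test(f, g)$p_value < 0.05
  }
  expect_gte(mean(reject), 0.9)
})
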