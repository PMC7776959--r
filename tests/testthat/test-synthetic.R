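test_that("generators are bit-reproducible under a fixed seed", {
  cfg <- sim_config(n_loci = 60, seed = 99)
  a <- simulate_genotypes(cfg); b <- simulate_genotypes(cfg)
  expect_identical(a, b)
  ta <- simulate_transect(cfg, 50); tb <- simulate_transect(cfg, 50)
  expect_identical(ta, tb)
  xa <- simulate_transplant(cfg); xb <- simulate_transplant(cfg)
  expect_identical(xa, xb)
})

test_that("forced-frequency classes produce the deterministic genotypes", {
  cfg <- sim_config(n_loci = 30, divergence = list(f1 = 1, f2 = 0),
                    class_counts = c(F1 = 3, P1 = 2),
                    ref_counts = c(P1 = 1, P2 = 1), seed = 5)
  sim <- simulate_genotypes(cfg)
  f1s <- sim$S$sample_id[grepl("query_F1", sim$S$sample_id)]
  expect_true(all(unclass(sim$G)[f1s, ] == 1L))   # forced heterozygosity
  p1s <- sim$S$sample_id[grepl("query_P1", sim$S$sample_id)]
  expect_true(all(unclass(sim$G)[p1s, ] == 2L))
  expect_error(sim_config(class_counts = c(XX = 3)), "invalid class name")
})

test_that("BC1 mean dosage and F1 heterozygosity match origin-weight expectations", {
  cfg <- sim_config(n_loci = 10000, divergence = list(f1 = 0.9, f2 = 0.1),
                    class_counts = c(BC1 = 1, F1 = 1),
                    ref_counts = c(P1 = 1, P2 = 1), seed = 21)
  sim <- simulate_genotypes(cfg)
  bc1 <- unclass(sim$G)[grepl("query_BC1", rownames(sim$G)), ]
  # E[dosage] = 2*(0.75*0.9 + 0.25*0.1) = 1.4; MC error ~ 3*sd/sqrt(1e4)
  expect_lt(abs(mean(bc1) - 1.4), 0.025)
  f1g <- unclass(sim$G)[grepl("query_F1", rownames(sim$G)), ]
  het_expected <- 0.9 * (1 - 0.1) + 0.1 * (1 - 0.9)  # f1(1-f2)+f2(1-f1)
  expect_lt(abs(mean(f1g == 1) - het_expected), 0.02)
})

test_that("transect generator follows the tanh cline in expectation", {
  cfg <- sim_config(cline = list(center = 10, width = 40, pmin = 0.05,
                                 pmax = 0.95, concentration = 200,
                                 span = 300), seed = 2)
  tr <- simulate_transect(cfg, 400)
  # at the center the expectation is the tail midpoint
  expect_equal(cline_expected(10, 10, 40, 0.05, 0.95), 0.5)
  # beyond +/- 2 widths of center the expectation is within 0.01 of a tail
  far <- abs(tr$position - 10) > 80
  tail_val <- ifelse(tr$position[far] > 10, 0.95, 0.05)
  expect_true(all(abs(tr$expected[far] - tail_val) < 0.01))
  expect_true(all(tr$q >= 0 & tr$q <= 1))
  cfg_bad <- cfg; cfg_bad$cline$width <- -5
  expect_error(simulate_transect(cfg_bad, 10), "width")
})

test_that("transplant generator honours cell parameters", {
  cells <- default_transplant_cells()
  # survival 0 in one cell kills every plant there
  cells0 <- cells
  cells0$p_surv[cells0$habitat == "dune" & cells0$phenotype == "P1"] <- 0
  cfg <- sim_config(transplant = list(n_per_cell = 25, cells = cells0,
                                      biomass_model = "lognormal"),
                    seed = 13)
  tt <- simulate_transplant(cfg)
  dune_p1 <- tt[tt$habitat == "dune" & tt$phenotype == "P1", ]
  expect_true(all(dune_p1$survived == 0))
  # no burial deaths in the desert; P2 never dies of burial
  expect_equal(sum(tt$death_cause == "burial" & tt$habitat == "desert"), 0)
  expect_equal(sum(tt$death_cause == "burial" & tt$phenotype == "P2"), 0)

  # CLT check on a big cell: mean ln(1+biomass) within 3 SE of the
  # integral truth
  one <- cells[cells$habitat == "desert" & cells$phenotype == "P1", ]
  cfg2 <- sim_config(transplant = list(n_per_cell = 10000, cells = one,
                                       biomass_model = "lognormal"),
                     seed = 31)
  t2 <- simulate_transplant(cfg2)
  g <- log1p(t2$biomass[t2$survived == 1])
  truth <- expected_ln1p_lognormal(one$meanlog, one$sdlog)
  expect_lt(abs(mean(g) - truth), 3 * sd(g) / sqrt(length(g)))

  bad <- cells; bad$p_other <- bad$p_other + 0.1
  expect_error(simulate_transplant(
    sim_config(transplant = list(n_per_cell = 5, cells = bad,
                                 biomass_model = "lognormal"), seed = 1)),
    "sum to 1")
})

test_that("default transplant cells encode the stated selection regime", {
  cells <- default_transplant_cells()
  truthy <- attr(simulate_transplant(sim_config(seed = 1)), "truth")
  s <- truthy$s_true
  names(s) <- paste(truthy$habitat, truthy$phenotype)
  expect_equal(unname(s["dune P1"]), 0.983, tolerance = 1e-9)
  expect_equal(unname(s["desert P2"]), 0.755, tolerance = 1e-9)
  expect_equal(unname(s["desert HYB"]), 0.097, tolerance = 1e-9)
  # the solved meanlog reproduces the target composite via the model
  i <- which(cells$habitat == "dune" & cells$phenotype == "HYB")
  expect_equal(cells$p_surv[i] *
                 expected_ln1p_lognormal(cells$meanlog[i], cells$sdlog[i]),
               cells$composite_true[i], tolerance = 1e-6)
})
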