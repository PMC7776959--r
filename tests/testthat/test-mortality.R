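test_that("saturated IPF reproduces the table exactly with G2 = 0", {
  set.seed(1)
  tab <- rand_table3()
  f <- ipf_fit(tab, list(1:3))
  expect_equal(unname(f$fitted), unname(unclass(tab)), tolerance = 1e-10)
  expect_equal(f$G2, 0, tolerance = 1e-8)
  expect_equal(f$df, 0)
})

test_that("complete independence matches the closed-form margin product", {
  set.seed(2)
  tab <- rand_table3(dims = c(2, 2, 2))
  f <- ipf_fit(tab, list(1, 2, 3))
  N <- sum(tab)
  m1 <- apply(tab, 1, sum); m2 <- apply(tab, 2, sum); m3 <- apply(tab, 3, sum)
  expected <- outer(outer(m1, m2), m3) / N^2
  expect_equal(unname(f$fitted), unname(expected), tolerance = 1e-7)
  expect_equal(f$df, 8 - 1 - (1 + 1 + 1))
})

test_that("IPF agrees with the stats::loglin oracle on random models", {
  set.seed(3)
  models <- list(list(1, 2, 3), list(c(1, 2), 3), list(c(1, 2), c(1, 3)),
                 list(c(1, 2), c(1, 3), c(2, 3)), list(c(1, 3), 2))
  for (rep in 1:3) {
    tab <- rand_table3()
    for (m in models) {
      mine <- ipf_fit(tab, m)
      orc <- loglin(tab, m, fit = TRUE, print = FALSE)
      expect_equal(mine$G2, orc$lrt, tolerance = 1e-5)
      expect_equal(mine$df, orc$df)
      expect_equal(unname(mine$fitted), unname(orc$fit), tolerance = 1e-4)
    }
  }
})

test_that("fitted margins named in the model are reproduced to 1e-8", {
  set.seed(4)
  for (rep in 1:5) {
    tab <- rand_table3(dims = c(3, 2, 2))
    m <- list(c(1, 2), c(2, 3))
    f <- ipf_fit(tab, m)
    expect_true(f$converged)
    for (mm in m)
      expect_lt(max(abs(apply(f$fitted, mm, sum) - apply(tab, mm, sum))),
                1e-8)
  }
})

test_that("G2 is monotone under model nesting", {
  set.seed(5)
  nested_pairs <- list(
    list(small = list(1, 2, 3), big = list(c(1, 2), 3)),
    list(small = list(c(1, 2), 3), big = list(c(1, 2), c(1, 3))),
    list(small = list(c(1, 2), c(1, 3)), big = list(c(1, 2), c(1, 3), c(2, 3))),
    list(small = list(c(1, 2), c(1, 3), c(2, 3)), big = list(1:3)))
  for (rep in 1:5) {
    tab <- rand_table3()
    for (pair in nested_pairs) {
      g_small <- ipf_fit(tab, pair$small)$G2
      g_big <- ipf_fit(tab, pair$big)$G2
      expect_gte(g_small, g_big - 1e-6)
    }
  }
})

test_that("delta G2 equals twice the Poisson log-likelihood difference", {
  set.seed(6)
  tab <- rand_table3(dims = c(2, 2, 2))
  pois_ll <- function(fit) {
    obs <- as.numeric(tab); mu <- as.numeric(fit)
    sum(ifelse(obs > 0, obs * log(mu), 0) - mu - lgamma(obs + 1))
  }
  f_full <- ipf_fit(tab, list(c(1, 2), c(1, 3), c(2, 3)))
  f_red <- ipf_fit(tab, list(c(1, 2), 3))
  dG2 <- f_red$G2 - f_full$G2
  expect_equal(dG2, 2 * (pois_ll(f_full$fitted) - pois_ll(f_red$fitted)),
               tolerance = 1e-6)
})

test_that("redundant and malformed margin specs are handled", {
  tab <- rand_table3(dims = c(2, 2, 2))
  a <- ipf_fit(tab, list(c(1, 2), 1))  # subset margin is redundant
  b <- ipf_fit(tab, list(c(1, 2)))
  expect_equal(a$G2, b$G2)
  expect_equal(a$df, b$df)
  expect_error(ipf_fit(tab, list(4)), "out of range")
  expect_error(ipf_fit(array(-1, c(2, 2, 2)), list(1)), "non-negative")
})

test_that("backward stepwise keeps a hard-coded three-way dependence", {
  tab <- array(40, c(2, 2, 2),
               dimnames = list(h = c("a", "b"), p = c("x", "y"),
                               o = c("u", "v")))
  tab[1, 1, 1] <- 400  # one cell inflated 10x
  st <- backward_stepwise(tab)
  expect_equal(st$trail$term[1], "h:p:o")
  expect_false(st$trail$removed[1])
  expect_identical(st$model, list(1:3))
})

test_that("identical outcome layers lead to removal of outcome interactions", {
  set.seed(7)
  layer <- matrix(rpois(9, 30), 3, 3)
  tab <- array(c(layer, layer), c(3, 3, 2),
               dimnames = list(h = paste0("h", 1:3), p = paste0("p", 1:3),
                               o = c("u", "v")))
  st <- backward_stepwise(tab)
  final_terms <- lapply(st$model, as.integer)
  expect_false(any(vapply(final_terms, function(t)
    3 %in% t && length(t) > 1, logical(1))))
  expect_lt(ipf_fit(tab, st$model)$G2,
            qchisq(0.99, prod(dim(tab)) - 1))
})

test_that("mutual independence tables are pared back to main effects", {
  # reaching mains-only needs ~4 sequential null removals to all pass at
  # alpha = 0.05, so the attainable rate is ~0.95^4 ~ 0.81; assert 0.75
  set.seed(8)
  hits <- 0; n_rep <- 100
  for (r in seq_len(n_rep)) {
    p1 <- c(.3, .3, .4); p2 <- c(.5, .5); p3 <- c(.6, .4)
    probs <- outer(outer(p1, p2), p3)
    counts <- array(rmultinom(1, 400, probs), dim = c(3, 2, 2))
    st <- backward_stepwise(counts)
    if (all(lengths(st$model) == 1)) hits <- hits + 1
  }
  expect_gte(hits / n_rep, 0.75)
})

test_that("mortality_table cross-tabulates one cause against the rest", {
  tt <- simulate_transplant(sim_config(seed = 3))
  tab <- mortality_table(tt, "burial")
  expect_equal(length(dim(tab)), 3L)
  expect_equal(sum(tab), nrow(tt))
  expect_equal(sum(tab[, , "burial"]), sum(tt$death_cause == "burial"))
  expect_equal(unname(tab["desert", , "burial"]),
               rep(0L, 3L))  # no desert burial in the stated world
})
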