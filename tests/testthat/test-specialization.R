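test_that("identical diets give pure generalists and disjoint diets pure specialists", {
  gen <- decompose_niche(rbind(c(2L, 2L), c(2L, 2L)))
  expect_equal(gen$tnw, log(2), tolerance = 1e-12)
  expect_equal(gen$wic, log(2), tolerance = 1e-12)
  expect_equal(gen$bic, 0, tolerance = 1e-12)
  expect_equal(gen$e_obs, 0)

  spec <- decompose_niche(rbind(c(4L, 0L), c(0L, 4L)))
  expect_equal(spec$tnw, log(2), tolerance = 1e-12)
  expect_equal(spec$wic, 0)
  expect_equal(spec$e_obs, 1)
})

test_that("bic reproduces the pinned mutual-information value of the 3x3 example", {
  d <- decompose_niche(rbind(c(2L, 1L, 0L), c(0L, 2L, 1L), c(1L, 0L, 2L)))
  # uniform margins: MI = (2/3) ln 2 by direct cell enumeration
  expect_equal(d$bic, 2 / 3 * log(2), tolerance = 1e-12)
  expect_equal(d$tnw, log(3), tolerance = 1e-12)
  expect_equal(d$wic, log(3) - 2 / 3 * log(2), tolerance = 1e-12)
})

test_that("tnw = wic + bic and bic equals brute-force mutual information on random matrices", {
  set.seed(2209)
  for (i in 1:200) {
    m <- random_count_matrix()
    d <- decompose_niche(m)
    expect_lt(abs(d$tnw - (d$wic + d$bic)), 1e-10)
    expect_lt(abs(d$bic - oracle_mutual_information(m)), 1e-10)
    expect_gte(d$bic, 0)
    expect_gte(d$wic, 0)
    expect_equal(sum(d$pooled), 1, tolerance = 1e-12)
    expect_equal(unname(rowSums(d$individual_props)), rep(1, nrow(m)),
                 tolerance = 1e-12)
    if (d$tnw > 0) expect_true(d$e_obs >= 0 && d$e_obs <= 1)
  }
})

test_that("merging individuals with identical diet proportions never increases bic", {
  set.seed(909)
  for (i in 1:30) {
    m <- random_count_matrix(nr = 3)
    split <- rbind(m, m[3, ])           # duplicate the third row...
    merged <- m
    merged[3, ] <- m[3, ] * 2L          # ...vs pooling it into one individual
    expect_lte(decompose_niche(merged)$bic,
               decompose_niche(split)$bic + 1e-12)
  }
})

test_that("degenerate inputs to the decomposition are rejected", {
  expect_error(decompose_niche(matrix(c(1L, 2L), 1)), "2 individuals")
  expect_error(decompose_niche(rbind(c(0L, 0L), c(1L, 1L))), "at least one")
  expect_error(decompose_niche(rbind(c(-1L, 2L), c(1L, 1L))), "non-negative")
})

test_that("the Monte Carlo ensemble is seed-deterministic and sized as requested", {
  m <- dm(rbind(c(5L, 1L, 0L), c(1L, 4L, 2L), c(0L, 2L, 5L)))
  a <- monte_carlo_null(m, replicates = 199, seed = 42)
  b <- monte_carlo_null(m, replicates = 199, seed = 42)
  expect_identical(a$values, b$values)
  expect_length(a$values, 199)
  expect_equal(a$e_null, mean(a$values))
  c2 <- monte_carlo_null(m, replicates = 199, seed = 43)
  expect_false(identical(a$values, c2$values))
  expect_error(monte_carlo_null(m, replicates = 0), "replicates")
})

test_that("a pure-generalist population yields p = 1 under the add-one convention", {
  m <- rbind(c(3L, 3L), c(3L, 3L), c(3L, 3L))
  null <- monte_carlo_null(m, replicates = 99, seed = 7)
  expect_equal(null$e_obs, 0)
  expect_equal(null$p_value, 1)   # every null value >= 0
  expect_true(all(null$values >= 0 & null$values <= 1))
})

test_that("adjusted_E follows the stated arithmetic and error contract", {
  expect_equal(adjusted_E(0.55, 0.2, 10), 0.5)
  expect_equal(adjusted_E(0.3, 0.3, 5), 0)
  expect_equal(adjusted_E(1 - 1 / 7, 0.25, 7), 1)
  expect_error(adjusted_E(0.5, 0.5, 2), "undefined")
  expect_error(adjusted_E(0.5, 0.2, 1), "p_categories")
})

test_that("the composed test flags out-of-range E_adj instead of clamping", {
  # pure specialists on two categories: e_obs = 1 > e_max = 0.5
  st <- specialization_test(rbind(c(4L, 0L), c(0L, 4L)),
                            replicates = 199, seed = 11)
  expect_equal(st$decomposition$e_obs, 1)
  expect_equal(st$e_max, 0.5)
  expect_gt(st$e_adj, 1)
  expect_false(st$e_adj_in_range)
  # e_adj is exactly reconstructible from its parts
  expect_equal(st$e_adj,
               (st$decomposition$e_obs - st$null$e_null) /
                 (st$e_max - st$null$e_null))

  gen <- specialization_test(rbind(c(3L, 3L), c(3L, 3L)),
                             replicates = 199, seed = 12)
  expect_lte(gen$e_adj, 0)
  expect_equal(gen$null$p_value, 1)
})

test_that("the JSON serialization carries every reported field", {
  st <- specialization_test(rbind(c(5L, 1L), c(1L, 5L)),
                            replicates = 99, seed = 3)
  js <- specialization_json(st)
  expect_named(js, c("tnw", "wic", "bic", "e_obs", "e_null", "e_max",
                     "e_adj", "p_value", "replicates", "seed",
                     "p_categories", "n_individuals", "degenerate_count",
                     "e_adj_in_range"))
  expect_equal(js$replicates, 99)
  expect_equal(js$seed, 3L)
  expect_equal(js$n_individuals, 2)
})
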