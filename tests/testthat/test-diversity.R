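test_that("pooling sums species counts and recomputes rarity classes", {
  a <- c(sp1 = 1, sp2 = 0)
  b <- c(sp1 = 1, sp2 = 2)
  pooled <- pool_samples(list(a, b))
  expect_equal(unname(pooled), c(2, 2))
  s <- abundance_summary(pooled)
  expect_identical(c(s$f1, s$f2), c(0L, 2L))

  z <- c(sp1 = 0, sp2 = 0, sp3 = 0)
  v <- c(sp1 = 3, sp2 = 1, sp3 = 2)
  expect_equal(pool_samples(list(v, z)), pool_samples(list(z, v)))
  expect_equal(unname(pool_samples(list(v, z))), unname(v))

  # named pooling unions the species universes
  p <- pool_samples(list(c(ant = 2), c(bee = 1, ant = 1)))
  expect_equal(p, c(ant = 3, bee = 1))
  expect_error(pool_samples(list()), "non-empty")
})

test_that("sample coverage follows the singleton/doubleton formula", {
  expect_equal(sample_coverage(c(4, 3, 2, 1)), 1 - 0.1 * (9 / 11), tolerance = 1e-12)
  expect_equal(sample_coverage(c(2, 2, 2)), 1)
  expect_equal(sample_coverage(c(10, 5, 3)), 1)        # f1 = 0
  expect_equal(sample_coverage(c(1, 1, 1)), 0)         # all singletons
})

test_that("appending an individual of an abundant species raises coverage", {
  # adding to a species of count >= 3 changes neither f1 nor f2, and
  # C = 1 - f1^2 / (n f1 + 2 f2) (up to the (n-1)/n factor) rises with n;
  # adding to a doubleton can lower the estimate slightly because it
  # removes an f2 count, so the guarantee starts at count >= 3
  set.seed(19)
  for (i in 1:40) {
    x <- random_counts(12)
    idx <- which(x >= 3)
    if (!length(idx)) next
    x2 <- x
    x2[idx[1]] <- x2[idx[1]] + 1
    expect_gte(sample_coverage(x2), sample_coverage(x) - 1e-12)
  }
})

test_that("asymptotic Shannon matches its closed form and edge conventions", {
  est <- asymptotic_shannon(c(2, 2, 2))
  # all X_i = 2, n = 6: 3 * (2/6) * (1/2 + 1/3 + 1/4 + 1/5) = 77/60
  expect_equal(est$h_asym, 77 / 60, tolerance = 1e-12)
  expect_equal(est$d_asym, exp(77 / 60), tolerance = 1e-12)
  expect_equal(est$coverage, 1)

  single <- asymptotic_shannon(c(0, 17, 0))
  expect_equal(single$h_asym, 0)
  expect_equal(single$d_asym, 1)

  # f2 = 0, f1 > 1 falls back to the alternative mixing weight
  est2 <- asymptotic_shannon(c(5, 1, 1))
  expect_equal(est2$a_weight, 2 / ((7 - 1) * (2 - 1) + 2))
  expect_true(is.finite(est2$h_asym))
  expect_error(asymptotic_shannon(c(0, 0)), "no positive")
})

test_that("the estimator corrects the plug-in's downward bias", {
  set.seed(23)
  for (i in 1:40) {
    x <- random_counts(15, lambda = 1.5)
    est <- asymptotic_shannon(x)
    if (est$f1 > 0) expect_gte(est$h_asym, est$h_obs - 1e-12)
  }
})

test_that("estimates converge to the true entropy as sampling deepens", {
  p <- abundance_profile(50, 2.5)
  expect_equal(shannon_entropy(p), 2.5, tolerance = 1e-6)

  set.seed(29)
  x <- as.integer(rmultinom(1, 10000, p))
  expect_lt(abs(shannon_entropy(x) - 2.5), 0.05)
  expect_lt(abs(asymptotic_shannon(x)$h_asym - 2.5), 0.02)

  # mean absolute error at n = 100000 is at most half that at n = 1000
  err <- function(n, reps = 15) {
    mean(replicate(reps, abs(asymptotic_shannon(as.integer(
      rmultinom(1, n, p)))$h_asym - 2.5)))
  }
  set.seed(31)
  expect_lte(err(100000), err(1000) / 2)
})

test_that("standardized diversity exposes both scales consistently", {
  x <- c(10, 10, 10)
  h <- standardized_diversity(x, scale = "entropy")
  d <- standardized_diversity(x, scale = "hill")
  expect_equal(d, exp(h), tolerance = 1e-12)
  # oracle: exp of the observed-part sum, sum_{k=10}^{29} 1/k for three
  # species of 10 in 30 (f1 = f2 = 0, no correction term)
  expect_equal(d, exp(sum(1 / (10:29))), tolerance = 1e-12)
  expect_lt(abs(d - 3), 0.15)    # complete uniform census of 3 species
  expect_error(standardized_diversity(c(0, 0)), "no positive")
})

test_that("per-plot tables standardize every plot of a community matrix", {
  comm <- tibble::tibble(plot_id = c("a", "b"),
                         sp1 = c(4, 2), sp2 = c(3, 2), sp3 = c(2, 2), sp4 = c(1, 0))
  out <- diversity_by_plot(comm)
  expect_identical(nrow(out), 2L)
  expect_equal(out$coverage[1], sample_coverage(c(4, 3, 2, 1)))
  expect_equal(out$h_asym[2], 77 / 60, tolerance = 1e-12)
  expect_equal(out$diversity, out$d_asym)
  out_h <- diversity_by_plot(comm, scale = "entropy")
  expect_equal(out_h$diversity, out_h$h_asym)
})
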