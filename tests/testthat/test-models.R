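test_that("a linear signal is fitted as an effectively linear smooth", {
  # a literally noise-free response makes GCV degenerate (every smoothness
  # interpolates); a vanishing noise floor realises the intended contract
  set.seed(43)
  d <- data.frame(x = runif(80, 0, 10))
  d$y <- 2 * d$x + 1 + rnorm(80, sd = 1e-3)
  fit <- fit_gam(d, "y", "x")
  expect_gte(fit$explained_deviance, 0.999)
  expect_lt(fit$edf[["x"]], 1.05)
})

test_that("curvature is recovered with extra effective degrees of freedom", {
  set.seed(47)
  d <- data.frame(x = runif(150, -2, 2))
  d$y <- (d$x - mean(d$x))^2 + rnorm(150, sd = 0.1)
  fit <- fit_gam(d, "y", "x")
  expect_gt(fit$edf[["x"]], 1.5)
  expect_gt(fit$explained_deviance, 0.9)
  expect_lte(fit$edf[["x"]], 3.2)    # basis caps flexibility at edf ~ 3
})

test_that("an infinite penalty reduces the GAM to ordinary least squares", {
  set.seed(53)
  d <- data.frame(x = runif(60))
  d$y <- 1.5 * d$x + rnorm(60, sd = 0.3)
  fit <- fit_gam(d, "y", "x", sp = 1e8)
  expect_equal(fit$explained_deviance, summary(lm(y ~ x, d))$r.squared,
               tolerance = 1e-6)
  expect_equal(unname(fit$edf), 1, tolerance = 1e-4)
})

test_that("explained deviance equals 1 - RSS/TSS worked by hand", {
  d <- data.frame(x = 1:5, y = c(2, 4, 5, 4, 6))
  # by hand: slope = 0.8, intercept = 1.8, RSS = 2.4, TSS = 8.8
  fit <- fit_gam(d, "y", "x", sp = 1e8)
  expect_equal(fit$explained_deviance, 1 - 2.4 / 8.8, tolerance = 1e-6)
  expect_equal(explained_deviance(fit), fit$explained_deviance)
})

test_that("fit_gam rejects undersized or malformed inputs", {
  d <- data.frame(y = rnorm(5), a = rnorm(5), b = rnorm(5))
  expect_error(fit_gam(d, "y", c("a", "b")), "too small")
  expect_error(fit_gam(d, "z", "a"), "not in data")
  d2 <- data.frame(y = c(1, NA, 3, 4, 5, 6), x = 1:6)
  expect_error(fit_gam(d2, "y", "x"), "finite")
})

test_that("tidy and glance expose the standard model summaries", {
  set.seed(59)
  d <- data.frame(a = rnorm(100), b = rnorm(100))
  d$y <- d$a + 0.5 * d$b + rnorm(100, sd = 0.4)
  fit <- fit_gam(d, "y", c("a", "b"))
  td <- tidy(fit)
  expect_identical(td$term, c("a", "b"))
  expect_true(all(td$edf >= 1 - 1e-6 & td$edf <= 3 + 0.2))
  gl <- glance(fit)
  expect_identical(gl$nobs, 100L)
  expect_equal(gl$deviance_explained, fit$explained_deviance)
  expect_true(is.finite(gl$aic) && is.finite(gl$gcv))
})

test_that("collinearity screen flags exactly the pairs past the threshold", {
  cp59 <- correlated_pair(200, 0.59, seed = 61)
  cp61 <- correlated_pair(200, 0.61, seed = 67)
  d <- data.frame(u = cp59$u, v59 = cp59$v, w = cp61$u, v61 = cp61$v)
  hits <- collinearity_screen(d, vars = c("u", "v59"))
  expect_identical(nrow(hits), 0L)
  hits2 <- collinearity_screen(d, vars = c("w", "v61"))
  expect_identical(nrow(hits2), 1L)
  expect_equal(hits2$r, 0.61, tolerance = 1e-9)

  dup <- data.frame(a = rnorm(50))
  dup$b <- dup$a
  expect_equal(collinearity_screen(dup)$r, 1, tolerance = 1e-12)

  dz <- data.frame(a = rnorm(50), z = rep(1, 50), b = rnorm(50))
  expect_warning(out <- collinearity_screen(dz), "zero-variance")
  expect_false("z" %in% c(out$var1, out$var2))
})

test_that("AIC selection finds the generating variant almost always", {
  set.seed(71)
  hits <- replicate(200, {
    x <- rnorm(100)
    d <- data.frame(y = x + rnorm(100, sd = 0.5), driver = x, noise = rnorm(100))
    select_by_aic(d, "y", c("driver", "noise")) == "driver"
  })
  expect_gte(mean(hits), 0.95)

  expect_identical(select_by_aic(data.frame(y = 1), "y", "only"), "only")
  d <- data.frame(y = rnorm(50), b = rnorm(50))
  d$a2 <- d$b
  expect_identical(as.character(select_by_aic(d, "y", c("b", "a2"))), "a2")
})

test_that("variance partition conserves the full deviance and handles redundancy", {
  set.seed(73)
  for (i in 1:4) {
    n <- 150
    d <- data.frame(c1 = rnorm(n), h1 = rnorm(n), s1 = rnorm(n))
    d$y <- d$c1 + 0.6 * d$h1 + 0.3 * d$s1 + rnorm(n, sd = 0.5 + 0.2 * i)
    vp <- variance_partition(d, "y", "c1", "h1", "s1")
    expect_equal(sum(vp$components), vp$full_deviance, tolerance = 1e-10)
    expect_length(vp$subset_deviance, 7L)
    # nesting monotonicity under frozen smoothing
    D <- vp$subset_deviance
    expect_lte(D[["A"]], D[["AB"]] + 1e-8)
    expect_lte(D[["A"]], D[["AC"]] + 1e-8)
    expect_lte(D[["AB"]], D[["ABC"]] + 1e-8)
    expect_lte(D[["BC"]], D[["ABC"]] + 1e-8)
  }
})

test_that("a duplicated predictor has (near) zero pure fractions", {
  set.seed(79)
  n <- 200
  d <- data.frame(a = rnorm(n), s1 = rnorm(n))
  d$b <- d$a
  d$y <- d$a + 0.5 * d$s1 + rnorm(n, sd = 0.3)
  vp <- variance_partition(d, "y", climate = "a", habitat = "b", soil = "s1")
  expect_lt(abs(vp$components[["pure_climate"]]), 1e-3)
  expect_lt(abs(vp$components[["pure_habitat"]]), 1e-3)
})

test_that("orthogonal additive predictors share almost nothing", {
  set.seed(83)
  n <- 1000
  q <- qr.Q(qr(matrix(rnorm(n * 3), n, 3))) * sqrt(n)   # exactly orthogonal
  d <- data.frame(c1 = q[, 1], h1 = q[, 2], s1 = q[, 3])
  d$y <- d$c1 + d$h1 + d$s1 + rnorm(n, sd = 0.5)
  vp <- variance_partition(d, "y", "c1", "h1", "s1")
  shared <- vp$components[c("shared_climate_habitat", "shared_habitat_soil",
                            "shared_climate_soil", "shared_all")]
  expect_true(all(abs(shared) < 0.02))
})

test_that("partition components agree with nested linear-model R2 algebra", {
  set.seed(89)
  n <- 1500
  z <- rnorm(n)
  d <- data.frame(c1 = z + rnorm(n), h1 = 0.5 * z + rnorm(n), s1 = rnorm(n))
  d$y <- d$c1 + 0.8 * d$h1 + 0.5 * d$s1 + rnorm(n)
  vp <- variance_partition(d, "y", "c1", "h1", "s1")
  r2 <- function(fml) summary(lm(fml, d))$r.squared
  L <- c(A = r2(y ~ c1), B = r2(y ~ h1), C = r2(y ~ s1),
         AB = r2(y ~ c1 + h1), AC = r2(y ~ c1 + s1), BC = r2(y ~ h1 + s1),
         ABC = r2(y ~ c1 + h1 + s1))
  lin <- c(pure_climate = L[["ABC"]] - L[["BC"]],
           pure_habitat = L[["ABC"]] - L[["AC"]],
           pure_soil = L[["ABC"]] - L[["AB"]],
           shared_climate_habitat = L[["AC"]] + L[["BC"]] - L[["C"]] - L[["ABC"]],
           shared_habitat_soil = L[["AB"]] + L[["AC"]] - L[["A"]] - L[["ABC"]],
           shared_climate_soil = L[["AB"]] + L[["BC"]] - L[["B"]] - L[["ABC"]])
  expect_true(all(abs(vp$components[names(lin)] - lin) < 0.01))
})

test_that("stepwise selection recovers a strong true predictor", {
  set.seed(97)
  hits <- replicate(200, {
    n <- 100
    d <- data.frame(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n),
                    x4 = rnorm(n), x5 = rnorm(n))
    d$y <- 2 * d$x3 + rnorm(n, sd = 0.5)
    "x3" %in% stepwise_linear(d, "y", paste0("x", 1:5))$terms
  })
  expect_gte(mean(hits), 0.95)
})

test_that("stepwise selection stays near-empty on pure noise", {
  set.seed(101)
  res <- replicate(50, {
    n <- 100
    d <- data.frame(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n), x4 = rnorm(n))
    d$y <- rnorm(n)
    f <- stepwise_linear(d, "y", paste0("x", 1:4))
    c(length(f$terms), f$adj_r2)
  })
  expect_lte(median(res[1, ]), 1)
  expect_lt(mean(res[2, ]), 0.05)
})

test_that("stepwise handles an exactly linear response and bad designs", {
  set.seed(103)
  d <- data.frame(x1 = 1:30, x2 = rnorm(30))
  d$y <- 3 * d$x1 + rnorm(30, sd = 1e-3)
  f <- stepwise_linear(d, "y", c("x1", "x2"))
  expect_identical(f$terms, "x1")
  expect_gt(f$adj_r2, 0.999)
  expect_error(stepwise_linear(d[1:3, ], "y", c("x1", "x2")), "need n")
  gl <- glance(f)
  expect_identical(gl$terms, "x1")
})

test_that("soil-model retention keeps only fits above the variance floor", {
  fits <- tibble::tibble(model = c("m1", "m2"), adj_r2 = c(0.44, 0.46))
  kept <- filter_soil_models(fits)
  expect_identical(kept$model, "m2")
  expect_identical(nrow(filter_soil_models(fits[0, ])), 0L)
  expect_identical(nrow(filter_soil_models(tibble::tibble(adj_r2 = c(0.5, 0.9)))), 2L)

  lst <- list(structure(list(adj_r2 = 0.3), class = "stepwise_fit"),
              structure(list(adj_r2 = 0.7), class = "stepwise_fit"))
  expect_length(filter_soil_models(lst), 1L)
})
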