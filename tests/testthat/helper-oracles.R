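# Independent oracles used across the suite. Everything here is brute force
# or closed form and never calls the code paths it checks.

# weighted within-class sum of squared deviations of one segment
oracle_wssd <- function(x, w) sum(w * x^2) - sum(w * x)^2 / sum(w)

# exhaustive enumeration of every contiguous partition of the distinct sorted
# values into exactly min(k, #distinct) classes; returns the minimal SSD
oracle_fisher_ssd <- function(values, k) {
  x <- sort(unique(values))
  w <- as.numeric(table(factor(values, levels = x)))
  n <- length(x)
  k <- min(k, n)
  rec <- function(start, left) {
    if (left == 1L) return(oracle_wssd(x[start:n], w[start:n]))
    ends <- start:(n - left + 1L)
    min(vapply(ends, function(e) {
      oracle_wssd(x[start:e], w[start:e]) + rec(e + 1L, left - 1L)
    }, 0))
  }
  rec(1L, k)
}

# small random count vectors with guaranteed positive totals
random_counts <- function(n_species, lambda = 2) {
  repeat {
    x <- stats::rpois(n_species, lambda)
    if (sum(x) > 1 && sum(x > 0) > 1) return(x)
  }
}

# a simple co-registered test grid
test_grid <- function(values, cell_size = 10) {
  raster_grid(values, origin = c(0, nrow(as.matrix(values)) * cell_size),
              cell_size = cell_size)
}

# two vectors with an exact sample Pearson correlation r
correlated_pair <- function(n, r, seed = 1) {
  set.seed(seed)
  u <- rnorm(n)
  v0 <- rnorm(n)
  v0 <- residuals(lm(v0 ~ u))
  u <- as.numeric(scale(u)); v0 <- as.numeric(scale(v0))
  list(u = u, v = r * u + sqrt(1 - r^2) * v0)
}
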