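#' Summaries of a species abundance vector
#'
#' Validates a vector of per-species counts and reports the quantities the
#' coverage framework needs: total individuals `n`, singletons `f1`
#' (species seen exactly once) and doubletons `f2` (seen exactly twice).
#'
#' @param counts non-negative integer counts, optionally named by species.
#' @return list with `counts` (zero-count species dropped), `n`, `f1`, `f2`.
#' @export
abundance_summary <- function(counts) {
  counts <- check_counts(counts)
  pos <- counts[counts > 0]
  list(counts = pos, n = sum(pos), f1 = sum(pos == 1), f2 = sum(pos == 2))
}

check_counts <- function(counts) {
  counts <- as.numeric(unlist(counts, use.names = TRUE))
  if (length(counts) == 0L) abort("abundance vector is empty.")
  if (anyNA(counts) || any(counts < 0) || any(counts != round(counts))) {
    abort("abundances must be non-negative integers.")
  }
  if (sum(counts) == 0) abort("abundance vector has no positive count.")
  counts
}

#' Pool abundance samples
#'
#' Per-species sums across repeated samples of the same community (e.g.
#' several point-count sessions or field campaigns for one plot); `n`, `f1`
#' and `f2` are recomputed on the pooled counts. Named vectors are matched by
#' species name; unnamed vectors must share length and order.
#'
#' @param samples list of abundance count vectors.
#' @return A single named (when inputs are named) count vector.
#' @export
pool_samples <- function(samples) {
  if (!is.list(samples) || length(samples) == 0L) {
    abort("`samples` must be a non-empty list of count vectors.")
  }
  named <- !is.null(names(samples[[1]]))
  if (named) {
    all_sp <- sort(unique(unlist(lapply(samples, names))))
    out <- setNames(numeric(length(all_sp)), all_sp)
    for (s in samples) {
      if (is.null(names(s))) abort("mixing named and unnamed samples.")
      out[names(s)] <- out[names(s)] + s
    }
  } else {
    len <- unique(lengths(samples))
    if (length(len) != 1L) abort("unnamed samples must share one species order.")
    out <- Reduce(`+`, lapply(samples, as.numeric))
  }
  check_counts(out)
  out
}

#' Estimated sample coverage
#'
#' The fraction of the community's total abundance accounted for by species
#' present in the sample, estimated from singleton and doubleton counts:
#' `C = 1 - (f1/n) * ((n-1) f1 / ((n-1) f1 + 2 f2))`. A sample with no
#' singletons is estimated as complete (`C = 1`).
#'
#' @param counts species abundance counts.
#' @return Coverage estimate in `[0, 1]`.
#' @examples
#' sample_coverage(c(4, 3, 2, 1))  # 1 - 0.1 * 9/11
#' @export
sample_coverage <- function(counts) {
  a <- abundance_summary(counts)
  if (a$n < 1) abort("need at least one individual.")
  if (a$f1 == 0) return(1)
  1 - (a$f1 / a$n) * ((a$n - 1) * a$f1 / ((a$n - 1) * a$f1 + 2 * a$f2))
}

#' Asymptotic (coverage-complete) Shannon diversity
#'
#' Estimates the Shannon entropy the sample would show at complete coverage -
#' the asymptote of the coverage-based rarefaction/extrapolation curve - from
#' a single abundance vector:
#' \deqn{\hat H = \sum_{X_i \le n-1} \frac{X_i}{n} \sum_{k=X_i}^{n-1}\frac1k
#'   + \frac{f_1}{n}(1-A)^{1-n}\Big(-\log A - \sum_{r=1}^{n-1}
#'   \frac{(1-A)^r}{r}\Big)}
#' with mixing weight `A = 2 f2 / ((n-1) f1 + 2 f2)` when doubletons exist,
#' `A = 2 / ((n-1)(f1-1) + 2)` when `f2 = 0` and `f1 > 1`, and `A = 1` (no
#' correction) when `f2 = 0` and `f1 <= 1`. The correction term removes the
#' downward bias of the plug-in entropy for unseen species.
#'
#' @param counts species abundance counts (total `n >= 2` unless a single
#'   species is present, which gives entropy 0).
#' @return A one-row tibble: `n`, `s_obs`, `f1`, `f2`, `h_obs` (plug-in
#'   entropy), `coverage`, `h_asym` (asymptotic entropy, nats), `d_asym`
#'   (`exp(h_asym)`, effective species) and `a_weight`.
#' @examples
#' asymptotic_shannon(c(2, 2, 2))  # h_asym = 1.28333...
#' @export
asymptotic_shannon <- function(counts) {
  a <- abundance_summary(counts)
  x <- a$counts; n <- a$n
  if (length(x) == 1L) {
    return(diversity_row(a, h_obs = 0, h_asym = 0, A = 1))
  }
  if (n < 2) abort("need n >= 2 individuals for the asymptotic estimator.")
  h_obs <- shannon_entropy(x)
  # observed part: sum over species with X_i <= n-1 of (X_i/n) * sum_{k=X_i}^{n-1} 1/k
  recip_cum <- rev(cumsum(rev(1 / seq_len(n - 1))))   # recip_cum[j] = sum_{k=j}^{n-1} 1/k
  xs <- x[x <= n - 1]
  h_part <- sum(xs / n * recip_cum[xs])
  # unseen-species correction
  if (a$f2 > 0) {
    A <- 2 * a$f2 / ((n - 1) * a$f1 + 2 * a$f2)
  } else if (a$f1 > 1) {
    A <- 2 / ((n - 1) * (a$f1 - 1) + 2)
  } else {
    A <- 1
  }
  corr <- if (a$f1 == 0 || A >= 1) 0 else shannon_correction(a$f1, n, A)
  diversity_row(a, h_obs = h_obs, h_asym = h_part + corr, A = A)
}

# (f1/n) (1-A)^{1-n} [ -log A - sum_{r=1}^{n-1} (1-A)^r / r ]
# The bracket is the tail sum_{r>=n} (1-A)^r / r, so the product equals
# (f1/n) sum_{m>=1} (1-A)^m / (n+m-1): evaluated directly when the leading
# power would overflow.
shannon_correction <- function(f1, n, A) {
  lead <- (1 - n) * log1p(-A)
  if (lead < 700) {
    r <- seq_len(n - 1)
    (f1 / n) * exp(lead) * (-log(A) - sum((1 - A)^r / r))
  } else {
    total <- 0
    q <- 1 - A
    m <- 1
    pw <- q
    repeat {
      term <- pw / (n + m - 1)
      total <- total + term
      if (term < 1e-17 * max(total, 1e-300) || m > 1e7) break
      m <- m + 1
      pw <- pw * q
    }
    (f1 / n) * total
  }
}

diversity_row <- function(a, h_obs, h_asym, A) {
  tibble::tibble(
    n = a$n, s_obs = length(a$counts), f1 = a$f1, f2 = a$f2,
    h_obs = h_obs,
    coverage = if (a$f1 == 0) 1 else
      1 - (a$f1 / a$n) * ((a$n - 1) * a$f1 / ((a$n - 1) * a$f1 + 2 * a$f2)),
    h_asym = h_asym, d_asym = exp(h_asym), a_weight = A
  )
}

#' Standardized Shannon diversity at complete coverage
#'
#' The single number used as a plot's standardized taxon diversity: the
#' asymptotic Shannon estimate, on the effective-species (Hill number,
#' `exp(H)`) scale by default or as raw entropy in nats.
#'
#' @param counts species abundance counts.
#' @param scale `"hill"` (default, effective species) or `"entropy"` (nats).
#' @return A single number.
#' @export
standardized_diversity <- function(counts, scale = c("hill", "entropy")) {
  scale <- match.arg(scale)
  est <- asymptotic_shannon(counts)
  if (scale == "hill") est$d_asym else est$h_asym
}

#' Per-plot standardized diversity from a plot-by-species table
#'
#' @param community data frame with a `plot_id` column and one count column
#'   per species (a wide plot x species table).
#' @param scale passed to [standardized_diversity()]; both scales plus the
#'   full estimator summary are returned regardless.
#' @return A tibble with one row per plot: `plot_id`, the
#'   [asymptotic_shannon()] columns, and `diversity` on the requested scale.
#' @export
diversity_by_plot <- function(community, scale = c("hill", "entropy")) {
  scale <- match.arg(scale)
  community <- tibble::as_tibble(community)
  if (!"plot_id" %in% names(community)) abort("`community` needs a `plot_id` column.")
  sp_cols <- setdiff(names(community), "plot_id")
  if (length(sp_cols) == 0L) abort("no species columns found.")
  est <- purrr::map(seq_len(nrow(community)), function(i) {
    asymptotic_shannon(as.numeric(community[i, sp_cols]))
  })
  out <- dplyr::bind_cols(tibble::tibble(plot_id = community$plot_id),
                          dplyr::bind_rows(est))
  out$diversity <- if (scale == "hill") out$d_asym else out$h_asym
  out
}
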