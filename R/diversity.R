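# Hill diversity and coverage-based rarefaction/extrapolation for
# detection-count ("abundance"-type) data, with a multinomial bootstrap on
# the estimated complete assemblage for confidence intervals.
#
# Parameterization: diversity is the generalized mean species rarity
# D = (sum_i p_i r_i^iota)^(1/iota) with rarity r_i = 1/p_i. The exponent
# iota relates to the conventional Hill order as q = 1 - iota, so iota = 1
# is richness, iota = 0 (the geometric-mean limit) is the exponential of
# Shannon entropy, and iota = -1 is inverse Simpson concentration.

#' Frequency-count summary of per-taxon detection counts
#'
#' Treats each detection as one sampled individual: `n` is the total number
#' of detections, `S_obs` the number of taxa detected, and `f[k]` the
#' number of taxa detected exactly `k` times (`f1` singletons, `f2`
#' doubletons drive all unseen-species corrections).
#'
#' @param x non-negative integer vector of per-taxon detection counts;
#'   zeros are dropped.
#' @return object of class `abundance_freqs` with fields `x`, `n`, `S_obs`,
#'   `f1`, `f2` and the full frequency-count table `f`.
#' @export
abundance_freqs <- function(x) {
  .stop_if(any(x < 0) || any(x != round(x)),
           "detection counts must be non-negative integers")
  x <- as.numeric(x[x > 0])
  .stop_if(length(x) == 0, "no taxa with positive counts")
  f <- table(x)
  fk <- function(k) {
    hit <- f[as.character(k)]
    if (is.na(hit)) 0 else as.numeric(hit)
  }
  structure(list(x = x, n = sum(x), S_obs = length(x),
                 f1 = fk(1), f2 = fk(2), f = f),
            class = "abundance_freqs")
}

#' @export
print.abundance_freqs <- function(x, ...) {
  cat(sprintf("<abundance_freqs> n = %d detections, S_obs = %d taxa, f1 = %d, f2 = %d\n",
              x$n, x$S_obs, x$f1, x$f2))
  invisible(x)
}

#' Hill diversity of a probability vector
#'
#' Computes the generalized mean rarity `(sum p_i (1/p_i)^iota)^(1/iota)`;
#' `iota = 0` is handled as its limit, the exponential of Shannon entropy.
#'
#' @param p probability vector, strictly positive, summing to 1 (tolerance
#'   1e-9).
#' @param iota rarity-scale exponent; 1 = richness, 0 = Hill-Shannon,
#'   -1 = Hill-Simpson. Any real value is accepted.
#' @return diversity in effective-species units.
#' @export
hill_diversity <- function(p, iota) {
  .stop_if(any(p <= 0), "probabilities must be strictly positive ",
           "(restrict to observed taxa first)")
  .stop_if(abs(sum(p) - 1) > 1e-9, "probabilities must sum to 1")
  if (iota == 0) exp(-sum(p * log(p))) else sum(p * (1 / p)^iota)^(1 / iota)
}

# geometric decay ratio of the singleton share; the (m > n) coverage
# estimator is 1 - (f1/n) * A^(m - n + 1)
.coverage_ratio <- function(freqs) {
  n <- freqs$n; f1 <- freqs$f1; f2 <- freqs$f2
  if (f1 == 0) return(0)
  if (f2 > 0) (n - 1) * f1 / ((n - 1) * f1 + 2 * f2)
  else (n - 1) * (f1 - 1) / ((n - 1) * (f1 - 1) + 2)
}

# bias-corrected Chao1 estimate of the number of undetected taxa
.f0_hat <- function(freqs) {
  n <- freqs$n; f1 <- freqs$f1; f2 <- freqs$f2
  if (f1 == 0) return(0)
  if (f2 > 0) (n - 1) / n * f1^2 / (2 * f2)
  else (n - 1) / n * f1 * (f1 - 1) / 2
}

#' Estimated sample coverage at a given number of detections
#'
#' Coverage is the estimated proportion of individuals in the sampled
#' community that belong to taxa already detected. For `m < n` the exact
#' expected coverage of a subsample is used; at `m = n` and beyond, the
#' singleton/doubleton estimator with its geometric extrapolation term.
#'
#' @param freqs an [abundance_freqs()].
#' @param m number of detections (>= 1) at which to estimate.
#' @return coverage in `[0, 1]`.
#' @export
estimate_coverage <- function(freqs, m) {
  stopifnot(inherits(freqs, "abundance_freqs"), m >= 1, m == round(m))
  n <- freqs$n; x <- freqs$x
  if (m < n) {
    # expected coverage of a size-m subsample without replacement
    w <- exp(lchoose(n - x, m) - lchoose(n - 1, m))
    return(1 - sum(x / n * w))
  }
  1 - (freqs$f1 / n) * .coverage_ratio(freqs)^(m - n + 1)
}

# expected number of taxa detected exactly k times in a size-m subsample
.expected_fk <- function(x, n, m, k) {
  colSums(exp(outer(x, k, lchoose) +
                outer(n - x, m - k, lchoose) - lchoose(n, m)))
}

#' Rarefied or extrapolated Hill diversity
#'
#' Interpolation (`m <= n`) uses the exact expectations under subsampling
#' without replacement; extrapolation (`m > n`) anchors on unseen-species
#' estimates (bias-corrected Chao1 for richness, an asymptotic entropy
#' estimate for Hill-Shannon). Hill-Simpson uses a single nearly unbiased
#' estimator valid at every `m`. Curves are continuous at `m = n`.
#'
#' @param freqs an [abundance_freqs()].
#' @param iota rarity exponent: 1, 0 or -1 (equivalently Hill order
#'   `q = 1 - iota`).
#' @param m number of detections, >= 1 (vectorized).
#' @return data frame with columns `iota`, `m`, `D`, `coverage`, `kind`.
#' @export
rarefy_extrapolate_hill <- function(freqs, iota, m) {
  stopifnot(inherits(freqs, "abundance_freqs"))
  .stop_if(!iota %in% c(1, 0, -1),
           "`iota` must be 1 (richness), 0 (Shannon) or -1 (Simpson)")
  .stop_if(any(m < 1) || any(m != round(m)), "`m` must be positive integers")
  n <- freqs$n; x <- freqs$x; S <- freqs$S_obs
  D <- vapply(m, function(mi) {
    if (iota == -1) {
      # nearly unbiased inverse-Simpson estimator, valid at every m
      denom <- 1 / mi + (1 - 1 / mi) * sum(x * (x - 1)) / (n * (n - 1))
      return(1 / denom)
    }
    if (iota == 1) {
      if (mi <= n) return(S - sum(exp(lchoose(n - x, mi) - lchoose(n, mi))))
      f0 <- .f0_hat(freqs)
      if (f0 == 0) return(S)
      return(S + f0 * (1 - (1 - freqs$f1 / (n * f0 + freqs$f1))^(mi - n)))
    }
    # iota == 0, Hill-Shannon
    if (mi < n) {
      k <- seq_len(mi)
      efk <- .expected_fk(x, n, mi, k)
      return(exp(-sum(k / mi * log(k / mi) * efk)))
    }
    H_n <- -sum(x / n * log(x / n))
    if (mi == n) return(exp(H_n))
    H_asy <- .entropy_asymptotic(freqs)
    exp(n / mi * H_n + (1 - n / mi) * H_asy)
  }, numeric(1))
  data.frame(iota = iota, m = m, D = D,
             coverage = vapply(m, function(mi) estimate_coverage(freqs, mi),
                               numeric(1)),
             kind = ifelse(m < n, "interpolated",
                           ifelse(m == n, "observed", "extrapolated")))
}

# asymptotic Shannon entropy estimate with singleton correction for the
# undetected tail (used to anchor Hill-Shannon extrapolation)
.entropy_asymptotic <- function(freqs) {
  n <- freqs$n; x <- freqs$x; f1 <- freqs$f1; f2 <- freqs$f2
  known <- sum(x / n * (digamma(n) - digamma(x)))
  if (f1 == 0) return(known)
  A <- if (f2 > 0) 2 * f2 / ((n - 1) * f1 + 2 * f2)
       else if (f1 > 1) 2 / ((n - 1) * (f1 - 1) + 2)
       else 1
  if (A == 1) return(known)
  r <- seq_len(n - 1)
  known + f1 / n * (1 - A)^(1 - n) * (-log(A) - sum((1 - A)^r / r))
}

#' Diversity and coverage profile over a grid of sample sizes
#'
#' Tabulates rarefied/extrapolated Hill diversity and coverage on a grid of
#' detection counts from 1 to `endpoint` (the observed size is always on
#' the grid), for each requested rarity exponent — the table behind
#' diversity-vs-detections, coverage-vs-detections and
#' diversity-vs-coverage sampling curves. Optionally adds bootstrap
#' confidence bands (one set of bootstrap assemblages shared across the
#' whole grid).
#'
#' @param freqs an [abundance_freqs()].
#' @param iotas rarity exponents (subset of 1, 0, -1).
#' @param n_grid approximate number of grid points.
#' @param endpoint largest sample size; defaults to twice the observed
#'   number of detections.
#' @param bootstrap number of bootstrap replicates for 95% bands (0 = none).
#' @param seed RNG seed used when `bootstrap > 0`.
#' @return data frame of [rarefy_extrapolate_hill()] rows (plus `ci_low`,
#'   `ci_high` when bootstrapped), stacked over `iotas`.
#' @export
diversity_profile <- function(freqs, iotas = c(1, 0, -1), n_grid = 40,
                              endpoint = NULL, bootstrap = 0, seed = 1) {
  stopifnot(inherits(freqs, "abundance_freqs"))
  n <- freqs$n
  if (is.null(endpoint)) endpoint <- 2 * n
  .stop_if(endpoint < n, "`endpoint` must be at least the observed size")
  m <- sort(unique(c(round(seq(1, endpoint, length.out = n_grid)), n)))
  out <- do.call(rbind, lapply(iotas, function(io)
    rarefy_extrapolate_hill(freqs, io, m)))
  rownames(out) <- NULL
  if (bootstrap > 0) {
    boot <- .bootstrap_freqs(freqs, bootstrap, seed)
    half <- unlist(lapply(iotas, function(io) {
      reps <- vapply(boot, function(fb)
        rarefy_extrapolate_hill(fb, io, m)$D, numeric(length(m)))
      reps <- matrix(reps, nrow = length(m))
      1.96 * apply(reps, 1, stats::sd)
    }))
    out$ci_low <- out$D - half
    out$ci_high <- out$D + half
  }
  out
}

# bootstrap assemblage: observed taxa with coverage-adjusted probabilities
# plus f0_hat equally likely undetected taxa; detections resampled
# multinomially at the observed size
.bootstrap_freqs <- function(freqs, B, seed) {
  set.seed(seed)
  n <- freqs$n; x <- freqs$x
  Chat <- estimate_coverage(freqs, n)
  w <- x / n * (1 - x / n)^n
  lambda <- if (sum(w) > 0) (1 - Chat) / sum(w) else 0
  p_seen <- x / n * (1 - lambda * (1 - x / n)^n)
  f0 <- ceiling(.f0_hat(freqs))
  p <- c(p_seen, if (f0 > 0) rep((1 - Chat) / f0, f0))
  p <- p / sum(p)
  lapply(seq_len(B), function(b) {
    xb <- stats::rmultinom(1, n, p)[, 1]
    abundance_freqs(xb[xb > 0])
  })
}

#' Bootstrap confidence interval for a diversity-type estimator
#'
#' Resamples `n` detections multinomially from the estimated complete
#' assemblage (observed taxa with coverage-adjusted probabilities plus the
#' estimated number of undetected taxa at equal shares) and evaluates
#' `estimator` on each bootstrap assemblage. The default interval is the
#' estimate plus/minus `z` bootstrap standard deviations (always centered
#' on the point estimate); `"percentile"` bounds are available.
#' Deterministic for a fixed seed.
#'
#' @param freqs an [abundance_freqs()].
#' @param estimator function taking an `abundance_freqs` and returning a
#'   numeric scalar or vector.
#' @param B number of bootstrap replicates (>= 50).
#' @param seed RNG seed.
#' @param level confidence level.
#' @param type `"normal"` (default) or `"percentile"`.
#' @return list with `estimate`, `low`, `high` (same shape as the
#'   estimator output) and the replicate matrix `reps`.
#' @export
bootstrap_ci <- function(freqs, estimator, B = 200, seed = 1, level = 0.95,
                         type = c("normal", "percentile")) {
  stopifnot(inherits(freqs, "abundance_freqs"), B >= 50)
  type <- match.arg(type)
  est <- estimator(freqs)
  boot <- .bootstrap_freqs(freqs, B, seed)
  reps <- vapply(boot, estimator, FUN.VALUE = est)
  reps <- matrix(reps, ncol = B)
  a <- (1 - level) / 2
  if (type == "normal") {
    half <- stats::qnorm(1 - a) * apply(reps, 1, stats::sd)
    list(estimate = est, low = est - half, high = est + half, reps = reps)
  } else {
    list(estimate = est,
         low = apply(reps, 1, stats::quantile, probs = a, names = FALSE),
         high = apply(reps, 1, stats::quantile, probs = 1 - a, names = FALSE),
         reps = reps)
  }
}
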