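#' Empirical excess mass statistic for k modes
#'
#' The excess mass statistic D_{n,k} measures how much probability mass,
#' maximised over the cutting level lambda >= 0, can be captured by k+1
#' disjoint intervals but not by k:
#' D_{n,k} = max_lambda ( E_n(lambda, k+1) - E_n(lambda, k) ), where
#' E_n(lambda, j) is the maximum over j disjoint closed intervals I of
#' sum ( P_n(I) - lambda |I| ) and P_n is the empirical measure. A large
#' value indicates the sample needs more than k modes.
#'
#' Interval endpoints can be restricted to data points without loss, and
#' since each E_n(., j) is the upper envelope of finitely many linear
#' functions of lambda, the maximum of their (piecewise linear) difference
#' is attained on the finite set of empirical-CDF difference quotients
#' (j - i)/n / (x_(j) - x_(i)); the statistic is computed exactly by a
#' dynamic program scanned over that set.
#'
#' The statistic is invariant under location shifts and positive rescaling
#' of the data, non-increasing in `k`, and lies in [0, 1].
#'
#' @param sample a [head_capsule_sample()] or numeric vector.
#' @param k null number of modes, k >= 1.
#' @return the excess mass statistic, a number in [0, 1].
#' @export
excess_mass_statistic <- function(sample, k) {
  x <- as_widths_any(sample)
  k <- as.integer(k)
  if (is.na(k) || k < 1L) stop("k must be a positive integer", call. = FALSE)
  if (length(x) < 1L) stop("sample must be non-empty", call. = FALSE)
  .excess_mass_cpp(x, k)
}

# like as_widths() but tolerant of arbitrary numeric samples (the statistic
# is scale-free, so sign restrictions do not apply here)
as_widths_any <- function(sample) {
  x <- if (inherits(sample, "head_capsule_sample")) sample$widths
       else as.numeric(sample)
  if (any(!is.finite(x))) stop("sample must be finite", call. = FALSE)
  x
}

#' Critical bandwidth for a k-modal kernel density
#'
#' Smallest Gaussian-kernel bandwidth at which the kernel density estimate of
#' the sample has at most `k` modes. Mode count is non-increasing in the
#' bandwidth for the Gaussian kernel, so the value is found by bisection.
#'
#' @param x numeric sample.
#' @param k target number of modes.
#' @param grid_size density grid resolution.
#' @param tol relative bisection tolerance.
#' @return the critical bandwidth (same units as `x`).
#' @export
critical_bandwidth <- function(x, k, grid_size = 512L, tol = 1e-3) {
  x <- as_widths_any(x)
  nmodes_at <- function(h) {
    d <- density(x, bw = h, n = as.integer(grid_size),
                 from = min(x) - 3 * h, to = max(x) + 3 * h)
    count_modes(d)
  }
  hi <- diff(range(x))
  if (hi <= 0) stop("degenerate sample: zero range", call. = FALSE)
  while (nmodes_at(hi) > k) hi <- hi * 2
  lo <- hi / 1024
  while (nmodes_at(lo) <= k && lo > hi * 1e-8) lo <- lo / 2
  if (nmodes_at(lo) <= k) return(lo)  # already <= k at tiny bandwidths
  while ((hi - lo) / hi > tol) {
    mid <- (lo + hi) / 2
    if (nmodes_at(mid) <= k) hi <- mid else lo <- mid
  }
  hi
}

#' Excess mass test of the number of modes
#'
#' Tests H0: the density has `k_null` modes against H_a: more than `k_null`
#' modes, using the excess mass statistic with a smoothed-bootstrap
#' calibration. Bootstrap samples are drawn from a calibration density
#' constrained to exactly `k_null` modes: the data smoothed with a Gaussian
#' kernel at the critical bandwidth (the smallest bandwidth at which the KDE
#' is `k_null`-modal), with the classical variance rescaling so the
#' calibration distribution keeps the sample variance. The p-value is the
#' proportion of bootstrap statistics at least as large as the observed one.
#'
#' @param sample a [head_capsule_sample()] or numeric vector, n >= 10.
#' @param k_null null number of modes.
#' @param n_boot bootstrap replicates, >= 100.
#' @param seed integer seed (mandatory: results are deterministic given
#'   `sample`, `k_null`, `n_boot`, `seed`).
#' @return object of class `mode_test` with fields `k_null`, `statistic`,
#'   `p_value`, `n_boot`, `seed`, `bw_crit`, `n`.
#' @export
excess_mass_test <- function(sample, k_null, n_boot = 500L, seed) {
  x <- as_widths_any(sample)
  if (length(x) < 10L) {
    stop("excess mass test needs at least 10 observations", call. = FALSE)
  }
  n_boot <- as.integer(n_boot)
  if (is.na(n_boot) || n_boot < 100L) {
    stop("n_boot must be >= 100 for a reliable calibration", call. = FALSE)
  }
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  k_null <- as.integer(k_null)
  obs <- excess_mass_statistic(x, k_null)
  h <- critical_bandwidth(x, k_null)
  n <- length(x)
  xbar <- mean(x)
  s2 <- var(x)
  shrink <- 1 / sqrt(1 + h^2 / s2)   # keep calibration variance at s2
  stat_boot <- withr_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      xs <- sample(x, n, replace = TRUE)
      y <- xbar + shrink * (xs - xbar + h * rnorm(n))
      .excess_mass_cpp(y, k_null)
    }, numeric(1))
  })
  structure(
    list(k_null = k_null, statistic = obs,
         p_value = mean(stat_boot >= obs),
         n_boot = n_boot, seed = as.integer(seed), bw_crit = h, n = n),
    class = "mode_test"
  )
}

# evaluate `code` under a temporary RNG state seeded with `seed`
withr_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  code
}

#' @export
print.mode_test <- function(x, ...) {
  cat(sprintf(
    "Excess mass test (H0: %d mode%s): statistic %.4f, p = %.3f (n = %d, %d bootstraps, seed %d)\n",
    x$k_null, if (x$k_null > 1) "s" else "", x$statistic, x$p_value,
    x$n, x$n_boot, x$seed))
  invisible(x)
}

#' Select the number of instars by sequential excess-mass testing
#'
#' Tests k = 1, 2, ... in turn and returns the smallest k whose excess mass
#' test is not rejected at level `alpha` -- the parsimonious number of modes
#' consistent with the width distribution. If every k up to `k_max` is
#' rejected, `k_max` is returned with `saturated = TRUE`.
#'
#' Each k gets an independent bootstrap calibration seeded deterministically
#' from `seed`.
#'
#' @inheritParams excess_mass_test
#' @param k_max largest candidate mode count.
#' @param alpha test level.
#' @param details return the per-k table as well?
#' @return integer k, or (with `details = TRUE`) a list `k`, `saturated`,
#'   `table` (data.frame k, statistic, p_value).
#' @export
find_instar_count <- function(sample, k_max = 5L, alpha = 0.05,
                              n_boot = 500L, seed = 1L, details = FALSE) {
  k_max <- as.integer(k_max)
  if (k_max < 1L) stop("k_max must be >= 1", call. = FALSE)
  rows <- vector("list", k_max)
  chosen <- NA_integer_
  for (k in seq_len(k_max)) {
    tst <- excess_mass_test(sample, k, n_boot = n_boot,
                            seed = seed_stream(seed, k))
    rows[[k]] <- data.frame(k = k, statistic = tst$statistic,
                            p_value = tst$p_value)
    if (tst$p_value > alpha) { chosen <- k; break }
  }
  saturated <- is.na(chosen)
  if (saturated) chosen <- k_max
  if (!details) return(chosen)
  list(k = chosen, saturated = saturated,
       table = do.call(rbind, rows[!vapply(rows, is.null, logical(1))]))
}

# deterministic 32-bit substream seeds from a master seed
seed_stream <- function(seed, i) {
  as.integer((as.numeric(seed) * 48271 + i * 16807) %% 2147483647)
}
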