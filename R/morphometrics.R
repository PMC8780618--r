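#' Construct a head-capsule measurement sample
#'
#' Bundles larval head-capsule widths (the variable used for instar
#' determination) with optional lengths and per-larva metadata. Widths and
#' lengths are in micrometres; head capsules grow only at moults, which is
#' why the width distribution of a mixed-age larval sample is multimodal
#' with one mode per instar.
#'
#' @param widths numeric vector of head-capsule widths, um; must be strictly
#'   positive and finite.
#' @param lengths optional numeric vector of head-capsule lengths, um, same
#'   order and length as `widths`.
#' @param larva_id optional identifier vector, recycled checks not applied;
#'   must match `length(widths)` when given.
#' @param collection_day optional non-negative integers, days since hatch.
#' @return an object of class `head_capsule_sample`.
#' @export
head_capsule_sample <- function(widths, lengths = NULL, larva_id = NULL,
                                collection_day = NULL) {
  widths <- as.numeric(widths)
  if (length(widths) == 0L) {
    stop("`widths` must contain at least one measurement", call. = FALSE)
  }
  if (!all(is.finite(widths)) || any(widths <= 0)) {
    stop("all widths must be strictly positive and finite", call. = FALSE)
  }
  if (!is.null(lengths)) {
    lengths <- as.numeric(lengths)
    if (length(lengths) != length(widths)) {
      stop("`lengths` must have the same count as `widths`", call. = FALSE)
    }
    if (any(!is.na(lengths) & lengths <= 0)) {
      stop("lengths must be strictly positive where present", call. = FALSE)
    }
  }
  if (!is.null(larva_id) && length(larva_id) != length(widths)) {
    stop("`larva_id` must match `widths` in length", call. = FALSE)
  }
  if (!is.null(collection_day)) {
    if (length(collection_day) != length(widths) ||
        any(!is.na(collection_day) & collection_day < 0)) {
      stop("`collection_day` must be non-negative, one per larva",
           call. = FALSE)
    }
  }
  structure(
    list(widths = widths, lengths = lengths, larva_id = larva_id,
         collection_day = collection_day),
    class = "head_capsule_sample"
  )
}

#' @export
print.head_capsule_sample <- function(x, ...) {
  cat("Head-capsule sample:", length(x$widths), "larvae\n")
  cat(sprintf("  width range %.2f - %.2f um%s\n",
              min(x$widths), max(x$widths),
              if (is.null(x$lengths)) "" else " (lengths present)"))
  invisible(x)
}

as_widths <- function(sample) {
  if (inherits(sample, "head_capsule_sample")) sample$widths
  else as.numeric(sample)
}

#' Kernel density estimate of the head-capsule width distribution
#'
#' Gaussian-kernel density of the widths, the curve whose modes are counted
#' during instar determination. The grid extends at least three bandwidths
#' beyond the data range so that essentially all kernel mass is captured and
#' the trapezoid integral of the curve is 1 to within 1e-3.
#'
#' @param sample a [head_capsule_sample()] or numeric vector of widths.
#' @param bandwidth_rule `"silverman"` (rule-of-thumb, default), `"scott"`,
#'   or `"fixed"` (then `bandwidth` must be given). May also be a single
#'   positive number, shorthand for a fixed bandwidth.
#' @param grid_size number of evaluation points (default 512).
#' @param bandwidth fixed bandwidth in um when `bandwidth_rule = "fixed"`.
#' @return object of class `hc_density` with elements `x` (grid), `y`
#'   (density values), `bw`, `n`.
#' @export
estimate_density <- function(sample, bandwidth_rule = c("silverman", "scott",
                                                        "fixed"),
                             grid_size = 512L, bandwidth = NULL) {
  w <- as_widths(sample)
  if (length(w) < 5L) {
    stop("density estimation needs at least 5 observations", call. = FALSE)
  }
  if (var(w) <= .Machine$double.eps * max(abs(w))^2) {
    stop("degenerate sample: zero variance in widths", call. = FALSE)
  }
  if (is.numeric(bandwidth_rule)) {
    bandwidth <- bandwidth_rule
    bandwidth_rule <- "fixed"
  }
  bandwidth_rule <- match.arg(bandwidth_rule)
  bw <- switch(bandwidth_rule,
    silverman = bw.nrd0(w),
    scott = bw.nrd(w),
    fixed = {
      if (is.null(bandwidth) || !is.finite(bandwidth) || bandwidth <= 0) {
        stop("a positive fixed `bandwidth` is required", call. = FALSE)
      }
      bandwidth
    }
  )
  d <- density(w, bw = bw, n = as.integer(grid_size),
               from = min(w) - 3 * bw, to = max(w) + 3 * bw)
  structure(list(x = d$x, y = d$y, bw = bw, n = length(w),
                 rule = bandwidth_rule),
            class = "hc_density")
}

#' Count modes of a density curve
#'
#' Number of strict local maxima of the evaluated curve; runs of equal
#' density values (plateaus) collapse to a single mode, and a maximum at a
#' grid boundary counts (a monotone density has one mode).
#'
#' @param dens an `hc_density` object, or any list with `x` and `y`.
#' @return positive integer count of modes.
#' @export
count_modes <- function(dens) {
  y <- dens$y
  if (is.null(y) || length(y) < 2L) stop("malformed density curve",
                                         call. = FALSE)
  r <- rle(y)$values          # collapse plateaus
  k <- length(r)
  if (k == 1L) return(1L)
  up <- c(TRUE, diff(r) > 0)   # boundary counts as rising into first value
  dn <- c(diff(r) < 0, TRUE)   # and falling off the last
  sum(up & dn)
}

# x-locations of the (plateau-collapsed) local maxima and minima of a curve
turning_points <- function(dens) {
  y <- dens$y; x <- dens$x
  r <- rle(y)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  mid <- (x[starts] + x[ends]) / 2
  v <- r$values
  k <- length(v)
  up <- c(TRUE, diff(v) > 0)
  dn <- c(diff(v) < 0, TRUE)
  list(max_x = mid[up & dn], max_y = v[up & dn],
       min_x = mid[!up & !dn], min_y = v[!up & !dn])
}

#' Instar boundaries from density antimodes
#'
#' Places the k-1 instar cut-points at the deepest local minima (antimodes)
#' of the width density lying between successive retained modes. When the
#' curve has more than `k` maxima the `k` highest are retained; within each
#' gap between retained modes the deepest minimum is used, ties broken by
#' the minimum closest to the geometric midpoint of the flanking modes.
#'
#' @param sample a [head_capsule_sample()] or numeric widths (used only to
#'   check the boundaries fall inside the data range).
#' @param dens an `hc_density` for the same sample.
#' @param k number of instars.
#' @return numeric vector of k-1 strictly increasing boundaries, um.
#' @export
split_at_antimodes <- function(sample, dens, k) {
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1", call. = FALSE)
  if (k == 1L) return(numeric(0))
  tp <- turning_points(dens)
  if (length(tp$max_x) < k) {
    stop(sprintf(paste("density has %d modes but %d instars requested;",
                       "try a smaller bandwidth"),
                 length(tp$max_x), k), call. = FALSE)
  }
  keep <- sort(order(tp$max_y, decreasing = TRUE)[seq_len(k)])
  mx <- tp$max_x[keep]
  boundaries <- numeric(k - 1L)
  for (i in seq_len(k - 1L)) {
    lo <- mx[i]; hi <- mx[i + 1L]
    in_gap <- tp$min_x > lo & tp$min_x < hi
    if (!any(in_gap)) {
      stop("no antimode found between successive modes", call. = FALSE)
    }
    cand_x <- tp$min_x[in_gap]; cand_y <- tp$min_y[in_gap]
    deepest <- cand_y <= min(cand_y) + 0e0
    cand_x <- cand_x[deepest]
    geomid <- sqrt(lo * hi)
    boundaries[i] <- cand_x[which.min(abs(cand_x - geomid))]
  }
  w <- as_widths(sample)
  stopifnot(all(boundaries > min(w)), all(boundaries < max(w)))
  boundaries
}

# instar index per observation: intervals closed on the left, open on the
# right, last interval closed on both sides (findInterval semantics)
assign_instars <- function(widths, boundaries) {
  findInterval(widths, boundaries) + 1L
}

#' Per-instar descriptive statistics
#'
#' Splits the widths at the given boundaries (intervals closed on the left,
#' open on the right; the last closed on both sides) and reports count, mean,
#' standard error, minimum and maximum per instar.
#'
#' @param sample a [head_capsule_sample()] or numeric widths.
#' @param boundaries strictly increasing cut-points, um.
#' @return data.frame with columns `instar, n, mean, se, min, max`.
#' @export
instar_stats <- function(sample, boundaries) {
  w <- as_widths(sample)
  boundaries <- sort(as.numeric(boundaries))
  idx <- assign_instars(w, boundaries)
  k <- length(boundaries) + 1L
  if (!all(seq_len(k) %in% idx)) {
    stop("classification error: at least one instar class is empty",
         call. = FALSE)
  }
  out <- do.call(rbind, lapply(seq_len(k), function(i) {
    wi <- w[idx == i]
    data.frame(instar = i, n = length(wi), mean = mean(wi),
               se = if (length(wi) > 1L) sd(wi) / sqrt(length(wi)) else NA_real_,
               min = min(wi), max = max(wi))
  }))
  if (any(diff(out$mean) <= 0)) {
    stop("classification error: instar means are not strictly increasing",
         call. = FALSE)
  }
  stopifnot(sum(out$n) == length(w))
  out
}

#' Brooks-Dyar growth ratios
#'
#' Ratio of successive instar mean head-capsule widths. Under Dyar's rule the
#' ratio is approximately constant across moults; the geometric mean of the
#' ratios is reported as the summary Dyar constant.
#'
#' @param means strictly increasing per-instar mean widths, um.
#' @return list with `ratios` (length k-1) and `constant` (geometric mean).
#' @export
dyar_ratios <- function(means) {
  means <- as.numeric(means)
  if (length(means) < 2L) stop("need at least 2 instar means", call. = FALSE)
  if (any(diff(means) <= 0)) {
    stop("instar means must be strictly increasing", call. = FALSE)
  }
  ratios <- means[-1L] / means[-length(means)]
  list(ratios = ratios, constant = exp(mean(log(ratios))))
}

#' Log-linear growth regression across instars
#'
#' Ordinary least squares of log head-capsule width on instar index. Under
#' Dyar's rule log-width is linear in instar number, so a high r-squared
#' supports the classification and `exp(slope)` is an alternative estimator
#' of the Dyar constant.
#'
#' @param widths numeric widths, um.
#' @param instar integer instar labels, same length.
#' @return list `slope, intercept, r_squared, n, dyar_from_slope`.
#' @export
growth_regression <- function(widths, instar) {
  widths <- as.numeric(widths); instar <- as.numeric(instar)
  stopifnot(length(widths) == length(instar))
  if (length(unique(instar)) < 2L) {
    stop("need at least 2 instar classes for a regression", call. = FALSE)
  }
  if (length(widths) < 3L) stop("need at least 3 points", call. = FALSE)
  fit <- lm(log(widths) ~ instar)
  s <- summary(fit)
  list(slope = unname(coef(fit)[2L]), intercept = unname(coef(fit)[1L]),
       r_squared = s$r.squared, n = length(widths),
       dyar_from_slope = exp(unname(coef(fit)[2L])))
}

#' Full instar classification from a head-capsule sample
#'
#' Runs the complete determination pipeline: sequential excess-mass testing
#' to choose the number of instars, antimode cut-points on the width density,
#' per-instar statistics, Dyar ratios, and the log-linear growth regression.
#'
#' @param sample a [head_capsule_sample()].
#' @param k_max largest number of instars entertained.
#' @param alpha significance level of each excess-mass test.
#' @param n_boot bootstrap replicates per test (>= 100).
#' @param seed integer seed for the bootstrap calibration.
#' @param bandwidth_rule passed to [estimate_density()].
#' @param grid_size density grid resolution.
#' @param bandwidth fixed bandwidth when `bandwidth_rule = "fixed"`.
#' @return object of class `instar_classification`: `n_instars`, `boundaries`,
#'   `per_instar`, `dyar`, `regression`, `mode_tests` (one row per k tried),
#'   `saturated` flag (TRUE when every k up to `k_max` was rejected).
#' @export
classify_instars <- function(sample, k_max = 5L, alpha = 0.05,
                             n_boot = 500L, seed = 1L,
                             bandwidth_rule = "silverman",
                             grid_size = 512L, bandwidth = NULL) {
  sel <- find_instar_count(sample, k_max = k_max, alpha = alpha,
                           n_boot = n_boot, seed = seed, details = TRUE)
  k <- sel$k
  dens <- estimate_density(sample, bandwidth_rule = bandwidth_rule,
                           grid_size = grid_size, bandwidth = bandwidth)
  # the rule-of-thumb curve may be too smooth to show all k modes; sharpen
  # the bandwidth until the antimodes are resolvable
  bw <- dens$bw
  while (count_modes(dens) < k && bw > dens$bw / 64) {
    bw <- bw * 0.8
    dens <- estimate_density(sample, bandwidth_rule = bw,
                             grid_size = grid_size)
  }
  boundaries <- split_at_antimodes(sample, dens, k)
  per <- instar_stats(sample, boundaries)
  dy <- if (k >= 2L) dyar_ratios(per$mean) else
    list(ratios = numeric(0), constant = NA_real_)
  reg <- if (k >= 2L) {
    growth_regression(as_widths(sample),
                      assign_instars(as_widths(sample), boundaries))
  } else NULL
  structure(
    list(n_instars = k, boundaries = boundaries, per_instar = per,
         dyar = dy, regression = reg, mode_tests = sel$table,
         saturated = sel$saturated, density = dens),
    class = "instar_classification"
  )
}

#' @export
print.instar_classification <- function(x, ...) {
  cat("Instar classification:", x$n_instars, "instars",
      if (x$saturated) "(saturated at k_max: every k rejected)" else "", "\n")
  if (length(x$boundaries)) {
    cat("  boundaries (um):", paste(sprintf("%.2f", x$boundaries),
                                    collapse = ", "), "\n")
  }
  print(x$per_instar, row.names = FALSE)
  if (length(x$dyar$ratios)) {
    cat(sprintf("  Dyar ratios: %s (geometric mean %.4f)\n",
                paste(sprintf("%.4f", x$dyar$ratios), collapse = ", "),
                x$dyar$constant))
  }
  if (!is.null(x$regression)) {
    cat(sprintf("  ln(width) ~ instar: slope %.4f, r^2 %.3f, n %d\n",
                x$regression$slope, x$regression$r_squared, x$regression$n))
  }
  invisible(x)
}
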