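# Independent oracles used across the suite. These deliberately avoid the
# package's own computational paths.

# All systems of at most k index-disjoint closed intervals over n sorted
# points, as 2-column (start, end) matrices. Exhaustive, for small n only.
enum_interval_systems <- function(n, k) {
  out <- list()
  rec <- function(start, left, acc) {
    out[[length(out) + 1]] <<- acc
    if (left == 0 || start > n) return()
    for (a in start:n) for (b in a:n) {
      rec(b + 1, left - 1, rbind(acc, c(a, b)))
    }
  }
  rec(1, k, matrix(numeric(0), 0, 2))
  out
}

# Brute-force excess mass statistic: evaluate every interval system at every
# critical lambda (empirical-CDF difference quotients over data-point pairs,
# plus 0 and a value beyond the largest).
brute_excess_mass <- function(x, k) {
  x <- sort(x)
  n <- length(x)
  lam <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    dx <- x[j] - x[i]
    if (dx > 0) lam <- c(lam, (j - i) / n / dx)
  }
  lam <- unique(c(lam, 2 * max(lam) + 1))
  sys_k <- enum_interval_systems(n, k)
  sys_k1 <- enum_interval_systems(n, k + 1)
  eval_sys <- function(sys, l) {
    if (nrow(sys) == 0) return(0)
    sum((sys[, 2] - sys[, 1] + 1) / n - l * (x[sys[, 2]] - x[sys[, 1]]))
  }
  best <- 0
  for (l in lam) {
    d <- max(vapply(sys_k1, eval_sys, numeric(1), l = l)) -
      max(vapply(sys_k, eval_sys, numeric(1), l = l))
    if (d > best) best <- d
  }
  best
}

# Random positive reproduction schedule for Euler-Lotka property tests.
random_schedule <- function(seed) {
  set.seed(seed)
  n <- sample(3:15, 1)
  x <- sort(runif(n, 0.5, 60))
  lx <- rev(sort(runif(n, 0.05, 1)))
  lx <- lx / lx[1]
  mx <- runif(n, 0, 8) * rbinom(n, 1, 0.8)
  if (all(mx == 0)) mx[1] <- 1
  data.frame(x = x, lx = lx, mx = mx, lxmx = lx * mx)
}

# Quick builder for female rearing records.
make_female <- function(id, eggs, longevity = length(eggs), ...) {
  individual_record(id, sex = "female", adult_longevity = longevity,
                    daily_eggs = eggs, ...)
}
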