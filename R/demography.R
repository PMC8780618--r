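#' Construct an individual rearing record
#'
#' One reared individual: immature stage durations, fate, adult longevity
#' and (for females) the daily oviposition trajectory. Ages are in days.
#'
#' @param individual_id identifier.
#' @param sex `"female"`, `"male"` or `"unknown"`.
#' @param stage_durations named numeric vector/list with any of
#'   `egg, L1, L2, L3, pupa` (days); stages after death are absent.
#' @param died_in_stage optional stage name in which the individual died;
#'   implies no later-stage durations and no adult data.
#' @param adult_longevity days from adult emergence to death (adults only).
#' @param daily_eggs non-negative integer vector, eggs laid on each adult
#'   day (females only); length must not exceed `ceiling(adult_longevity)`.
#' @param eggs_hatched optional number of the laid eggs that hatched.
#' @param offspring_female_fraction optional proportion of female offspring.
#' @param treatment optional treatment/group label.
#' @return object of class `individual_record`.
#' @export
individual_record <- function(individual_id, sex = c("female", "male",
                                                     "unknown"),
                              stage_durations = NULL, died_in_stage = NULL,
                              adult_longevity = NULL, daily_eggs = NULL,
                              eggs_hatched = NULL,
                              offspring_female_fraction = NULL,
                              treatment = NULL) {
  sex <- match.arg(sex)
  stages <- c("egg", "L1", "L2", "L3", "pupa")
  if (!is.null(stage_durations)) {
    stage_durations <- unlist(stage_durations)
    bad <- setdiff(names(stage_durations), stages)
    if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "),
                          call. = FALSE)
    if (any(stage_durations < 0)) stop("stage durations must be >= 0",
                                       call. = FALSE)
  }
  if (!is.null(died_in_stage)) {
    died_in_stage <- match.arg(died_in_stage, stages)
    later <- stages[seq_along(stages) > match(died_in_stage, stages)]
    if (any(later %in% names(stage_durations))) {
      stop("died_in_stage implies no later-stage durations", call. = FALSE)
    }
    if (!is.null(adult_longevity) || !is.null(daily_eggs)) {
      stop("an individual that died immature has no adult data",
           call. = FALSE)
    }
  }
  if (!is.null(adult_longevity) && adult_longevity < 0) {
    stop("adult_longevity must be >= 0", call. = FALSE)
  }
  if (!is.null(daily_eggs)) {
    if (sex == "male") stop("males cannot have daily_eggs", call. = FALSE)
    daily_eggs <- as.numeric(daily_eggs)
    if (any(daily_eggs < 0)) stop("daily_eggs must be >= 0", call. = FALSE)
    if (is.null(adult_longevity)) {
      stop("daily_eggs require adult_longevity", call. = FALSE)
    }
    if (length(daily_eggs) > ceiling(adult_longevity)) {
      stop("daily_eggs longer than ceiling(adult_longevity)", call. = FALSE)
    }
  }
  structure(
    list(individual_id = individual_id, sex = sex,
         stage_durations = stage_durations, died_in_stage = died_in_stage,
         adult_longevity = adult_longevity, daily_eggs = daily_eggs,
         eggs_hatched = eggs_hatched,
         offspring_female_fraction = offspring_female_fraction,
         treatment = treatment),
    class = "individual_record"
  )
}

is_adult_female <- function(r) {
  r$sex == "female" && !is.null(r$adult_longevity)
}

#' Build a cohort life table from individual records
#'
#' Daily-census life table for the adult female cohort. For adult day d the
#' pivotal age is x = d - 0.5 (shifted by the mean egg-to-adult duration when
#' `age_origin = "oviposition"`), survivorship l_x is the fraction of the
#' starting female cohort alive during interval d, and age-specific fecundity
#' m_x is the mean number of eggs laid per living female in interval d times
#' `female_fraction` (times `egg_viability` when that discount is switched
#' on). The schedule extends to the last day any female is alive.
#'
#' @param records list of [individual_record()]s; at least one adult female
#'   with a `daily_eggs` trajectory is required.
#' @param age_origin `"adult_emergence"` (default) or `"oviposition"`.
#' @param female_fraction proportion of eggs assumed female (default 0.5).
#' @param apply_egg_viability multiply m_x by `egg_viability`? Default FALSE.
#' @param egg_viability hatch proportion used when `apply_egg_viability`.
#' @param apply_immature_survival multiply l_x by the observed egg-to-adult
#'   survival of the full record set? Default FALSE.
#' @param immature_duration override for the mean egg-to-adult time (days)
#'   used when `age_origin = "oviposition"`; by default it is estimated from
#'   records carrying complete stage durations.
#' @return a `life_table` data.frame with columns `x, lx, mx, lxmx` and
#'   attributes `age_origin`, `n_females`.
#' @export
build_life_table <- function(records,
                             age_origin = c("adult_emergence", "oviposition"),
                             female_fraction = 0.5,
                             apply_egg_viability = FALSE, egg_viability = NULL,
                             apply_immature_survival = FALSE,
                             immature_duration = NULL) {
  age_origin <- match.arg(age_origin)
  if (!is.numeric(female_fraction) || female_fraction < 0 ||
      female_fraction > 1) {
    stop("female_fraction must lie in [0, 1]", call. = FALSE)
  }
  females <- Filter(is_adult_female, records)
  if (!length(females) || !any(vapply(females, function(r)
      !is.null(r$daily_eggs), logical(1)))) {
    stop("empty cohort: no adult female records with oviposition data",
         call. = FALSE)
  }
  n0 <- length(females)
  longev <- vapply(females, `[[`, numeric(1), "adult_longevity")
  days <- seq_len(max(ceiling(longev)))
  eggs_on <- function(r, d) {
    if (is.null(r$daily_eggs) || d > length(r$daily_eggs)) 0 else
      r$daily_eggs[d]
  }
  lx <- mx <- numeric(length(days))
  for (d in days) {
    alive <- ceiling(longev) >= d
    lx[d] <- sum(alive) / n0
    mx[d] <- mean(vapply(females[alive], eggs_on, numeric(1), d = d)) *
      female_fraction
  }
  if (apply_egg_viability) {
    if (is.null(egg_viability) || egg_viability < 0 || egg_viability > 1) {
      stop("egg_viability in [0, 1] is required when applied", call. = FALSE)
    }
    mx <- mx * egg_viability
  }
  if (apply_immature_survival) {
    n_adult <- sum(vapply(records, function(r) !is.null(r$adult_longevity),
                          logical(1)))
    lx <- lx * n_adult / length(records)
  }
  shift <- 0
  if (age_origin == "oviposition") {
    if (is.null(immature_duration)) {
      dev <- vapply(records, function(r) {
        if (is.null(r$died_in_stage) && !is.null(r$stage_durations) &&
            all(c("egg", "L1", "L2", "L3", "pupa") %in%
                names(r$stage_durations))) {
          sum(r$stage_durations)
        } else NA_real_
      }, numeric(1))
      if (all(is.na(dev))) {
        stop(paste("age_origin = 'oviposition' needs stage durations or an",
                   "explicit immature_duration"), call. = FALSE)
      }
      immature_duration <- mean(dev, na.rm = TRUE)
    }
    shift <- immature_duration
  }
  out <- data.frame(x = days - 0.5 + shift, lx = lx, mx = mx,
                    lxmx = lx * mx)
  attr(out, "age_origin") <- age_origin
  attr(out, "n_females") <- n0
  class(out) <- c("life_table", "data.frame")
  out
}

check_schedule <- function(schedule) {
  need <- c("x", "lx", "mx")
  if (!is.data.frame(schedule) || !all(need %in% names(schedule)) ||
      nrow(schedule) == 0L) {
    stop("schedule must be a non-empty data.frame with columns x, lx, mx",
         call. = FALSE)
  }
  schedule
}

#' Net reproductive rate R0
#'
#' `R0 = sum(lx * mx)`: expected lifetime female offspring per newborn (or
#' newly emerged, depending on the age origin) female.
#' @param schedule a `life_table` (or data.frame with `x, lx, mx`).
#' @return R0, female offspring per female.
#' @export
net_reproductive_rate <- function(schedule) {
  s <- check_schedule(schedule)
  sum(s$lx * s$mx)
}

#' Cohort generation time T
#'
#' Mean age of mothers at offspring production:
#' `T = sum(x * lx * mx) / sum(lx * mx)`.
#' @inheritParams net_reproductive_rate
#' @return T in days.
#' @export
generation_time <- function(schedule) {
  s <- check_schedule(schedule)
  R0 <- sum(s$lx * s$mx)
  if (R0 <= 0) stop("generation time undefined: R0 = 0", call. = FALSE)
  sum(s$x * s$lx * s$mx) / R0
}

#' Intrinsic rate of increase, Birch approximation
#'
#' `r_m = ln(R0) / T`: exact when all reproduction happens at a single age,
#' and the convention used in classical insect life-table reports.
#' @param R0 net reproductive rate, > 0.
#' @param T_gen cohort generation time, days, > 0.
#' @return r_m per day.
#' @export
intrinsic_rate_birch <- function(R0, T_gen) {
  if (R0 <= 0) stop("R0 must be > 0", call. = FALSE)
  if (T_gen <= 0) stop("T must be > 0", call. = FALSE)
  log(R0) / T_gen
}

#' Intrinsic rate of increase, Euler-Lotka solution
#'
#' Solves `sum(exp(-r * x) * lx * mx) = 1` for r by root bracketing on
#' \[-2, 5\] per day. This is the exact renewal-equation definition of the
#' intrinsic rate; the Birch value is its single-pulse approximation.
#' @inheritParams net_reproductive_rate
#' @param tol absolute residual tolerance (default 1e-10).
#' @return r_m per day, with Euler-Lotka residual below `tol`.
#' @export
intrinsic_rate_lotka <- function(schedule, tol = 1e-10) {
  s <- check_schedule(schedule)
  R0 <- sum(s$lx * s$mx)
  if (R0 <= 0) stop("R0 must be > 0", call. = FALSE)
  f <- function(r) sum(exp(-r * s$x) * s$lx * s$mx) - 1
  lo <- -2; hi <- 5
  if (f(lo) * f(hi) > 0) {
    stop("no Euler-Lotka sign change in [-2, 5]", call. = FALSE)
  }
  r <- uniroot(f, c(lo, hi), tol = .Machine$double.eps^0.75)$root
  if (abs(f(r)) > tol) {
    stop(sprintf("Euler-Lotka residual %.2e exceeds tol", abs(f(r))),
         call. = FALSE)
  }
  r
}

#' Population doubling time
#'
#' `DT = ln(2) / r_m` days. For a non-growing cohort (r <= 0) the doubling
#' time is infinite and returned as `Inf` with a warning.
#' @param r_m intrinsic rate of increase per day.
#' @return DT in days.
#' @export
doubling_time <- function(r_m) {
  if (!is.finite(r_m)) stop("r_m must be finite", call. = FALSE)
  if (r_m <= 0) {
    warning("population not growing (r_m <= 0): doubling time is infinite")
    return(Inf)
  }
  log(2) / r_m
}

#' Finite rate of increase
#'
#' `lambda = exp(r_m)`: the per-day multiplicative growth factor.
#' @param r_m intrinsic rate of increase per day.
#' @return lambda per day.
#' @export
finite_rate <- function(r_m) {
  if (!is.finite(r_m)) stop("r_m must be finite", call. = FALSE)
  exp(r_m)
}

# all five parameters from a schedule
schedule_parameters <- function(schedule, r_method = c("birch", "lotka")) {
  r_method <- match.arg(r_method)
  R0 <- net_reproductive_rate(schedule)
  T_gen <- generation_time(schedule)
  r <- if (r_method == "birch") intrinsic_rate_birch(R0, T_gen)
       else intrinsic_rate_lotka(schedule, tol = 1e-8)
  DT <- if (r > 0) log(2) / r else Inf
  c(R0 = R0, T = T_gen, r_m = r, DT = DT, lambda = exp(r))
}

#' Demographic parameters with jackknife confidence intervals
#'
#' Computes R0, T, r_m, DT and lambda for the full female cohort, then
#' leave-one-female-out jackknife 95% confidence intervals from the
#' pseudo-values `theta_j = n * theta_all - (n - 1) * theta_(-j)`:
#' `CI = mean(theta_j) +/- t(0.975, n-1) * SE(theta_j)`. The reported point
#' estimate is the all-female estimate, not the pseudo-value mean. The
#' procedure is deterministic given the records.
#'
#' @param records list of [individual_record()]s with >= 3 adult females.
#' @param r_method `"birch"` (default, ln(R0)/T) or `"lotka"` (Euler-Lotka).
#' @param conf_level confidence level (default 0.95).
#' @param ... passed to [build_life_table()] (age origin, female fraction,
#'   viability flags...).
#' @return object of class `demographic_parameters`: `estimates` (named
#'   vector R0, T, r_m, DT, lambda), `ci_95` (matrix with `low`/`high`),
#'   `se`, `r_method`, `n_females`.
#' @export
jackknife_parameters <- function(records, r_method = c("birch", "lotka"),
                                 conf_level = 0.95, ...) {
  r_method <- match.arg(r_method)
  females <- Filter(is_adult_female, records)
  n <- length(females)
  if (n < 3L) {
    stop("jackknife needs at least 3 female records", call. = FALSE)
  }
  others <- Filter(function(r) !is_adult_female(r), records)
  theta_all <- schedule_parameters(build_life_table(records, ...), r_method)
  pseudo <- matrix(NA_real_, n, length(theta_all),
                   dimnames = list(NULL, names(theta_all)))
  for (j in seq_len(n)) {
    rec_j <- c(others, females[-j])
    theta_j <- schedule_parameters(build_life_table(rec_j, ...), r_method)
    pseudo[j, ] <- n * theta_all - (n - 1) * theta_j
  }
  se <- apply(pseudo, 2, sd) / sqrt(n)
  centre <- colMeans(pseudo)
  tq <- qt(1 - (1 - conf_level) / 2, df = n - 1)
  ci <- cbind(low = centre - tq * se, high = centre + tq * se)
  structure(
    list(estimates = theta_all, ci_95 = ci, se = se,
         pseudo_mean = centre, r_method = r_method, n_females = n,
         ci_method = "jackknife", conf_level = conf_level),
    class = "demographic_parameters"
  )
}

#' Demographic parameters with bootstrap-over-females confidence intervals
#'
#' Percentile bootstrap alternative to [jackknife_parameters()]: females are
#' resampled with replacement `n_boot` times and the 2.5/97.5 percentiles of
#' the resampled parameters form the interval. A seed is mandatory.
#'
#' @inheritParams jackknife_parameters
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed integer seed.
#' @return object of class `demographic_parameters` (as for the jackknife,
#'   with `ci_method = "bootstrap"`).
#' @export
bootstrap_parameters <- function(records, r_method = c("birch", "lotka"),
                                 n_boot = 1000L, seed, conf_level = 0.95,
                                 ...) {
  r_method <- match.arg(r_method)
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  females <- Filter(is_adult_female, records)
  n <- length(females)
  if (n < 3L) stop("bootstrap needs at least 3 female records",
                   call. = FALSE)
  others <- Filter(function(r) !is_adult_female(r), records)
  theta_all <- schedule_parameters(build_life_table(records, ...), r_method)
  boot <- withr_seed(seed, {
    t(vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      schedule_parameters(build_life_table(c(others, females[idx]), ...),
                          r_method)
    }, theta_all))
  })
  a <- (1 - conf_level) / 2
  ci <- cbind(low = apply(boot, 2, quantile, probs = a, names = FALSE),
              high = apply(boot, 2, quantile, probs = 1 - a, names = FALSE))
  rownames(ci) <- names(theta_all)
  structure(
    list(estimates = theta_all, ci_95 = ci, se = apply(boot, 2, sd),
         r_method = r_method, n_females = n, ci_method = "bootstrap",
         n_boot = n_boot, seed = as.integer(seed), conf_level = conf_level),
    class = "demographic_parameters"
  )
}

#' @importFrom stats quantile
#' @export
print.demographic_parameters <- function(x, ...) {
  cat(sprintf("Demographic parameters (%s r, %s CI, %d females)\n",
              x$r_method, x$ci_method, x$n_females))
  est <- x$estimates
  fmt <- c(R0 = "%.2f", T = "%.2f", r_m = "%.4f", DT = "%.2f",
           lambda = "%.4f")
  for (p in names(est)) {
    cat(sprintf(paste0("  %-6s ", fmt[p], "  [", fmt[p], ", ", fmt[p], "]\n"),
                p, est[p], x$ci_95[p, "low"], x$ci_95[p, "high"]))
  }
  invisible(x)
}

#' Reproductive-period and fecundity summary
#'
#' Per-female pre-oviposition period (adult emergence to first egg),
#' oviposition period (first to last egg, inclusive), post-oviposition
#' period (last egg to death) and fecundity, summarised as mean, SE and n.
#' Fecundity is total eggs divided by oviposition days by default
#' (`fecundity_denominator = "oviposition_days"`); set it to `"adult_days"`
#' for total eggs over the whole adult lifespan. Females that never laid are
#' excluded from the reproductive means and counted in `n_nonlaying`.
#'
#' @param records list of [individual_record()]s.
#' @param fecundity_denominator `"oviposition_days"` or `"adult_days"`.
#' @return list with a `summary` data.frame (metric, mean, se, n), the
#'   per-female `details` data.frame, and `n_nonlaying`.
#' @export
reproduction_summary <- function(records,
                                 fecundity_denominator =
                                   c("oviposition_days", "adult_days")) {
  fecundity_denominator <- match.arg(fecundity_denominator)
  females <- Filter(function(r) is_adult_female(r) && !is.null(r$daily_eggs),
                    records)
  if (!length(females)) stop("no female records with daily_eggs",
                             call. = FALSE)
  rows <- lapply(females, function(r) {
    eggs <- r$daily_eggs
    total <- sum(eggs)
    if (total == 0) {
      return(data.frame(individual_id = r$individual_id, laid = FALSE,
                        pre = NA_real_, ovi = NA_real_, post = NA_real_,
                        total_eggs = 0, fecundity = NA_real_,
                        longevity = r$adult_longevity))
    }
    first <- min(which(eggs > 0)); last <- max(which(eggs > 0))
    pre <- first - 1
    ovi <- last - first + 1
    post <- r$adult_longevity - last
    fec <- switch(fecundity_denominator,
                  oviposition_days = total / ovi,
                  adult_days = total / r$adult_longevity)
    data.frame(individual_id = r$individual_id, laid = TRUE, pre = pre,
               ovi = ovi, post = post, total_eggs = total, fecundity = fec,
               longevity = r$adult_longevity)
  })
  det <- do.call(rbind, rows)
  laid <- det[det$laid, , drop = FALSE]
  mse <- function(v) {
    v <- v[!is.na(v)]
    data.frame(mean = mean(v),
               se = if (length(v) > 1) sd(v) / sqrt(length(v)) else NA_real_,
               n = length(v))
  }
  hatch <- unlist(lapply(females, function(r) {
    if (is.null(r$eggs_hatched) || sum(r$daily_eggs) == 0) NA_real_
    else 100 * r$eggs_hatched / sum(r$daily_eggs)
  }))
  metrics <- rbind(
    cbind(metric = "fecundity", mse(laid$fecundity)),
    cbind(metric = "fertility_pct", if (all(is.na(hatch)))
      data.frame(mean = NA_real_, se = NA_real_, n = 0L) else mse(hatch)),
    cbind(metric = "pre_oviposition", mse(laid$pre)),
    cbind(metric = "oviposition", mse(laid$ovi)),
    cbind(metric = "post_oviposition", mse(laid$post))
  )
  list(summary = metrics, details = det, n_nonlaying = sum(!det$laid))
}

#' Adult longevity summary by group
#'
#' Descriptive statistics (mean, SE, min, max, n) of adult longevity,
#' grouped by sex and, when present, treatment. No inference is performed.
#' Groups with a single record get `se = NA`; empty groups are omitted with
#' a warning.
#'
#' @param records list of [individual_record()]s with adult longevity.
#' @return data.frame with one row per (treatment, sex) group.
#' @export
longevity_summary <- function(records) {
  adults <- Filter(function(r) !is.null(r$adult_longevity), records)
  if (!length(adults)) stop("no adult records", call. = FALSE)
  df <- do.call(rbind, lapply(adults, function(r) {
    data.frame(sex = r$sex,
               treatment = if (is.null(r$treatment)) "all" else r$treatment,
               longevity = r$adult_longevity)
  }))
  groups <- split(df, list(df$treatment, df$sex), drop = TRUE)
  dropped <- vapply(groups, nrow, integer(1)) == 0L
  if (any(dropped)) warning("empty longevity group(s) omitted")
  out <- do.call(rbind, lapply(groups[!dropped], function(g) {
    data.frame(treatment = g$treatment[1], sex = g$sex[1], n = nrow(g),
               mean = mean(g$longevity),
               se = if (nrow(g) > 1) sd(g$longevity) / sqrt(nrow(g))
                    else NA_real_,
               min = min(g$longevity), max = max(g$longevity))
  }))
  rownames(out) <- NULL
  out[order(out$treatment, out$sex), , drop = FALSE]
}
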