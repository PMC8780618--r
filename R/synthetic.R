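#' Morphometry generator configuration
#'
#' Parameters of the synthetic head-capsule width generator: a k-component
#' lognormal mixture whose successive component medians follow Dyar's rule
#' (constant multiplicative ratio) with a small within-instar coefficient of
#' variation. Defaults emulate a 3-instar weevil sample of 98 larvae with
#' component medians near 248, 383 and 563 um (per-transition ratios 1.5447
#' and 1.4694) and class weights 29/26/43.
#'
#' @param n_instars number of mixture components (instars).
#' @param base_width median width of the first instar, um.
#' @param dyar_ratio multiplicative growth ratio between successive instars;
#'   scalar, or vector of length `n_instars - 1` for per-transition ratios.
#' @param cv within-instar coefficient of variation, in (0, 0.5).
#' @param class_weights mixture weights, length `n_instars`, summing to 1.
#' @param n sample size.
#' @param seed integer seed.
#' @param lengths also generate head-capsule lengths via a fixed allometry?
#' @return a `morphometry_config` list.
#' @export
morphometry_config <- function(n_instars = 3L, base_width = 248.14,
                               dyar_ratio = c(1.5447, 1.4694), cv = 0.06,
                               class_weights = c(29, 26, 43) / 98,
                               n = 98L, seed = 1L, lengths = FALSE) {
  n_instars <- as.integer(n_instars)
  if (n_instars < 1L) stop("n_instars must be >= 1", call. = FALSE)
  if (n_instars > 1L) {
    if (length(dyar_ratio) == 1L) {
      dyar_ratio <- rep(dyar_ratio, n_instars - 1L)
    }
    if (length(dyar_ratio) != n_instars - 1L || any(dyar_ratio <= 1)) {
      stop("dyar_ratio must be > 1, scalar or length n_instars - 1",
           call. = FALSE)
    }
  } else dyar_ratio <- numeric(0)
  if (cv <= 0 || cv >= 0.5) stop("cv must lie in (0, 0.5)", call. = FALSE)
  if (length(class_weights) != n_instars || any(class_weights < 0)) {
    stop("class_weights must be non-negative, one per instar", call. = FALSE)
  }
  class_weights <- class_weights / sum(class_weights)
  medians <- base_width * cumprod(c(1, dyar_ratio))
  structure(
    list(n_instars = n_instars, base_width = base_width,
         dyar_ratio = dyar_ratio, cv = cv, class_weights = class_weights,
         medians = medians, n = as.integer(n), seed = as.integer(seed),
         lengths = lengths),
    class = "morphometry_config"
  )
}

#' Generate a synthetic head-capsule sample
#'
#' Draws widths from the lognormal mixture described by the config:
#' component i has median `base_width * prod(dyar_ratio[1:(i-1)])` and
#' log-scale standard deviation `sqrt(log(1 + cv^2))` (approximately `cv`).
#' Output is reproducible from the seed. When adjacent components are so
#' wide that they overlap heavily (log-median gap under two log-sds) a
#' warning flags that mode-test power will collapse.
#'
#' @param config a [morphometry_config()].
#' @return a [head_capsule_sample()] with attribute `true_instar` (the
#'   generating component of each larva).
#' @export
generate_head_capsules <- function(config = morphometry_config()) {
  stopifnot(inherits(config, "morphometry_config"))
  sdlog <- sqrt(log(1 + config$cv^2))
  if (config$n_instars > 1L &&
      any(diff(log(config$medians)) < 2 * sdlog)) {
    warning("adjacent instar components overlap heavily; ",
            "mode detection power will be poor")
  }
  withr_seed(config$seed, {
    comp <- sample.int(config$n_instars, config$n, replace = TRUE,
                       prob = config$class_weights)
    w <- config$medians[comp] * exp(rnorm(config$n, 0, sdlog))
    len <- if (config$lengths) {
      # fixed allometry: capsule length ~ 0.9 x width with 4% lognormal noise
      0.9 * w * exp(rnorm(config$n, 0, 0.04))
    } else NULL
    out <- head_capsule_sample(w, lengths = len)
    attr(out, "true_instar") <- comp
    out
  })
}

#' Cohort generator configuration
#'
#' Parameters of the individual-based cohort simulator. Defaults are the
#' stated world of a weevil cohort reared at 27 C: stage-duration means
#' (egg 3.35, L1 2.6, L2 3.73, L3 2.05, pupa 4.1 days) with individual-level
#' SDs back-calculated from reported standard errors, stage survival from
#' the per-stage sample attrition (20, 20, 19, 18, 18, 18), reproduction
#' means of 4.05 pre-oviposition, 40.35 oviposition and 4.45 post-oviposition
#' days at 5.85 eggs/female/day, a 1:1 sex ratio, 55.2% egg viability, and
#' cohorts of 20 reproducing females. Default spreads are the reported
#' "plus-minus" values taken at face value as individual-level SDs; a user
#' who reads those values as standard errors of the mean can instead pass
#' `se * sqrt(n)` rescalings (see the methods vignette for what each
#' reading implies).
#'
#' @param stage_means named numeric: mean days in egg, L1, L2, L3, pupa.
#' @param stage_sds named numeric, same names: individual SD of each
#'   duration (days).
#' @param stage_survival named numeric in \[0,1\]: per-stage survival.
#' @param pre_ovi_mean,pre_ovi_sd pre-oviposition period, days.
#' @param ovi_mean,ovi_sd oviposition period, days.
#' @param post_ovi_mean,post_ovi_sd post-oviposition period, days.
#' @param daily_fecundity_mean eggs per female per oviposition day.
#' @param fecundity_dispersion negative-binomial size of daily egg counts.
#' @param male_longevity_mean,male_longevity_sd adult male longevity, days.
#' @param female_fraction probability an individual is female.
#' @param egg_viability hatch probability of a laid egg.
#' @param n_females target number of adult females in the cohort.
#' @param seed integer master seed; each individual uses a derived
#'   substream, so growing the cohort does not reshuffle existing ones.
#' @param duration_dist `"gamma"` (default) or `"truncnorm"` durations.
#' @param egg_dist `"nbinom"` (default) or `"poisson"` daily egg counts.
#' @param fecundity_shape `"flat"` (default) or `"triangular"` allocation of
#'   eggs across the oviposition window (mean-preserving).
#' @return a `cohort_config` list.
#' @export
cohort_config <- function(
    stage_means = c(egg = 3.35, L1 = 2.6, L2 = 3.73, L3 = 2.05, pupa = 4.1),
    stage_sds = c(egg = 0.31, L1 = 0.24, L2 = 0.48, L3 = 0.19,
                  pupa = 0.27),
    stage_survival = c(egg = 1, L1 = 19 / 20, L2 = 18 / 19, L3 = 1,
                       pupa = 1),
    pre_ovi_mean = 4.05, pre_ovi_sd = 0.4,
    ovi_mean = 40.35, ovi_sd = 3.53,
    post_ovi_mean = 4.45, post_ovi_sd = 1,
    daily_fecundity_mean = 5.85, fecundity_dispersion = 5,
    male_longevity_mean = 111.1, male_longevity_sd = 8.4,
    female_fraction = 0.5, egg_viability = 0.552,
    n_females = 20L, seed = 1L,
    duration_dist = c("gamma", "truncnorm"),
    egg_dist = c("nbinom", "poisson"),
    fecundity_shape = c("flat", "triangular")) {
  stages <- c("egg", "L1", "L2", "L3", "pupa")
  stopifnot(all(stages %in% names(stage_means)),
            all(stages %in% names(stage_sds)),
            all(stages %in% names(stage_survival)))
  if (any(stage_survival < 0 | stage_survival > 1)) {
    stop("stage_survival must lie in [0, 1]", call. = FALSE)
  }
  if (female_fraction < 0 || female_fraction > 1) {
    stop("female_fraction must lie in [0, 1]", call. = FALSE)
  }
  if (egg_viability < 0 || egg_viability > 1) {
    stop("egg_viability must lie in [0, 1]", call. = FALSE)
  }
  if (any(c(stage_means, pre_ovi_mean, ovi_mean, post_ovi_mean,
            daily_fecundity_mean, male_longevity_mean) < 0)) {
    stop("means must be non-negative", call. = FALSE)
  }
  structure(
    list(stage_means = stage_means[stages], stage_sds = stage_sds[stages],
         stage_survival = stage_survival[stages],
         pre_ovi_mean = pre_ovi_mean, pre_ovi_sd = pre_ovi_sd,
         ovi_mean = ovi_mean, ovi_sd = ovi_sd,
         post_ovi_mean = post_ovi_mean, post_ovi_sd = post_ovi_sd,
         daily_fecundity_mean = daily_fecundity_mean,
         fecundity_dispersion = fecundity_dispersion,
         male_longevity_mean = male_longevity_mean,
         male_longevity_sd = male_longevity_sd,
         female_fraction = female_fraction, egg_viability = egg_viability,
         n_females = as.integer(n_females), seed = as.integer(seed),
         duration_dist = match.arg(duration_dist),
         egg_dist = match.arg(egg_dist),
         fecundity_shape = match.arg(fecundity_shape)),
    class = "cohort_config"
  )
}

# one positive duration draw with given mean/sd under the configured family
draw_duration <- function(mean, sd, dist) {
  if (mean == 0) return(0)
  if (sd == 0) return(mean)
  if (dist == "gamma") {
    shape <- (mean / sd)^2
    rgamma(1, shape = shape, rate = shape / mean)
  } else {
    x <- rnorm(1, mean, sd)
    while (x <= 0) x <- rnorm(1, mean, sd)
    x
  }
}

draw_daily_eggs <- function(n_days, config) {
  mu <- rep(config$daily_fecundity_mean, n_days)
  if (config$fecundity_shape == "triangular" && n_days > 1) {
    w <- 1 - abs(seq_len(n_days) - (n_days + 1) / 2) / ((n_days + 1) / 2)
    mu <- mu * w * n_days / sum(w)   # mean-preserving
  }
  if (config$egg_dist == "nbinom") {
    rnbinom(n_days, size = config$fecundity_dispersion, mu = mu)
  } else {
    rpois(n_days, lambda = mu)
  }
}

# simulate individual i of the cohort on its own RNG substream
simulate_individual <- function(config, i) {
  withr_seed(seed_stream(config$seed, i), {
    sex <- if (runif(1) < config$female_fraction) "female" else "male"
    stages <- names(config$stage_means)
    dur <- numeric(0)
    for (s in stages) {
      if (runif(1) > config$stage_survival[[s]]) {
        return(individual_record(paste0("ind", i), sex = sex,
                                 stage_durations = dur, died_in_stage = s))
      }
      d <- draw_duration(config$stage_means[[s]], config$stage_sds[[s]],
                         config$duration_dist)
      dur <- c(dur, setNames(d, s))
    }
    if (sex == "male") {
      return(individual_record(paste0("ind", i), sex = "male",
                               stage_durations = dur,
                               adult_longevity = draw_duration(
                                 config$male_longevity_mean,
                                 config$male_longevity_sd, "gamma")))
    }
    pre <- max(0L, as.integer(round(draw_duration(
      config$pre_ovi_mean, config$pre_ovi_sd, config$duration_dist))))
    ovi <- max(1L, as.integer(round(draw_duration(
      config$ovi_mean, config$ovi_sd, config$duration_dist))))
    post <- max(0L, as.integer(round(draw_duration(
      config$post_ovi_mean, config$post_ovi_sd, config$duration_dist))))
    eggs <- c(rep(0L, pre), draw_daily_eggs(ovi, config), rep(0L, post))
    total <- sum(eggs)
    hatched <- if (total > 0) rbinom(1, total, config$egg_viability) else 0L
    off_f <- if (hatched > 0) rbinom(1, hatched, 0.5) / hatched else NULL
    individual_record(paste0("ind", i), sex = "female",
                      stage_durations = dur,
                      adult_longevity = pre + ovi + post,
                      daily_eggs = eggs, eggs_hatched = hatched,
                      offspring_female_fraction = off_f)
  })
}

#' Generate an individual-based synthetic cohort
#'
#' Simulates individuals one at a time -- sex Bernoulli(`female_fraction`),
#' stage durations from the configured family (gamma by default, matched
#' mean and SD), per-stage Bernoulli death, then for adult females a
#' pre-oviposition delay, an oviposition window with daily egg counts
#' (negative-binomial by default around a mean-preserving schedule),
#' binomial egg hatch, and a post-oviposition period -- until the target
#' number of adult females is reached (males and immature deaths are kept
#' in the output). Each individual has its own seed substream derived from
#' the master seed, so enlarging the cohort regenerates existing
#' individuals identically.
#'
#' @param config a [cohort_config()].
#' @return list of [individual_record()]s.
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  records <- list()
  n_f <- 0L
  i <- 0L
  max_draws <- 40L * config$n_females + 200L
  while (n_f < config$n_females && i < max_draws) {
    i <- i + 1L
    rec <- simulate_individual(config, i)
    records[[i]] <- rec
    if (is_adult_female(rec)) n_f <- n_f + 1L
  }
  records
}

# pmf of round(X) for X ~ gamma(mean, sd), on 0..K; sd = 0 is a point mass
rounded_gamma_pmf <- function(mean, sd) {
  if (mean == 0) return(1)            # point mass at 0 (index 1 = day 0)
  if (sd == 0) {
    p <- rep(0, round(mean) + 1); p[round(mean) + 1] <- 1
    return(p)
  }
  shape <- (mean / sd)^2
  rate <- shape / mean
  K <- ceiling(mean + 12 * sd) + 2
  j <- 0:K
  p <- pgamma(j + 0.5, shape, rate) - pgamma(pmax(j - 0.5, 0), shape, rate)
  p / sum(p)
}

conv_pmf <- function(p, q) {
  r <- rep(0, length(p) + length(q) - 1L)
  for (i in seq_along(p)) {
    if (p[i] > 0) {
      idx <- i + seq_along(q) - 1L
      r[idx] <- r[idx] + p[i] * q
    }
  }
  r
}

#' Exact expected demographic parameters for a cohort configuration
#'
#' Analytic oracle for the cohort generator: builds the expected adult
#' female l_x / m_x schedule implied by the configuration (distributions of
#' the rounded pre-oviposition, oviposition and post-oviposition day counts,
#' convolved numerically), then computes R0 and T in closed form and the
#' intrinsic rate by the Euler-Lotka solver on the expected schedule. The
#' result is deterministic: no simulation is involved. Exact for the default
#' flat fecundity schedule; for the triangular option R0 is still exact but
#' T and r are approximations.
#'
#' @param config a [cohort_config()].
#' @param age_origin `"adult_emergence"` (default) or `"oviposition"` (the
#'   pivotal ages are then shifted by the summed mean stage durations).
#' @return list with the expected `schedule` (x, lx, mx, lxmx), `R0`, `T`,
#'   `r_birch`, `r_lotka`, `DT`, `lambda` (from the Euler-Lotka rate).
#' @export
expected_parameters <- function(config = cohort_config(),
                                age_origin = c("adult_emergence",
                                               "oviposition")) {
  stopifnot(inherits(config, "cohort_config"))
  age_origin <- match.arg(age_origin)
  pre <- rounded_gamma_pmf(config$pre_ovi_mean, config$pre_ovi_sd)
  ovi <- rounded_gamma_pmf(config$ovi_mean, config$ovi_sd)
  if (length(ovi) >= 1 && ovi[1] > 0) {         # ovi days floor at 1
    if (length(ovi) == 1) ovi <- c(0, 1) else {
      ovi[2] <- ovi[2] + ovi[1]; ovi[1] <- 0
    }
  }
  post <- rounded_gamma_pmf(config$post_ovi_mean, config$post_ovi_sd)
  life <- conv_pmf(conv_pmf(pre, ovi), post)    # pmf of longevity in days
  K <- length(life) - 1L
  S_life <- rev(cumsum(rev(life)))              # P(L >= j), j = 0..K
  ovi_surv <- rev(cumsum(rev(ovi)))             # P(G >= g), g = 0..
  days <- seq_len(K)
  p_lay <- vapply(days, function(d) {
    a <- 0:min(d - 1L, length(pre) - 1L)
    g <- d - a
    s <- ifelse(g + 1L <= length(ovi_surv), ovi_surv[g + 1L], 0)
    sum(pre[a + 1L] * s)
  }, numeric(1))
  lx <- vapply(days, function(d) S_life[d + 1L], numeric(1))
  keep <- lx > 1e-12
  days <- days[keep]; lx <- lx[keep]; p_lay <- p_lay[keep]
  f <- config$daily_fecundity_mean * config$female_fraction
  mx <- f * p_lay / lx
  shift <- if (age_origin == "oviposition") sum(config$stage_means) else 0
  schedule <- data.frame(x = days - 0.5 + shift, lx = lx, mx = mx,
                         lxmx = lx * mx)
  class(schedule) <- c("life_table", "data.frame")
  attr(schedule, "age_origin") <- age_origin
  R0 <- sum(schedule$lxmx)
  if (R0 <= 0) {
    return(list(schedule = schedule, R0 = 0, T = NA_real_,
                r_birch = NA_real_, r_lotka = NA_real_, DT = Inf,
                lambda = NA_real_))
  }
  T_gen <- generation_time(schedule)
  r_b <- intrinsic_rate_birch(R0, T_gen)
  r_l <- intrinsic_rate_lotka(schedule, tol = 1e-8)
  list(schedule = schedule, R0 = R0, T = T_gen, r_birch = r_b,
       r_lotka = r_l, DT = log(2) / r_l, lambda = exp(r_l))
}
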