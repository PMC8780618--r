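test_that("head_capsule_sample validates its invariants", {
  expect_s3_class(head_capsule_sample(c(100, 200)), "head_capsule_sample")
  expect_error(head_capsule_sample(c(100, -5)), "strictly positive")
  expect_error(head_capsule_sample(c(100, Inf)), "strictly positive")
  expect_error(head_capsule_sample(numeric(0)), "at least one")
  expect_error(head_capsule_sample(c(100, 200), lengths = 80),
               "same count")
  expect_error(head_capsule_sample(100, collection_day = -1),
               "non-negative")
})

test_that("estimate_density normalises, extends the grid and errors on bad input", {
  set.seed(10)
  w <- rlnorm(60, log(300), 0.2)
  for (rule in c("silverman", "scott")) {
    d <- estimate_density(w, bandwidth_rule = rule, grid_size = 512)
    expect_true(all(d$y >= 0))
    integral <- sum(diff(d$x) * (head(d$y, -1) + tail(d$y, -1)) / 2)
    expect_equal(integral, 1, tolerance = 1e-3)
    expect_lte(d$x[1], min(w) - 3 * d$bw + 1e-9)
    expect_gte(d$x[length(d$x)], max(w) + 3 * d$bw - 1e-9)
  }
  d <- estimate_density(w, bandwidth_rule = 5)   # numeric shorthand = fixed
  expect_equal(d$bw, 5)
  expect_error(estimate_density(w[1:4]), "at least 5")
  expect_error(estimate_density(rep(300, 20) + runif(20, -1e-9, 1e-9)),
               "degenerate")
  expect_error(estimate_density(w, bandwidth_rule = "fixed"),
               "bandwidth")
})

test_that("a Dyar-structured trimodal sample yields exactly 3 density maxima", {
  s <- generate_head_capsules(morphometry_config(seed = 1))
  d <- estimate_density(s, grid_size = 512)
  expect_equal(count_modes(d), 3L)
})

test_that("count_modes collapses plateaus and counts boundary maxima", {
  # monotone decreasing curve: single boundary mode
  expect_equal(count_modes(list(x = 1:100, y = exp(-(1:100) / 20))), 1L)
  # plateau at the top counts once
  expect_equal(count_modes(list(x = 1:7, y = c(0, 1, 2, 2, 2, 1, 0))), 1L)
  # two separated plateaus
  expect_equal(count_modes(list(x = 1:9,
                                y = c(0, 2, 2, 1, 1, 1, 3, 3, 0))), 2L)
  # flat curve is one (degenerate) mode
  expect_equal(count_modes(list(x = 1:5, y = rep(1, 5))), 1L)
  expect_error(count_modes(list(x = 1, y = 1)), "malformed")
  # sampled cases: unimodal Gaussian and a monotone exponential KDE
  set.seed(2)
  expect_equal(count_modes(estimate_density(rnorm(100, 50, 5) + 200)), 1L)
  set.seed(9)
  expect_equal(count_modes(estimate_density(rexp(200) + 1)), 1L)
})

test_that("antimode boundaries land between the instar modes", {
  s <- generate_head_capsules(morphometry_config(seed = 1))
  d <- estimate_density(s)
  b <- split_at_antimodes(s, d, 3)
  expect_length(b, 2L)
  expect_gt(b[1], 280); expect_lt(b[1], 350)
  expect_gt(b[2], 430); expect_lt(b[2], 520)
  expect_true(all(b > min(s$widths) & b < max(s$widths)))
  expect_identical(split_at_antimodes(s, d, 1), numeric(0))
  # oversmoothed curve cannot be split into 3
  d_smooth <- estimate_density(s, bandwidth_rule = 200)
  expect_error(split_at_antimodes(s, d_smooth, 3), "smaller bandwidth")
})

test_that("instar_stats partitions the sample with increasing means", {
  st <- instar_stats(c(100, 110, 200, 210), boundaries = 150)
  expect_equal(st$n, c(2L, 2L))
  expect_equal(st$mean, c(105, 205))
  expect_equal(st$se, c(sd(c(100, 110)) / sqrt(2), sd(c(200, 210)) / sqrt(2)))
  # boundary values go to the upper class (closed-left intervals)
  st2 <- instar_stats(c(100, 150, 200), boundaries = 150)
  expect_equal(st2$n, c(1L, 2L))
  expect_error(instar_stats(c(100, 110), boundaries = 500), "empty")
  # trimodal fixture: counts track the configured 29/26/43 weights
  s <- generate_head_capsules(morphometry_config(seed = 1))
  b <- split_at_antimodes(s, estimate_density(s), 3)
  st3 <- instar_stats(s, b)
  expect_equal(sum(st3$n), 98L)
  expect_true(all(abs(st3$n - c(29, 26, 43)) <= 8))
  expect_true(all(diff(st3$mean) > 0))
})

test_that("dyar_ratios reproduces ratios of published instar means", {
  means <- c(248.14, 383.31, 563.23)
  dy <- dyar_ratios(means)
  expect_equal(dy$ratios, c(383.31 / 248.14, 563.23 / 383.31),
               tolerance = 1e-12)
  expect_equal(dy$ratios, c(1.5447, 1.4694), tolerance = 1e-4)
  expect_equal(dy$constant, sqrt(prod(dy$ratios)), tolerance = 1e-12)
  expect_equal(dy$constant, 1.5066, tolerance = 1e-4)
  expect_equal(dyar_ratios(c(1, 2, 4)),
               list(ratios = c(2, 2), constant = 2))
  # exact geometric growth returns the generating constant everywhere
  w <- 120 * 1.5^(0:4)
  expect_equal(dyar_ratios(w)$ratios, rep(1.5, 4), tolerance = 1e-12)
  expect_error(dyar_ratios(c(2, 1)), "increasing")
  expect_error(dyar_ratios(5), "at least 2")
})

test_that("growth_regression recovers log-linear Dyar growth", {
  # noiseless geometric growth: slope = log ratio, perfect fit
  w <- rep(100 * 1.5^(1:3), each = 10)
  i <- rep(1:3, each = 10)
  fit <- suppressWarnings(growth_regression(w, i))  # "essentially perfect fit"
  expect_equal(fit$slope, log(1.5), tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  expect_equal(fit$dyar_from_slope, 1.5, tolerance = 1e-9)
  # trimodal fixture with its classified labels fits well
  s <- generate_head_capsules(morphometry_config(seed = 1))
  b <- split_at_antimodes(s, estimate_density(s), 3)
  lab <- findInterval(s$widths, b) + 1
  expect_gte(growth_regression(s$widths, lab)$r_squared, 0.85)
  # shuffled labels destroy the association
  set.seed(4)
  expect_lt(growth_regression(s$widths, sample(lab))$r_squared, 0.2)
  expect_error(growth_regression(w, rep(1, 30)), "2 instar classes")
})

test_that("classify_instars runs the full pipeline on the trimodal fixture", {
  s <- generate_head_capsules(morphometry_config(seed = 1))
  cl <- classify_instars(s, k_max = 4, n_boot = 200, seed = 3)
  expect_s3_class(cl, "instar_classification")
  expect_equal(cl$n_instars, 3L)
  expect_false(cl$saturated)
  expect_equal(nrow(cl$per_instar), 3L)
  expect_length(cl$dyar$ratios, 2L)
  expect_true(all(cl$dyar$ratios > 1))
  expect_gte(cl$regression$r_squared, 0.85)
  expect_equal(nrow(cl$mode_tests), 3L)   # k = 1, 2 rejected, 3 accepted
  expect_output(print(cl), "3 instars")
})
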