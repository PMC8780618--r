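test_that("individual_record enforces its invariants", {
  expect_error(individual_record("a", "male", daily_eggs = c(1, 2)),
               "males")
  expect_error(individual_record("a", "female", adult_longevity = 2,
                                 daily_eggs = c(1, 1, 1)),
               "longer than")
  expect_error(individual_record("a", "female", died_in_stage = "L2",
                                 stage_durations = c(egg = 3, L1 = 2,
                                                     L3 = 1)),
               "later-stage")
  expect_error(individual_record("a", "female", died_in_stage = "pupa",
                                 adult_longevity = 5),
               "died immature")
  r <- individual_record("ok", "female", stage_durations = c(egg = 3),
                         adult_longevity = 2.5, daily_eggs = c(1, 0, 2))
  expect_s3_class(r, "individual_record")
})

test_that("build_life_table matches hand-computed schedules", {
  f1 <- make_female("f1", c(2, 2, 0), longevity = 3)
  lt <- build_life_table(list(f1), female_fraction = 0.5)
  expect_equal(lt$x, c(0.5, 1.5, 2.5))
  expect_equal(lt$lx, c(1, 1, 1))
  expect_equal(lt$mx, c(1, 1, 0))
  expect_equal(lt$lxmx, lt$lx * lt$mx)
  expect_equal(net_reproductive_rate(lt), 2)

  # a death halves survivorship and the day-2 mean is over the survivor
  f2 <- make_female("f2", c(1), longevity = 1)
  lt2 <- build_life_table(list(f1, f2), female_fraction = 0.5)
  expect_equal(lt2$lx, c(1, 0.5, 0.5))
  expect_equal(lt2$mx, c(0.75, 1, 0))

  expect_error(build_life_table(list()), "empty cohort")
  expect_error(build_life_table(list(individual_record("m", "male",
                                                       adult_longevity = 5))),
               "empty cohort")
  expect_error(build_life_table(list(f1), female_fraction = 1.5), "\\[0, 1\\]")
})

test_that("life-table flags discount mx and lx as documented", {
  f1 <- make_female("f1", c(4, 4), longevity = 2)
  base <- build_life_table(list(f1))
  viab <- build_life_table(list(f1), apply_egg_viability = TRUE,
                           egg_viability = 0.5)
  expect_equal(viab$mx, base$mx * 0.5)
  # immature survival scales lx by the egg-to-adult survival of the records
  died <- individual_record("d", "unknown", died_in_stage = "egg")
  surv <- build_life_table(list(f1, died), apply_immature_survival = TRUE)
  expect_equal(surv$lx, base$lx * 0.5)
  # oviposition origin shifts pivotal ages by the mean development time
  full <- individual_record("f2", "female",
                            stage_durations = c(egg = 3, L1 = 2, L2 = 4,
                                                L3 = 2, pupa = 4),
                            adult_longevity = 2, daily_eggs = c(4, 4))
  ovi <- build_life_table(list(full), age_origin = "oviposition")
  expect_equal(ovi$x, c(0.5, 1.5) + 15)
  expect_error(build_life_table(list(f1), age_origin = "oviposition"),
               "immature_duration")
  expect_equal(build_life_table(list(f1), age_origin = "oviposition",
                                immature_duration = 10)$x, c(10.5, 11.5))
})

test_that("R0, T and their degenerate cases follow the definitions", {
  one <- data.frame(x = 1, lx = 1, mx = 1)
  expect_equal(net_reproductive_rate(one), 1)
  expect_equal(generation_time(data.frame(x = 10, lx = 0.7, mx = 3)), 10)
  sym <- data.frame(x = c(1, 3), lx = c(1, 1), mx = c(1, 1))
  expect_equal(generation_time(sym), 2)
  # doubling every mx doubles R0, leaves T unchanged
  s <- random_schedule(1)
  s2 <- transform(s, mx = 2 * mx)
  expect_equal(net_reproductive_rate(s2), 2 * net_reproductive_rate(s))
  expect_equal(generation_time(s2), generation_time(s))
  expect_error(net_reproductive_rate(data.frame(x = numeric(0),
                                                lx = numeric(0),
                                                mx = numeric(0))),
               "non-empty")
  expect_error(generation_time(data.frame(x = 1, lx = 1, mx = 0)),
               "undefined")
})

test_that("published life-table parameter chain is reproduced exactly", {
  # diet-row r from printed R0 and T, to the printed 4 dp
  expect_equal(round(intrinsic_rate_birch(7.65, 35.2), 4), 0.0578)
  # doubling times from each printed r, to the printed 2 dp
  expect_equal(round(doubling_time(0.4547), 2), 1.52)
  expect_equal(round(doubling_time(0.0578), 2), 11.99)
  expect_equal(round(doubling_time(0.0841), 2), 8.24)
  # finite rate from the diet+buds r, to the printed 4 dp
  expect_equal(round(finite_rate(0.0841), 4), 1.0877)
  # bud-row T back-computed from printed R0 and r, to the printed 2 dp
  expect_equal(round(log(136.73) / 0.4547, 2), 10.82)
})

test_that("intrinsic rate identities and trivial values hold", {
  expect_equal(intrinsic_rate_birch(1, 17), 0)
  expect_equal(intrinsic_rate_birch(exp(1), 1), 1)
  expect_error(intrinsic_rate_birch(0, 10), "R0")
  expect_equal(doubling_time(log(2)), 1)
  expect_warning(dt0 <- doubling_time(-0.1), "not growing")
  expect_identical(dt0, Inf)
  expect_equal(finite_rate(0), 1)
  for (r in c(-0.3, 0.01, 0.45, 2)) {
    expect_equal(log(finite_rate(r)), r, tolerance = 1e-12)
  }
})

test_that("Euler-Lotka solver agrees with closed forms and Birch", {
  # single pulse: r = ln(R0)/T exactly
  pulse <- data.frame(x = 12, lx = 0.8, mx = 10)
  r_l <- intrinsic_rate_lotka(pulse)
  expect_equal(r_l, intrinsic_rate_birch(8, 12), tolerance = 1e-10)
  # {(1,1,2),(2,1,2)}: 2u + 2u^2 = 1 with u = exp(-r), so r = -ln((sqrt(3)-1)/2)
  s <- data.frame(x = c(1, 2), lx = c(1, 1), mx = c(2, 2))
  expect_equal(intrinsic_rate_lotka(s), -log((sqrt(3) - 1) / 2),
               tolerance = 1e-9)
  # residual is the defining property
  for (seed in 1:40) {
    sch <- random_schedule(seed)
    r <- intrinsic_rate_lotka(sch, tol = 1e-8)
    expect_lte(abs(sum(exp(-r * sch$x) * sch$lx * sch$mx) - 1), 1e-8)
  }
  # no sign change in [-2, 5] is a solver error
  expect_error(intrinsic_rate_lotka(data.frame(x = 0.1, lx = 1, mx = 3)),
               "sign change")
})

test_that("schedule transformations move r the way theory says", {
  s <- random_schedule(3)
  s$mx <- s$mx + 0.5          # ensure R0 > 1
  r0 <- intrinsic_rate_lotka(s)
  # scaling mx up increases r, leaves T (Birch) unchanged
  up <- transform(s, mx = 3 * mx)
  expect_gt(intrinsic_rate_lotka(up), r0)
  # delaying reproduction leaves R0 unchanged and decreases r (R0 > 1)
  late <- transform(s, x = x + 5)
  expect_equal(net_reproductive_rate(late), net_reproductive_rate(s))
  expect_lt(intrinsic_rate_lotka(late), r0)
  # DT * r = ln 2 and ln(lambda) = r to machine precision
  expect_equal(doubling_time(r0) * r0, log(2), tolerance = 1e-12)
  expect_equal(log(finite_rate(r0)), r0, tolerance = 1e-12)
})

test_that("jackknife CIs behave: identical females give zero width", {
  recs <- lapply(1:5, function(i) make_female(paste0("f", i), c(2, 4, 2),
                                              longevity = 3))
  jk <- jackknife_parameters(recs)
  expect_equal(unname(jk$se), rep(0, 5), tolerance = 1e-10)
  expect_equal(unname(jk$ci_95[, "low"]), unname(jk$estimates),
               tolerance = 1e-8)
  # point estimate is the all-female estimate
  lt <- build_life_table(recs)
  expect_equal(unname(jk$estimates["R0"]), net_reproductive_rate(lt))
  expect_error(jackknife_parameters(recs[1:2]), "at least 3")
})

test_that("bootstrap CIs are reproducible and bracket the estimate", {
  set.seed(99)
  recs <- lapply(1:8, function(i)
    make_female(paste0("f", i), rpois(10, 3), longevity = 10))
  b1 <- bootstrap_parameters(recs, n_boot = 200, seed = 5)
  b2 <- bootstrap_parameters(recs, n_boot = 200, seed = 5)
  expect_identical(b1$ci_95, b2$ci_95)
  expect_true(all(b1$ci_95[, "low"] <= b1$ci_95[, "high"]))
  expect_error(bootstrap_parameters(recs, n_boot = 200), "seed")
})

test_that("reproduction_summary computes periods and fecundity per female", {
  f <- make_female("f", c(0, 0, 3, 2, 0, 1, 0, 0), longevity = 8)
  rs <- reproduction_summary(list(f))
  d <- rs$details
  expect_equal(d$pre, 2)
  expect_equal(d$ovi, 4)
  expect_equal(d$post, 2)
  expect_equal(d$fecundity, 1.5)
  # all-zero layer excluded from reproductive means, flagged separately
  z <- make_female("z", rep(0, 5), longevity = 5)
  rs2 <- reproduction_summary(list(f, z))
  expect_equal(rs2$n_nonlaying, 1L)
  expect_equal(rs2$summary$n[rs2$summary$metric == "fecundity"], 1L)
  # alternative denominator: eggs over all adult days
  rs3 <- reproduction_summary(list(f), fecundity_denominator = "adult_days")
  expect_equal(rs3$details$fecundity, 6 / 8)
  # fertility needs eggs_hatched
  fh <- individual_record("fh", "female", adult_longevity = 2,
                          daily_eggs = c(5, 5), eggs_hatched = 6)
  rs4 <- reproduction_summary(list(fh))
  expect_equal(rs4$summary$mean[rs4$summary$metric == "fertility_pct"], 60)
})

test_that("longevity_summary gives descriptive stats per group", {
  recs <- list(
    individual_record("a", "female", adult_longevity = 10),
    individual_record("b", "female", adult_longevity = 20),
    individual_record("c", "female", adult_longevity = 30),
    individual_record("d", "male", adult_longevity = 40))
  ls <- longevity_summary(recs)
  fem <- ls[ls$sex == "female", ]
  expect_equal(fem$mean, 20)
  expect_equal(fem$se, sd(c(10, 20, 30)) / sqrt(3), tolerance = 1e-12)
  expect_equal(fem$se, 5.7735, tolerance = 1e-4)
  expect_equal(c(fem$min, fem$max), c(10, 40 - 10))
  # single-record group: SE reported missing
  expect_true(is.na(ls[ls$sex == "male", "se"]))
  expect_error(longevity_summary(list()), "no adult")
})
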