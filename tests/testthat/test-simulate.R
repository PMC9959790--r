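test_that("a TMSP-only spectrum leaves every analyte region empty", {
  p <- default_panel()
  s <- simulate_spectrum(p, stats::setNames(numeric(0), character(0)))
  tm <- p$regions[p$regions$analyte_id == "tmsp", ]
  expect_gt(integrate_region(s, tm$ppm_min, tm$ppm_max), 0)
  for (i in which(p$regions$analyte_id != "tmsp")) {
    a <- integrate_region(s, p$regions$ppm_min[i], p$regions$ppm_max[i])
    expect_lt(a, 1e-6 * integrate_region(s, tm$ppm_min, tm$ppm_max))
  }
})

test_that("region areas are proportional to concentration times protons", {
  p <- default_panel()
  s <- simulate_spectrum(p, c(proline = 1.0))
  pr <- p$regions[p$regions$analyte_id == "proline", ]
  tm <- p$regions[p$regions$analyte_id == "tmsp", ]
  a_pro <- integrate_region(s, pr$ppm_min, pr$ppm_max)
  a_tm <- integrate_region(s, tm$ppm_min, tm$ppm_max)
  # (A/nH) ratio equals the molar ratio 1.0 / 0.966
  expect_equal((a_pro / pr$n_protons_effective) / (a_tm / 9),
               1.0 / 0.966, tolerance = 0.005)
})

test_that("doubling every concentration doubles every analyte region area", {
  p <- default_panel()
  conc <- realistic_mM(p)
  s1 <- simulate_spectrum(p, conc)
  s2 <- simulate_spectrum(p, 2 * conc)
  for (id in c("trigonelline", "fructose", "turanose")) {
    rr <- p$regions[p$regions$analyte_id == id, , drop = FALSE]
    a1 <- sum(mapply(integrate_region, rr$ppm_min, rr$ppm_max,
                     MoreArgs = list(s = s1)))
    a2 <- sum(mapply(integrate_region, rr$ppm_min, rr$ppm_max,
                     MoreArgs = list(s = s2)))
    expect_equal(a2, 2 * a1, tolerance = 1e-10)
  }
})

test_that("simulation is bit-identical under a fixed seed and validates input", {
  p <- default_panel()
  shp <- lineshape_params(points = 2048, ppm_range = c(-0.5, 9.5),
                          noise_sd = 0.01)
  s1 <- simulate_spectrum(p, c(proline = 1), shape = shp, seed = 7)
  s2 <- simulate_spectrum(p, c(proline = 1), shape = shp, seed = 7)
  expect_identical(s1$intensity, s2$intensity)
  expect_error(simulate_spectrum(p, c(nonsense = 1)), "unknown analyte")
  expect_error(simulate_spectrum(p, c(proline = -1)), "negative concentration")
  expect_error(
    simulate_spectrum(p, c(proline = 1),
                      shape = lineshape_params(points = 1024,
                                               ppm_range = c(0.5, 1.0))),
    "outside the simulated grid")
})

test_that("the default cohort reproduces the designed class structure", {
  co <- simulate_cohort(cohort_design(seed = 3))
  expect_equal(dim(co$concentrations), c(424, 33))
  expect_equal(sum(co$class == "positive"), 105)
  expect_true(all(co$concentrations > 0))
  tri <- co$concentrations[, "trigonelline"]
  expect_gt(mean(tri[co$class == "positive"]),
            2 * mean(tri[co$class == "negative"]))
  expect_gt(mean(tri[co$class == "positive"] > 20), 0.8)
  for (id in c("ethanol", "succinate", "lactate", "alanine", "phenylalanine")) {
    v <- co$concentrations[, id]
    expect_lt(mean(v[co$class == "positive"]),
              0.5 * mean(v[co$class == "negative"]) * 1.1)
  }
  # reproducibility
  co2 <- simulate_cohort(cohort_design(seed = 3))
  expect_identical(co$concentrations, co2$concentrations)
})

test_that("cohort sample means converge to the design means", {
  eff <- honeynmr:::cohort_effect_table()
  d <- cohort_design(n_positive = 10000, n_negative = 2, effects = eff,
                     seed = 12)
  co <- simulate_cohort(d)
  pos <- co$concentrations[co$class == "positive", ]
  for (id in c("trigonelline", "proline", "fructose")) {
    m <- eff$mean_positive[eff$analyte_id == id]
    se <- sd(pos[, id]) / sqrt(nrow(pos))
    expect_lt(abs(mean(pos[, id]) - m), 3 * se + 1e-12)
  }
})

test_that("degenerate dispersion separates the classes deterministically", {
  eff <- honeynmr:::cohort_effect_table()
  eff$cv_negative <- eff$cv_positive <- 0
  co <- simulate_cohort(cohort_design(n_positive = 20, n_negative = 30,
                                      effects = eff, seed = 1))
  tri <- co$concentrations[, "trigonelline"]
  expect_gt(min(tri[co$class == "positive"]),
            max(tri[co$class == "negative"]))
})

test_that("replicate maps follow the requested coefficient of variation", {
  conc <- c(proline = 2, glucose = 100)
  expect_identical(simulate_replicates(conc, 0, 3, seed = 1),
                   rep(list(conc), 3))
  expect_length(simulate_replicates(conc, 0.05, 1, seed = 1), 1)
  reps <- simulate_replicates(conc, 0.05, 3000, seed = 2)
  M <- do.call(rbind, reps)
  emp_cv <- apply(M, 2, sd) / colMeans(M)
  expect_true(all(abs(emp_cv - 0.05) < 0.005))
})

test_that("cohort tables round trip through delimited text", {
  co <- simulate_cohort(cohort_design(n_positive = 5, n_negative = 7, seed = 2))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_cohort(co, f)
  back <- read_cohort(f)
  expect_equal(back$concentrations, co$concentrations, tolerance = 1e-6)
  expect_equal(back$class, co$class)
  expect_equal(back$units, co$units)
})
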