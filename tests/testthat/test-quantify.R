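test_that("region integration is a plain inclusive point sum", {
  s <- flat_spectrum(n = 101, value = 0)
  expect_equal(integrate_region(s, 0.2, 0.8), 0)
  s1 <- flat_spectrum(n = 101, value = 1)          # grid step 0.01
  # [0.20, 0.36] covers exactly 17 grid points, endpoints inclusive
  expect_equal(integrate_region(s1, 0.195, 0.365), 17)
  expect_error(integrate_region(s1, 0.9, 1.5), "outside the axis")
  s_unref <- nmr_spectrum(seq(0, 1, 0.01), rep(1, 101))
  expect_error(integrate_region(s_unref, 0.2, 0.8), "referenced")
})

test_that("a Lorentzian integrates to its analytic area on the grid", {
  # amplitude A, HWHM g, grid step d: point sum over a wide region ~ pi*A*g/d
  d <- 1e-4; g <- 20e-4; A <- 3
  ppm <- seq(-1, 1, by = d)
  s <- nmr_spectrum(ppm, A * g^2 / (ppm^2 + g^2), referenced = TRUE)
  expect_equal(integrate_region(s, -0.9, 0.9), pi * A * g / d,
               tolerance = 0.01)
})

test_that("internal-standard quantitation recovers known concentrations", {
  p <- default_panel()
  # proline 1.0 mM at the default preparation: 1 umol x 115.13 g/mol in
  # 1 mL over 0.05 g honey = 2302.6 mg/kg
  s <- simulate_spectrum(p, c(proline = 1.0))
  q <- quantify(s, p)
  expect_equal(q$concentration[q$analyte_id == "proline"], 2302.6,
               tolerance = 0.01)
  expect_equal(q$mM[q$analyte_id == "proline"], 1.0, tolerance = 0.005)
  # glucose 10 mM through the 2-proton H-4 region: 3.6032 g/100 g
  s2 <- simulate_spectrum(p, c(glucose = 10))
  q2 <- quantify(s2, p)
  expect_equal(q2$concentration[q2$analyte_id == "glucose"],
               10 * 180.16 * 20 / 1e4, tolerance = 0.01)
  expect_equal(q2$unit[q2$analyte_id == "glucose"], "g/100g")
})

test_that("a TMSP-only spectrum flags every analyte below LOQ", {
  p <- default_panel()
  s <- simulate_spectrum(p, stats::setNames(numeric(0), character(0)))
  q <- quantify(s, p)
  expect_true(all(q$loq_flag))
  expect_true(all(q$concentration >= 0 | abs(q$concentration) < 1e-8))
})

test_that("quantitation is invariant to global intensity rescaling", {
  p <- default_panel()
  s <- simulate_spectrum(p, realistic_mM(p, jitter_sd = 0.3, seed = 5))
  q1 <- quantify(s, p)
  for (c_scale in c(1e-3, 7.7, 1e4)) {
    s2 <- nmr_spectrum(s$ppm, s$intensity * c_scale, referenced = TRUE,
                       meta = s$meta)
    q2 <- quantify(s2, p)
    expect_equal(q2$concentration, q1$concentration, tolerance = 1e-10)
  }
})

test_that("unit identity holds: mg/kg = 1e4 x g/100g", {
  p <- default_panel()
  s <- simulate_spectrum(p, c(glucose = 20, proline = 1))
  q <- quantify(s, p)
  g <- q[q$analyte_id == "glucose", ]
  # recompute glucose as mg/kg via its molar concentration
  expect_equal(g$mM * 180.16 * 20, g$concentration * 1e4, tolerance = 1e-9)
})

test_that("triplicate averaging uses the n-1 sd and re-flags on the mean", {
  p <- default_panel()
  mk <- function(val, id = "s1") {
    s <- simulate_spectrum(p, c(proline = val), sample_id = id)
    quantify(s, p)
  }
  reps <- lapply(c(1, 2, 3), mk)
  avg <- average_triplicates(reps, p)
  i <- which(avg$analyte_id == "proline")
  expect_equal(avg$mM[i], 2, tolerance = 0.005)
  expect_equal(avg$sd[i], sd(sapply(reps, function(r) r$concentration[i])))
  one <- average_triplicates(reps[1], p)
  expect_true(is.na(one$sd[i]))
  expect_equal(one$concentration, reps[[1]]$concentration)
  bad <- mk(1, id = "other")
  expect_error(average_triplicates(list(reps[[1]], bad), p),
               "mixed sample ids")
})

test_that("identical replicates average to themselves with zero sd", {
  p <- default_panel()
  s <- simulate_spectrum(p, c(proline = 1.5), sample_id = "a")
  q <- quantify(s, p)
  avg <- average_triplicates(list(q, q, q), p)
  expect_equal(avg$concentration, q$concentration)
  expect_true(all(avg$sd == 0))
})

test_that("frequency distributions conserve counts and flag sub-LOQ bins", {
  set.seed(8)
  v <- runif(500, 0, 100)
  fd <- frequency_distribution(v)
  expect_equal(nrow(fd), 100)
  expect_equal(sum(fd$count), 500)
  expect_warning(fd1 <- frequency_distribution(c(1, 1, 1)), "single bin")
  expect_equal(fd1$count, 3)
  # brute-force check of the below-LOQ flag
  loq <- stats::median(v)
  fd2 <- frequency_distribution(v, loq = loq)
  expect_equal(fd2$below_loq, fd2$bin_high <= loq)
})
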