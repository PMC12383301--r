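test_that("baseline normalization subtracts T0 and clips at zero", {
  tr <- confluence_trace("A1", 0:2, c(10, 15, 40))
  expect_equal(normalize_to_t0(tr)$values, c(0, 5, 30))
  tr2 <- confluence_trace("A1", 0:2, c(10, 8, 40))
  expect_equal(normalize_to_t0(tr2)$values, c(0, 0, 30))
  tr3 <- confluence_trace("A1", 0:2, c(30, 30, 30))
  expect_equal(normalize_to_t0(tr3)$values, c(0, 0, 0))
  expect_equal(attr(normalize_to_t0(tr), "raw"), c(10, 15, 40))
})

test_that("3-point smoothing averages the window and contracts variance", {
  expect_equal(smooth_ma3(c(5, 5, 5, 5)), c(5, 5, 5, 5))
  expect_equal(smooth_ma3(c(0, 3, 6, 9)), c(1.5, 3, 6, 7.5))
  expect_error(smooth_ma3(c(1, 2)), "length >= 3")
  set.seed(11)
  for (i in 1:200) {
    x <- rnorm(49)
    expect_lt(var(smooth_ma3(x)), var(x))
  }
})

test_that("group mean curve matches a per-point loop oracle", {
  reps <- list(confluence_trace("A1", 0:1, c(48, 48)),
               confluence_trace("A2", 0:1, c(50, 50)),
               confluence_trace("A3", 0:1, c(52, 52)))
  gc <- group_mean_curve(reps)
  expect_equal(unname(gc$mean), c(50, 50))
  expect_equal(unname(gc$sd), c(2, 2))

  set.seed(3)
  reps2 <- make_reps(logistic_curve(50, 0.25, 20), n = 3, sd = 1)
  gc2 <- group_mean_curve(reps2)
  for (j in seq_along(hours)) {
    vals <- vapply(reps2, function(r) r$values[j], 0)
    expect_equal(unname(gc2$mean[j]), mean(vals))
    expect_equal(unname(gc2$sd[j]), sd(vals))
  }
  expect_error(group_mean_curve(list(
    confluence_trace("A1", 0:1, c(1, 2)),
    confluence_trace("A2", c(0, 2), c(1, 2)))), "shared time grid")
})

test_that("delta versus control reproduces cohort magnitudes", {
  d <- delta_vs_control(63.2, 29.1)
  expect_equal(d$delta_points, 34.1, tolerance = 1e-12)
  expect_equal(d$delta_relative, 1.172, tolerance = 1e-3)
  d2 <- delta_vs_control(52.6, 35.9)
  expect_equal(d2$delta_points, 16.7, tolerance = 1e-12)
  expect_equal(d2$delta_relative, 0.465, tolerance = 1e-3)
  expect_equal(delta_vs_control(42, 42)$delta_relative, 0)
  expect_error(delta_vs_control(10, 0), "> 0")
})

test_that("pointwise Welch tests agree with stats::t.test and conventions", {
  same <- make_reps(rep(30, 5), n = 3, sd = 0, times = 0:4)
  st <- pointwise_tests(same, same)
  expect_equal(st$p_values, rep(1, 5))
  expect_equal(st$n_sig, 0)

  treated <- lapply(1:3, function(i)
    confluence_trace(paste0("T", i), 0:1, rep(59 + i, 2)))
  control <- lapply(1:3, function(i)
    confluence_trace(paste0("C", i), 0:1, rep(29 + i, 2)))
  st2 <- pointwise_tests(treated, control)
  expect_lt(st2$p_values[1], 0.001)
  # dual route: vectorized implementation vs stats::t.test per point
  ref <- t.test(c(60, 61, 62), c(30, 31, 32))$p.value
  expect_equal(st2$p_values[1], ref, tolerance = 1e-12)

  set.seed(21)
  a <- make_reps(logistic_curve(40, 0.2, 24), n = 4, sd = 2, seed = 5)
  b <- make_reps(logistic_curve(35, 0.2, 24), n = 3, sd = 2, seed = 6)
  st3 <- pointwise_tests(a, b)
  j <- 25
  ref3 <- t.test(vapply(a, function(r) r$values[j], 0),
                 vapply(b, function(r) r$values[j], 0))$p.value
  expect_equal(st3$p_values[j], ref3, tolerance = 1e-12)

  expect_error(pointwise_tests(treated[1], control), ">= 2")
})

test_that("the pointwise test is calibrated under the null", {
  rate <- welch_null_calibration(n_points = 10000, n_rep = 10, seed = 4)
  expect_gt(rate, 0.04)
  expect_lt(rate, 0.06)
})

test_that("divergence onset finds the first sustained qualifying run", {
  flat <- rep(20, 49)
  reps_t <- make_reps(flat, sd = 0.01, seed = 1)
  reps_c <- make_reps(flat, sd = 0.01, seed = 2)
  st <- pointwise_tests(reps_t, reps_c)
  expect_true(is.na(divergence_onset(flat, flat, st)))

  # step: relative difference jumps from 0 to 0.5 at t = 10
  base <- rep(20, 49)
  step <- ifelse(hours >= 10, 30, 20)
  rt <- make_reps(step, sd = 0.05, seed = 3)
  rc <- make_reps(base, sd = 0.05, seed = 4)
  st2 <- pointwise_tests(rt, rc)
  expect_equal(divergence_onset(step, base, st2), 10)

  # logistic pair with a growth boost from t = 10: onset within [10, 14];
  # oracle: brute-force scan of the qualifying rule
  mu_c <- logistic_curve(30, 0.35, 12)
  mu_t <- ifelse(hours < 10, mu_c, logistic_curve(55, 0.35, 14))
  rt2 <- make_reps(mu_t, sd = 0.05, seed = 7)
  rc2 <- make_reps(mu_c, sd = 0.05, seed = 8)
  st3 <- pointwise_tests(rt2, rc2)
  onset <- divergence_onset(mu_t, mu_c, st3)
  expect_gte(onset, 10); expect_lte(onset, 14)
  cfgk <- stip_config()$kinetics
  q <- abs(mu_t - mu_c) / mu_c >= cfgk$onset_rel &
    st3$p_values < st3$alpha & mu_c >= cfgk$onset_floor
  brute <- NA
  for (i in 1:(49 - 2)) if (all(q[i:(i + 2)])) { brute <- hours[i]; break }
  expect_equal(onset, brute)
})

test_that("sustained duration counts the longest qualifying run in hours", {
  flat <- rep(20, 49)
  rt <- make_reps(flat, sd = 0.01, seed = 1)
  rc <- make_reps(flat, sd = 0.01, seed = 2)
  st <- pointwise_tests(rt, rc)
  expect_equal(sustained_duration(flat, flat, st), 0)

  # constructed run of 28 consecutive qualifying points
  mu_c <- rep(20, 49)
  mu_t <- ifelse(hours >= 15 & hours <= 42, 30, 20)
  rt2 <- make_reps(mu_t, sd = 0.05, seed = 3)
  rc2 <- make_reps(mu_c, sd = 0.05, seed = 4)
  st2 <- pointwise_tests(rt2, rc2)
  expect_equal(sustained_duration(mu_t, mu_c, st2), 28)

  # alternating qualify/fail -> longest run is a single point
  mu_t3 <- ifelse(hours %% 2 == 0, 30, 20)
  rt3 <- make_reps(mu_t3, sd = 0.05, seed = 5)
  rc3 <- make_reps(mu_c, sd = 0.05, seed = 6)
  st3 <- pointwise_tests(rt3, rc3)
  expect_equal(sustained_duration(mu_t3, mu_c, st3), 1)
})

test_that("log-phase slope recovers exact lines and the logistic maximum", {
  line_up <- 5 + 1.0 * hours
  expect_equal(logphase_slope(hours, line_up), 1.0, tolerance = 1e-9)
  line_dn <- 100 - 2.5 * (0:20)
  expect_equal(logphase_slope(0:20, line_dn), -2.5, tolerance = 1e-9)
  # logistic K = 60, r = 0.2: max derivative K*r/4 = 3.0 %/h
  mu <- logistic_curve(60, 0.2, 24)
  sl <- logphase_slope(hours, mu)
  expect_equal(sl, 3.0, tolerance = 0.1 * 3.0)
  expect_error(logphase_slope(0:3, c(1, 2, 3, 4)), "window")
})

test_that("trapezoidal AUC is exact for polynomials and refines for smooth curves", {
  expect_equal(trapezoid_auc(hours, rep(50, 49)), 2400)
  expect_equal(trapezoid_auc(hours, hours), 1152)
  mu <- logistic_curve(60, 0.25, 20)
  fine_t <- seq(0, 48, by = 0.01)
  fine <- trapezoid_auc(fine_t, logistic_curve(60, 0.25, 20, fine_t))
  expect_lt(abs(trapezoid_auc(hours, mu) - fine) / fine, 0.005)
})

test_that("plateau window finds the quiet terminal stretch", {
  mu <- c(seq(5, 50, length.out = 39), rep(50, 10))  # flat from t = 38
  pw <- plateau_window(hours, mu)
  expect_equal(pw[1], 38, tolerance = 1)
  expect_equal(pw[2], 48)
  expect_null(plateau_window(hours, 5 + 1.0 * hours))
  expect_equal(plateau_window(hours, rep(42, 49)), c(0, 48))
})

test_that("intra-assay CV matches its definition and recovers generative CV", {
  expect_equal(intra_cv(c(50, 50, 50)), 0)
  expect_equal(intra_cv(c(48, 50, 52)), 4.0)
  expect_error(intra_cv(c(-3, 1)), "> 0")
  set.seed(9)
  finals <- 50 * exp(rnorm(1000, 0, 0.05))  # lognormal, CV ~ 5.006%
  expect_equal(intra_cv(finals), 100 * sqrt(exp(0.05^2) - 1), tolerance = 0.1)
})

test_that("kinetic profiles are invariant to replicate ordering", {
  mu_t <- logistic_curve(55, 0.25, 18)
  mu_c <- logistic_curve(35, 0.25, 20)
  rt <- make_reps(mu_t, sd = 1, seed = 31)
  rc <- make_reps(mu_c, sd = 1, seed = 32)
  p1 <- kinetic_profile(rt, rc, cell_line = "X")
  p2 <- kinetic_profile(rev(rt), rev(rc), cell_line = "X")
  for (f in c("final_confluence_mean", "delta_relative", "onset_hours",
              "logphase_slope", "auc", "divergence_duration", "intra_cv",
              "n_sig_points")) {
    expect_equal(p1[[f]], p2[[f]], info = f)
  }
})
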