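cfg_cl <- stip_config()$classifier

test_that("the printed cohort metrics reclassify to their printed categories", {
  profs <- stip_reference_profiles()
  ref <- stip_reference_cohort()
  got <- vapply(profs, kinetic_category, "", cfg = cfg_cl)
  expect_equal(unname(got[ref$cell_line]), ref$category)
})

test_that("the 10-20% band and weak responses are indeterminate, ties are active", {
  expect_equal(kinetic_category(profile_stub(0.15, duration = 20, n_sig = 10)),
               "indeterminate")
  # exactly at the class threshold: active (rule reads >=)
  expect_equal(kinetic_category(profile_stub(0.20, duration = 12, n_sig = 5)),
               "stimulatory")
  expect_equal(kinetic_category(profile_stub(-0.20, duration = 12, n_sig = 5)),
               "inhibitory")
  # large but brief change
  expect_equal(kinetic_category(profile_stub(0.5, duration = 6, n_sig = 10)),
               "indeterminate")
  # small change with many significant points is not neutral
  expect_equal(kinetic_category(profile_stub(0.02, duration = 0, n_sig = 9)),
               "indeterminate")
  expect_equal(kinetic_category(profile_stub(0.02, duration = 0, n_sig = 2)),
               "neutral")
})

test_that("every profile receives exactly one category", {
  set.seed(13)
  cats <- c("stimulatory", "inhibitory", "neutral", "indeterminate")
  for (i in 1:200) {
    p <- profile_stub(runif(1, -1.5, 1.5), duration = sample(0:48, 1),
                      n_sig = sample(0:49, 1))
    got <- kinetic_category(p)
    expect_length(got, 1)
    expect_true(got %in% cats)
  }
})

test_that("increasing delta never demotes a stimulatory call", {
  set.seed(14)
  for (i in 1:100) {
    dur <- sample(0:48, 1); nsig <- sample(0:49, 1)
    dr <- sort(runif(2, 0.0, 1.5))
    lo <- kinetic_category(profile_stub(dr[1], dur, nsig))
    hi <- kinetic_category(profile_stub(dr[2], dur, nsig))
    if (lo == "stimulatory") expect_equal(hi, "stimulatory")
  }
})

test_that("the death gate thresholds cumulative mortality correctly", {
  mk <- function(final) list(death_trace("A1", 0:48,
                                         final * (1 - exp(-(0:48) / 16)) /
                                           (1 - exp(-3))))
  g1 <- death_gate(mk(3.2))
  expect_equal(g1$status, "pass")
  expect_true(g1$positive)  # exceeded the 2.5% positivity threshold
  g2 <- death_gate(list(death_trace("A1", 0:48, rep(0, 49))))
  expect_equal(g2$status, "pass")
  expect_false(g2$positive)
  g3 <- death_gate(mk(7))
  expect_equal(g3$status, "cytotoxic")
})

test_that("cytotoxic death overrides any kinetics (gate precedence)", {
  set.seed(15)
  bad_death <- list(death_trace("A1", 0:48, seq(0, 8, length.out = 49)))
  for (dr in c(1.2, -0.5, 0.01, 0.15)) {
    call <- classify_stip(profile_stub(dr, duration = 30, n_sig = 20),
                          death = bad_death)
    expect_equal(call$category, "cytotoxic_confounded")
    expect_true(is.na(call$type))
  }
  ok_death <- list(death_trace("A1", 0:48, seq(0, 2.8, length.out = 49)))
  call2 <- classify_stip(profile_stub(-0.478, duration = 24, n_sig = 20),
                         death = ok_death)
  expect_equal(call2$category, "inhibitory")
  expect_equal(call2$type, "Type II")
  expect_equal(call2$evidence$death_gate$status, "pass")
})

test_that("secretome congruence follows the ratio bounds and is advisory", {
  mk_panel <- function(ifng, il10) data.frame(
    analyte = rep(c("IFN-gamma", "IL-10"), each = 3),
    concentration_pg_ml = c(ifng + c(-1, 0, 1), il10 + c(-0.5, 0, 0.5)),
    below_llod = FALSE)
  # measured inhibitory-group ratio 5.89 fails the strict > 6 bound
  expect_equal(secretome_congruence("inhibitory", mk_panel(83.6, 14.2), NULL),
               "incongruent")
  expect_equal(secretome_congruence("inhibitory", mk_panel(90, 10), NULL),
               "congruent")
  # stimulatory-group ratio 1.38 sits below the < 3 bound
  expect_equal(secretome_congruence("stimulatory", mk_panel(54.1, 39.2), NULL),
               "congruent")
  expect_equal(secretome_congruence("stimulatory", NULL, NULL), "not_assessed")
  # IL-10 at zero -> undefined ratio
  zero <- data.frame(analyte = rep(c("IFN-gamma", "IL-10"), each = 2),
                     concentration_pg_ml = c(50, 52, 0, 0),
                     below_llod = FALSE)
  expect_warning(out <- secretome_congruence("inhibitory", zero, NULL))
  expect_equal(out, "not_assessed")
  # neutral congruence: identical treated/control panels cannot differ
  pan <- mk_panel(47.5, 45.2)
  expect_equal(secretome_congruence("neutral", pan, pan), "congruent")
  # strongly shifted panel breaks neutral congruence
  expect_equal(secretome_congruence("neutral", mk_panel(200, 5), pan),
               "incongruent")
})
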