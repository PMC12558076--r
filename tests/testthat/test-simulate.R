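test_that("simulation_config validates its parameters", {
  expect_s3_class(simulation_config(), "simulation_config")
  expect_error(simulation_config(n_asymptomatic = 0), "n_asymptomatic")
  expect_error(simulation_config(prrt_fraction = 1.2), "prrt_fraction")
  expect_error(simulation_config(growth_sd = -1), "growth_sd")
  expect_error(simulation_config(location_probs = c(.5, .5, 0, 0, 0.1)),
               "location_probs")
  expect_error(generate_cohort(list(n_asymptomatic = -3)), "n_asymptomatic")
})

test_that("generate_cohort is deterministic and honours group sizes", {
  cfg <- simulation_config(seed = 123)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)
  expect_equal(sum(!a$patients$symptomatic_at_dx), 44L)
  expect_equal(sum(a$patients$symptomatic_at_dx), 10L)
  expect_equal(nrow(a$patients), 54L)
  # different seed, different draw
  expect_false(identical(
    a$lesions, generate_cohort(simulation_config(seed = 124))$lesions))
  # generator leaves the caller's RNG state untouched
  set.seed(42); before <- .Random.seed
  invisible(generate_cohort(cfg))
  expect_identical(before, .Random.seed)
})

test_that("generated tables pass input validation and the schema round-trips", {
  coh <- generate_cohort(simulation_config(seed = 9))
  val <- validate_inputs(coh$lesions, coh$patients)
  expect_true(val$ok)
  # every patient has >= 2 scans >= 2 months apart
  g <- estimate_growth(scans_to_volumes(coh$lesions))
  expect_equal(nrow(g), 54L)
  expect_true(all(g$interval_months >= 2))
  expect_equal(nrow(attr(g, "exclusions")), 0L)
})

test_that("noise-free degenerate growth round-trips exactly through the pipeline", {
  cfg <- simulation_config(seed = 5, diameter_noise_sd = 0, growth_sd = 0,
                           growth_mean = log(1.02), prrt_fraction = 0)
  coh <- generate_cohort(cfg)
  g <- estimate_growth(scans_to_volumes(coh$lesions))
  expect_equal(g$g_per_month, rep(log(1.02), 54), tolerance = 1e-10)
  expect_equal(g$tgr_pct_per_month, rep(2, 54), tolerance = 1e-8)
})

test_that("symmetric diameter noise does not bias median growth recovery", {
  cfg <- simulation_config(seed = 300, prrt_fraction = 0, growth_mean = 0,
                           n_asymptomatic = 200, n_symptomatic = 0)
  meds <- vapply(1:10, function(r) {
    cfg$seed <- 300 + r
    g <- estimate_growth(scans_to_volumes(generate_cohort(cfg)$lesions))
    median(g$g_per_month)
  }, numeric(1))
  # Monte-Carlo tolerance: SE of a median of n=200 draws with sd 0.04
  expect_lt(abs(median(meds)), 3 * 1.25 * 0.04 / sqrt(200))
})

test_that("10-year symptom-event fraction matches the exponential closed form", {
  lam <- -log(0.91) / 120
  cfg <- simulation_config(n_asymptomatic = 10000, n_symptomatic = 0,
                           seed = 42, symptom_hazard_growth_coef = 0,
                           death_hazard = 0, symptom_hazard_base = lam)
  frac <- mean(generate_cohort(cfg)$patients$symptom_surgery_event)
  expected <- 1 - exp(-120 * lam)
  se <- sqrt(expected * (1 - expected) / 10000)
  expect_lt(abs(frac - expected), 4 * se)
})

test_that("recovery_report tracks the generative targets", {
  cfg <- simulation_config(seed = 70)
  rep <- recovery_report(cfg, 10)
  expect_setequal(rep$parameter,
                  c("median_tgr_pct_per_month", "symptom_event_fraction",
                    "prrt_tgr_shift_pct_per_month"))
  expect_equal(rep$error, rep$median_estimate - rep$truth)
  # PRRT shift recovered with the right sign
  prrt <- rep[rep$parameter == "prrt_tgr_shift_pct_per_month", ]
  expect_lt(prrt$median_estimate, 0)
  # null growth -> median recovered TGR within Monte-Carlo error of zero
  cfg0 <- simulation_config(seed = 80, growth_mean = 0, prrt_fraction = 0)
  rep0 <- recovery_report(cfg0, 20)
  tgr0 <- rep0[rep0$parameter == "median_tgr_pct_per_month", ]
  expect_equal(tgr0$truth, 0)
  expect_lt(abs(tgr0$median_estimate), 0.5)
})
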