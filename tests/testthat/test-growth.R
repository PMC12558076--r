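test_that("growth_constant matches the exponential-model closed form", {
  expect_equal(growth_constant(1000, 1000, 12), 0)
  expect_equal(growth_constant(1000, 2000, 1), log(2), tolerance = 1e-12)
  expect_equal(growth_constant(2000, 1000, 10), log(0.5) / 10,
               tolerance = 1e-12)
  expect_equal(growth_constant(2000, 1000, 10), -0.06931, tolerance = 1e-4)
  expect_error(growth_constant(1000, 1000, 0), "interval")
  expect_error(growth_constant(-1, 1000, 2), "v1")
  expect_error(growth_constant(1000, 0, 2), "v2")
})

test_that("tumor_growth_rate back-transforms g to percent per month", {
  expect_equal(tumor_growth_rate(0), 0)
  expect_equal(tumor_growth_rate(log(2)), 100, tolerance = 1e-12)
  expect_equal(tumor_growth_rate(-0.06931), 100 * (exp(-0.06931) - 1),
               tolerance = 1e-12)
  expect_equal(tumor_growth_rate(-0.06931), -6.697, tolerance = 1e-3)
  expect_error(tumor_growth_rate(NA_real_), "finite")
  expect_error(tumor_growth_rate(Inf), "finite")
})

test_that("months_between uses the 30.4375-day month", {
  expect_equal(months_between("2015-01-01", "2015-01-01"), 0)
  expect_equal(months_between("2014-01-01", "2015-01-01"), 365 / 30.4375)
  # calendar span 2014-03-01 .. 2016-08-01 is 884 days (2016 is a leap year)
  expect_equal(months_between("2014-03-01", "2016-08-01"), 884 / 30.4375)
  expect_error(months_between("2015-06-01", "2015-01-01"), "precedes")
})

test_that("kinetics invariants hold across randomized inputs", {
  set.seed(99)
  for (i in 1:30) {
    v1 <- runif(1, 100, 50000)
    v2 <- runif(1, 100, 50000)
    t <- runif(1, 2, 80)
    k <- runif(1, 0.1, 10)
    g <- growth_constant(v1, v2, t)
    # scale invariance
    expect_equal(growth_constant(k * v1, k * v2, t), g, tolerance = 1e-10)
    # g <-> TGR inversion
    expect_equal(log(1 + tumor_growth_rate(g) / 100), g, tolerance = 1e-12)
    # time composition through an intermediate volume
    vm <- sqrt(v1 * v2) * runif(1, 0.5, 2)
    expect_equal((log(vm / v1) + log(v2 / vm)) / t, g, tolerance = 1e-10)
    # volumes -> TGR equals effective-diameter form 3*log(d2/d1)/t
    d1 <- (6 * v1 / pi)^(1 / 3)
    d2 <- (6 * v2 / pi)^(1 / 3)
    expect_equal(3 * log(d2 / d1) / t, g, tolerance = 1e-10)
  }
})

test_that("estimate_growth uses endpoint scans and the interval filter", {
  # three scans: baseline = first, follow-up = last, middle ignored
  les <- make_lesions(rep("A", 3),
                      c("2014-01-01", "2015-01-01", "2016-05-20"),
                      c(1000, 5000, 702))
  g <- estimate_growth(scans_to_volumes(les))
  expect_equal(nrow(g), 1L)
  expect_equal(g$v1_mm3, 1000, tolerance = 1e-9)
  expect_equal(g$v2_mm3, 702, tolerance = 1e-9)
  expect_equal(g$delta_v_mm3, -298, tolerance = 1e-9)
  t <- months_between("2014-01-01", "2016-05-20")
  expect_equal(g$interval_months, t)
  expect_equal(g$g_per_month, log(702 / 1000) / t, tolerance = 1e-12)
  expect_false(g$progressed)

  # 1.5-month interval -> excluded and reported
  short <- make_lesions(rep("B", 2), c("2015-01-01", "2015-02-15"),
                        c(1000, 1100))
  g2 <- estimate_growth(scans_to_volumes(short))
  expect_equal(nrow(g2), 0L)
  excl <- attr(g2, "exclusions")
  expect_equal(excl$patient_id, "B")
  expect_match(excl$reason, "below minimum")

  # single scan -> warning, not an error
  lone <- make_lesions("C", "2015-01-01", 1000)
  expect_warning(g3 <- estimate_growth(scans_to_volumes(lone)),
                 "fewer than two")
  expect_equal(attr(g3, "exclusions")$reason, "fewer than two scans")
})

test_that("estimate_growth round-trips a known growth constant exactly", {
  set.seed(3)
  for (i in 1:10) {
    v1 <- runif(1, 500, 20000)
    g_true <- runif(1, -0.05, 0.05)
    days <- sample(70:2000, 1)
    t <- days / 30.4375
    les <- make_lesions(rep("X", 2),
                        as.Date("2015-01-01") + c(0, days),
                        c(v1, v1 * exp(g_true * t)))
    est <- estimate_growth(scans_to_volumes(les))
    expect_equal(est$g_per_month, g_true, tolerance = 1e-12)
  }
})

test_that("progression is a strict volume increase", {
  d <- data.frame(delta_v_mm3 = c(1e-9, 0, -1e-9, 500, -298))
  expect_identical(classify_progression(d), c(TRUE, FALSE, FALSE, TRUE, FALSE))
  # equivalence with the tgr sign on an estimated cohort
  les <- rbind(make_lesions(rep("U", 2), c("2015-01-01", "2016-01-01"),
                            c(1000, 1250)),
               make_lesions(rep("D", 2), c("2015-01-01", "2016-01-01"),
                            c(1000, 930)))
  g <- estimate_growth(scans_to_volumes(les))
  expect_identical(g$progressed, g$tgr_pct_per_month > 0)
  expect_identical(g$progressed, g$delta_v_mm3 > 0)
})
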