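test_that("location_distribution counts, percentages and conservation", {
  lev <- c(rep("I", 13), rep("II", 12), rep("III_down", 16),
           rep("III_up", 2), rep("IV", 1))
  d <- make_patients(44, mlnm_level = lev)
  tab <- location_distribution(d)
  asym <- tab[tab$group == "asymptomatic", ]
  expect_equal(asym$count[asym$mlnm_level == "III_down"], 16L)
  expect_equal(asym$percent[asym$mlnm_level == "III_down"], 36)
  expect_equal(asym$percent[asym$mlnm_level == "I"], 30)
  expect_equal(sum(asym$count), 44L)
  # empty symptomatic group: zero counts, NA percentages
  sym <- tab[tab$group == "symptomatic", ]
  expect_equal(sum(sym$count), 0L)
  expect_true(all(is.na(sym$percent)))
  expect_error(location_distribution(make_patients(3, mlnm_level = "V")),
               "unknown")
})

test_that("location counts sum to group sizes on random cohorts", {
  set.seed(14)
  for (i in 1:5) {
    n <- sample(10:60, 1)
    d <- make_patients(n,
                       symptomatic = runif(n) < 0.3,
                       mlnm_level = sample(MLNM_LEVELS, n, TRUE))
    tab <- location_distribution(d)
    agg <- tapply(tab$count, tab$group, sum)
    expect_equal(unname(agg["asymptomatic"]), sum(!d$symptomatic_at_dx))
    expect_equal(unname(agg["symptomatic"]), sum(d$symptomatic_at_dx))
  }
})

test_that("symptom_onset_rate counts events among the asymptomatic", {
  d <- make_patients(44, symptom_surgery_event = c(rep(TRUE, 4),
                                                   rep(FALSE, 40)))
  r <- symptom_onset_rate(d)
  expect_equal(r, list(events = 4L, n = 44L, percent = 9))
  expect_equal(symptom_onset_rate(make_patients(10))$percent, 0)
  expect_equal(symptom_onset_rate(
    make_patients(10, symptom_surgery_event = TRUE))$percent, 100)
  expect_error(symptom_onset_rate(make_patients(5, symptomatic = TRUE)),
               "no asymptomatic")
})

test_that("prrt_comparison reports group kinetics with a Mann-Whitney p", {
  set.seed(9)
  n <- 44
  d <- make_patients(n, prrt_treated = c(rep(TRUE, 16), rep(FALSE, 28)))
  growth <- data.frame(
    patient_id = d$patient_id,
    v1_mm3 = 1000, v2_mm3 = 1000, interval_months = 29,
    delta_v_mm3 = c(rnorm(16, -562, 300), rnorm(28, -48, 300)),
    g_per_month = 0,
    tgr_pct_per_month = c(rnorm(16, -1.2, 1), rnorm(28, 0.04, 1)),
    progressed = FALSE, stringsAsFactors = FALSE)
  joined <- join_growth(d, growth)
  tab <- prrt_comparison(joined)
  expect_equal(tab$n_treated, c(16L, 16L))
  expect_equal(tab$n_untreated, c(28L, 28L))
  row_dv <- tab[tab$quantity == "delta_v_mm3", ]
  expect_lt(row_dv$treated_median, row_dv$untreated_median)
  # p matches calling mann_whitney directly
  expect_equal(row_dv$p_value,
               mann_whitney(growth$delta_v_mm3[1:16],
                            growth$delta_v_mm3[17:44])$p_value)
  expect_true(all(tab$treated_q1 <= tab$treated_median &
                    tab$treated_median <= tab$treated_q3))
})

test_that("summarize_baseline builds the grouped comparison table", {
  set.seed(10)
  n <- 54
  d <- make_patients(n, symptomatic = c(rep(FALSE, 44), rep(TRUE, 10)))
  d$age <- round(c(rnorm(44, 70, 5), rnorm(10, 63, 6)))
  d$sex <- sample(c("female", "male"), n, TRUE)
  d$grade <- sample(1:3, n, TRUE, prob = c(.4, .55, .05))
  d$ki67 <- rlnorm(n, log(4), 1)
  d$u5hiaa <- rlnorm(n, log(300), 1.5)
  d$death_event <- runif(n) < 0.55
  tab <- summarize_baseline(d)
  expect_setequal(tab$variable,
                  c("age_years", "sex_female", "deceased", "liver_mets",
                    "peritoneal_mets", "extraabdominal_mets",
                    "u5hiaa_umol_dl", "ki67_pct", "carcinoid_heart",
                    "grade_1_2_3"))
  expect_true(all(tab$p_value >= 0 & tab$p_value <= 1, na.rm = TRUE))
  # age p-value matches a direct Mann-Whitney
  expect_equal(tab$p_value[tab$variable == "age_years"],
               mann_whitney(d$age[1:44], d$age[45:54])$p_value)
  # sex row matches a direct Fisher test
  ka <- sum(d$sex[1:44] == "female"); ks <- sum(d$sex[45:54] == "female")
  expect_equal(tab$p_value[tab$variable == "sex_female"],
               fisher_exact_2x2(matrix(c(ka, 44 - ka, ks, 10 - ks), 2,
                                       byrow = TRUE)))
  # degenerate: no symptomatic patients must not error
  tab0 <- summarize_baseline(make_patients(20))
  expect_true(all(tab0$symptomatic %in% c("", paste(0, 0, 0, sep = "/"))))
})
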