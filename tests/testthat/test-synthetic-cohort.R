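# Synthetic cohort generator: marginal calibration, planted-effect recovery,
# matched sampling and missingness.

test_that("null planted effects give exchangeable cases and controls", {
  panel <- test_panel()
  beta0 <- setNames(rep(0, 8),
                    c("prs", "md", "e1s", "t", "prl", "alcohol",
                      "family_history", "bbd"))
  cfg <- generator_config(panel, planted_log_or = beta0, seed = 31)
  pop <- generate_population(cfg, 10000)
  for (col in c("md_percent", "bmi", "alcohol", "age_menarche")) {
    x1 <- pop[[col]][pop$is_case]
    x0 <- pop[[col]][!pop$is_case]
    pooled_se <- sqrt(var(x1) / length(x1) + var(x0) / length(x0))
    expect_lt(abs(mean(x1) - mean(x0)), 3 * pooled_se)
  }
  for (col in c("t_level", "e1s_level", "prl_level")) {
    x1 <- log(pop[[col]][pop$is_case])
    x0 <- log(pop[[col]][!pop$is_case])
    pooled_se <- sqrt(var(x1) / length(x1) + var(x0) / length(x0))
    expect_lt(abs(mean(x1) - mean(x0)), 3 * pooled_se)
  }
})

test_that("log-normal hormones hit the configured quantiles", {
  # closed form: p90 = median^2 / p10 by log-scale symmetry
  q <- bcriskaug:::lnorm_from_quantiles(562, 240)
  expect_equal(qlnorm(0.9, q$meanlog, q$sdlog), 562^2 / 240, tolerance = 1e-12)
  expect_equal(qlnorm(0.5, q$meanlog, q$sdlog), 562, tolerance = 1e-12)
  expect_equal(qlnorm(0.1, q$meanlog, q$sdlog), 240, tolerance = 1e-12)

  panel <- test_panel()
  cfg <- generator_config(panel, seed = 32)
  pop <- generate_population(cfg, 20000)
  ctrl <- pop[!pop$is_case, ]
  # control medians within 2 percent of configured
  expect_lt(abs(median(ctrl$e1s_level) / 562 - 1), 0.02)
  expect_lt(abs(median(ctrl$t_level) / 0.66 - 1), 0.02)
  expect_lt(abs(median(ctrl$prl_level) / 9.7 - 1), 0.02)
  # empirical control E1S 90th percentile near 1,316
  p90 <- quantile(ctrl$e1s_level, 0.9, names = FALSE)
  expect_lt(abs(p90 / 1316 - 1), 0.06)
  # MD control mean near 28.7, bounded support
  expect_lt(abs(mean(ctrl$md_percent) - 28.7), 1.0)
  expect_true(all(pop$md_percent >= 0 & pop$md_percent <= 100))
})

test_that("planted binary log OR is recovered by logistic regression", {
  panel <- test_panel()
  cfg <- generator_config(
    panel,
    planted_log_or = c(family_history = log(2)),
    seed = 33)
  pop <- generate_population(cfg, 50000)
  fit <- glm(is_case ~ family_history, binomial(), data = pop)
  or <- exp(coef(fit)[["family_historyTRUE"]])
  expect_gt(or, 1.8)
  expect_lt(or, 2.2)
})

test_that("generated records satisfy the structural invariants", {
  co <- shared_cohort()
  pop <- co$population
  expect_true(all(pop$age_at_draw >= 25 & pop$age_at_draw <= 75))
  expect_true(all(pop$t_level > 0 & pop$e1s_level > 0 & pop$prl_level > 0))
  # ht_use only among postmenopausal women
  expect_true(all(!pop$ht_use[pop$menopausal_status == "pre"]))
  # parity equals the number of recorded birth ages
  nb <- vapply(pop$birth_ages, function(s)
    length(bcriskaug:::parse_birth_ages(s)), numeric(1))
  expect_equal(nb, as.numeric(pop$parity), ignore_attr = TRUE)
  # ER status only assigned to cases
  expect_true(all(is.na(pop$er_status[!pop$is_case])))
  expect_true(all(!is.na(pop$er_status[pop$is_case])))
})

test_that("matched sampling obeys the design: ratio, constraints, no reuse", {
  co <- shared_cohort()
  ds <- co$dataset
  sets <- split(seq_len(nrow(ds)), ds$match_id)
  for (s in sets[1:200]) {
    case <- ds[s[ds$is_case[s]], ]
    ctrls <- ds[s[!ds$is_case[s]], ]
    expect_equal(nrow(case), 1)
    k_expected <- if (case$menopausal_status == "post" && !case$ht_use) 2 else 1
    expect_equal(nrow(ctrls), k_expected)
    expect_true(all(abs(ctrls$age_at_draw - case$age_at_draw) <= 1))
    expect_true(all(ctrls$menopausal_status == case$menopausal_status))
    expect_true(all(ctrls$ht_use == case$ht_use))
  }
  expect_false(anyDuplicated(ds$subject_id) > 0)
})

test_that("matching with no cases yields an empty dataset", {
  panel <- test_panel()
  cfg <- generator_config(panel, seed = 35)
  pop <- generate_population(cfg, 300)
  pop$is_case <- FALSE
  out <- sample_nested_case_control(pop, cfg)
  expect_equal(nrow(out), 0)
  expect_true("match_id" %in% names(out))
})

test_that("exhausted matching cells drop the case with a warning", {
  panel <- test_panel()
  cfg <- generator_config(panel, seed = 36)
  pop <- generate_population(cfg, 400)
  # remove all premenopausal controls so premenopausal cases cannot match
  pre_case <- pop$is_case & pop$menopausal_status == "pre"
  pop <- pop[pop$is_case | pop$menopausal_status == "post", , drop = FALSE]
  if (sum(pre_case) > 0) {
    expect_warning(out <- sample_nested_case_control(pop, cfg),
                   "matching cell exhausted")
    expect_gt(attr(out, "n_dropped"), 0)
  }
})

test_that("missingness rates are honoured (MCAR)", {
  df <- data.frame(age_at_draw = rnorm(10000, 52, 8),
                   t_level = rlnorm(10000))
  out0 <- apply_missingness(df, c(t_level = 0), seed = 5)
  expect_identical(out0$t_level, df$t_level)
  out1 <- apply_missingness(df, c(t_level = 1), seed = 5)
  expect_true(all(is.na(out1$t_level)))
  out <- apply_missingness(df, c(t_level = 0.4), seed = 5)
  expect_lt(abs(mean(is.na(out$t_level)) - 0.4), 0.015)
  # MAR-by-age variant keeps the approximate marginal rate
  outm <- apply_missingness(df, c(t_level = 0.4), seed = 5,
                            mechanism = "mar_age")
  expect_lt(abs(mean(is.na(outm$t_level)) - 0.4), 0.05)
})

test_that("identical config and seed reproduce the identical dataset", {
  panel <- test_panel()
  cfg <- generator_config(panel, seed = 77)
  pop1 <- generate_population(cfg, 2000)
  pop2 <- generate_population(cfg, 2000)
  expect_identical(pop1, pop2)
  ds1 <- sample_nested_case_control(pop1, cfg)
  ds2 <- sample_nested_case_control(pop2, cfg)
  expect_identical(ds1, ds2)
})

test_that("subject table CSV round-trips with empty-string missing values", {
  co <- shared_cohort()
  ds <- utils::head(co$dataset, 50)
  ds <- apply_missingness(ds, c(md_percent = 0.5), seed = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_subject_table(ds, path)
  raw <- readLines(path, n = 2)
  expect_match(raw[1], "^\"?subject_id")
  back <- read_subject_table(path)
  expect_equal(back$is_case, ds$is_case)
  expect_equal(back$md_percent, ds$md_percent, tolerance = 1e-8)
  expect_identical(is.na(back$md_percent), is.na(ds$md_percent))
})

test_that("planted log OR on an unparameterised covariate is rejected", {
  panel <- test_panel()
  expect_error(
    generator_config(panel, planted_log_or = c(coffee = 0.2), seed = 1),
    "no generated marginal")
})
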