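# PRS construction, Gail and Rosner-Colditz scores, quartile categorisation.

test_that("PRS is the genotype-weighted sum of log odds ratios", {
  panel <- snp_panel(c("rs1", "rs2"), c("A", "G"), c(0.3, 0.45), c(1.1, 1.2))
  expect_equal(compute_prs(c(0, 0), panel), 0)
  expect_equal(compute_prs(c(1, 2), panel), 1 * log(1.1) + 2 * log(1.2))
  expect_equal(compute_prs(c(1, 2), panel), 0.4599, tolerance = 2e-4)
  # missing genotype -> expected dosage 2 * freq
  panel2 <- snp_panel("rs1", "A", 0.25, 1.1)
  expect_equal(compute_prs(NA, panel2), 0.5 * log(1.1))
  expect_equal(round(compute_prs(NA, panel2), 5), 0.04766)
  expect_error(compute_prs(c(0, 1, 2), panel), "does not match panel size")
  expect_error(compute_prs(c(0, 3), panel), "risk-allele counts")
})

test_that("PRS is invariant to SNP order and to OR = 1 variants", {
  set.seed(41)
  panel <- test_panel(6)
  g <- matrix(sample(0:2, 10 * 6, TRUE), 10, 6)
  perm <- sample(6)
  panel_p <- snp_panel(panel$rsid[perm], panel$risk_allele[perm],
                       panel$risk_allele_freq[perm], panel$odds_ratio[perm])
  expect_equal(compute_prs(g, panel), compute_prs(g[, perm], panel_p))
  # appending a null-effect SNP changes nothing
  panel_null <- snp_panel(c(panel$rsid, "rs_null"),
                          c(panel$risk_allele, "A"),
                          c(panel$risk_allele_freq, 0.5),
                          c(panel$odds_ratio, 1.0))
  expect_equal(compute_prs(cbind(g, sample(0:2, 10, TRUE)), panel_null),
               compute_prs(g, panel))
})

test_that("standardisation gives mean 0, SD 1 with the population convention", {
  z <- standardize_prs(c(1, 2, 3))
  expect_equal(z, c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-12)
  expect_equal(round(z[3], 4), 1.2247)
  # idempotence
  expect_equal(standardize_prs(z), z, tolerance = 1e-12)
  expect_error(standardize_prs(rep(2, 10)), "zero variance")
  expect_error(standardize_prs(1), "at least 2")
})

test_that("modified Gail score: reference woman has RR 1, terms multiply", {
  ref <- reference_profile()
  expect_equal(compute_gail_rr(ref), 1.0)
  # single-term change exponentiates its coefficient (plus interaction)
  p_fh <- ref; p_fh$family_history <- TRUE
  spec <- read_model_spec(bcriskaug_extdata("gail_modified.json"))
  # with first birth < 20 the family-history interaction term is 0
  expect_equal(compute_gail_rr(p_fh, spec), exp(0.95830))
  # custom one-term spec: family history with coefficient ln 2 -> RR exactly 2
  tmp <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(
    model_name = "fh_only",
    terms = list(list(covariate = "family_history", transform = "binary",
                      coef = log(2)))), tmp, auto_unbox = TRUE, digits = NA)
  expect_equal(compute_gail_rr(p_fh, read_model_spec(tmp)), 2.0)
  # log-linearity: joint change equals the product of single changes
  p_men <- ref; p_men$age_menarche <- 11
  p_both <- p_fh; p_both$age_menarche <- 11
  expect_equal(compute_gail_rr(p_both, spec),
               compute_gail_rr(p_fh, spec) * compute_gail_rr(p_men, spec),
               tolerance = 1e-12)
})

test_that("Gail biopsy term interacts with age 50", {
  spec <- read_model_spec(bcriskaug_extdata("gail_modified.json"))
  p <- reference_profile(); p$n_biopsies <- 1
  expect_equal(log(compute_gail_rr(p, spec)), 0.52926)
  p$age_at_draw <- 55
  expect_equal(log(compute_gail_rr(p, spec)), 0.52926 - 0.28804)
})

test_that("missing required factors are reported by name", {
  p <- reference_profile()
  p$family_history <- NULL
  expect_error(compute_gail_rr(p), "family_history")
})

test_that("Rosner-Colditz-style score is linear and zero at reference", {
  # minimal spec: alcohol only, zero at 0 g/day, slope c per g/day
  tmp <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(
    model_name = "alc_only",
    terms = list(list(covariate = "alcohol", transform = "identity",
                      coef = 0.013))), tmp, auto_unbox = TRUE, digits = NA)
  spec <- read_model_spec(tmp)
  p0 <- data.frame(alcohol = 0)
  p10 <- data.frame(alcohol = 10)
  expect_equal(compute_rc_score(p0, spec), 0)
  expect_equal(compute_rc_score(p10, spec) - compute_rc_score(p0, spec),
               10 * 0.013, tolerance = 1e-12)
  # shipped spec: +10 g/day alcohol shifts the predictor by 10 * coef
  co <- shared_cohort()
  full <- read_model_spec(bcriskaug_extdata("rosner_colditz_simplified.json"))
  alc_coef <- Filter(function(tm) tm$covariate == "alcohol", full$terms)[[1]]$coef
  row <- co$dataset[1, ]
  row2 <- row; row2$alcohol <- row2$alcohol + 10
  expect_equal(compute_rc_score(row2, full) - compute_rc_score(row, full),
               10 * alc_coef, tolerance = 1e-10)
})

test_that("birth index accumulates woman-years up to menopause", {
  expect_equal(birth_index(c(25, 28), current_age = 40), 27)
  expect_equal(birth_index(numeric(0), current_age = 40), 0)
  # exposure stops at menopause
  expect_equal(birth_index(c(25, 28), current_age = 60, age_menopause = 50),
               (50 - 25) + (50 - 28))
  # births after the horizon contribute nothing
  expect_equal(birth_index(c(45), current_age = 60, age_menopause = 40), 0)
})

test_that("quartile categories use control type-7 cut points, left-closed", {
  ctrl <- 1:8
  # type-7 quartiles of 1..8 are 2.75 / 4.5 / 6.25
  expect_equal(quartile_categorize(8.5, ctrl), 4L)
  expect_equal(quartile_categorize(2.5, ctrl), 1L)   # 2.5 <= Q1 = 2.75
  expect_equal(quartile_categorize(4.5, ctrl), 2L)   # ties go down
  expect_equal(quartile_categorize(2.75, ctrl), 1L)
  expect_equal(quartile_categorize(c(1, 3, 5, 7), ctrl), 1:4)
  expect_true(all(is.na(quartile_categorize(NA_real_, ctrl))))
  expect_error(quartile_categorize(1, rep(5, 10)), "identical")
  expect_error(quartile_categorize(1, c(1, 2, 3)), "at least 4")
  # brute-force check against the declared convention on random data
  set.seed(42)
  for (i in 1:20) {
    cv <- rnorm(40)
    v <- rnorm(15)
    q <- quantile(cv, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    oracle <- vapply(v, function(x) sum(x > q) + 1, numeric(1))
    expect_equal(as.numeric(quartile_categorize(v, cv)), oracle)
  }
})

test_that("standardised PRS separates cases from controls as planted", {
  co <- shared_cohort()
  ds <- co$dataset
  gap <- mean(ds$prs[ds$is_case]) - mean(ds$prs[!ds$is_case])
  # planted separation is 0.34 SD
  expect_gt(gap, 0.34 - 3 * sqrt(2 / sum(ds$is_case)))
  expect_lt(gap, 0.34 + 3 * sqrt(2 / sum(ds$is_case)))
  expect_equal(mean(ds$prs), 0, tolerance = 1e-10)
  expect_equal(bcriskaug:::pop_sd(ds$prs), 1, tolerance = 1e-10)
})
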