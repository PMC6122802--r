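# AUC concordance, age-adjusted meta-analysis, delta-AUC, NRI, cross-validation.
# (The brute-force pairwise oracle lives in helper-oracles.R.)

test_that("concordance AUC equals the brute-force pairwise count", {
  expect_equal(auc_concordance(c(0.9, 0.4), c(0.7, 0.1))$auc, 3 / 4)
  expect_equal(auc_concordance(rep(1, 5), rep(1, 7))$auc, 0.5)
  expect_equal(auc_concordance(rep(1, 4), rep(0, 6))$auc, 1.0)
  set.seed(71)
  for (i in 1:200) {
    nc <- sample(1:25, 1)
    nn <- sample(1:25, 1)
    # discrete support forces ties
    cases <- sample(seq(0, 1, 0.1), nc, TRUE) + rbinom(nc, 1, 0.3) * 0.2
    controls <- sample(seq(0, 1, 0.1), nn, TRUE)
    expect_identical(auc_concordance(cases, controls)$auc,
                     auc_bruteforce(cases, controls))
  }
})

test_that("concordance AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(72)
  cases <- rnorm(80, 1)
  controls <- rnorm(120)
  a <- auc_concordance(cases, controls)$auc
  ref <- as.numeric(pROC::auc(
    response = c(rep(1, 80), rep(0, 120)),
    predictor = c(cases, controls), quiet = TRUE))
  expect_equal(a, ref, tolerance = 1e-12)
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(73)
  cases <- rnorm(40, 0.5)
  controls <- rnorm(60)
  a1 <- auc_concordance(cases, controls)$auc
  a2 <- auc_concordance(exp(cases), exp(controls))$auc
  expect_identical(a1, a2)
})

test_that("age-adjusted AUC is the inverse-variance stratum combination", {
  # constant stratum AUCs combine to the same value
  set.seed(74)
  age <- c(runif(300, 40, 45), runif(300, 55, 60))
  is_case <- rep(c(TRUE, FALSE), 300)
  # identical score configuration in both bands -> identical stratum AUCs
  scores <- rep(ifelse(is_case[1:300], rnorm(150, 1), rnorm(150)), 2)
  out <- age_adjusted_auc(scores, is_case, age)
  expect_equal(nrow(out$strata), 2)
  expect_equal(out$strata$auc[1], out$strata$auc[2])
  expect_equal(out$auc_x100, 100 * out$strata$auc[1], tolerance = 1e-10)
  # generic: combined value equals the weighted mean recomputed by hand
  st <- out$strata
  expect_equal(out$auc_x100,
               100 * sum(st$auc / st$variance) / sum(1 / st$variance))
  # hand-computed equal-weight combination: AUCs 0.6 and 0.8 -> 70
  w <- c(1, 1)
  expect_equal(sum(w * c(0.6, 0.8)) / sum(w), 0.7)
})

test_that("age adjustment removes an age-only effect", {
  set.seed(75)
  n <- 6000
  age <- runif(n, 35, 70)
  is_case <- runif(n) < plogis(-1.5 + 0.04 * (age - 50))
  # the risk score IS age: unadjusted discrimination is clearly above chance
  raw <- auc_concordance(age[is_case], age[!is_case])$auc
  expect_gt(raw * 100, 55)
  adj <- age_adjusted_auc(age, is_case, age)
  expect_gt(adj$auc_x100, 47)
  expect_lt(adj$auc_x100, 53)
})

test_that("delta AUC is zero under monotone transforms and null additions", {
  co <- shared_cohort()
  sub <- subgroup_subset(co$dataset, "postmeno_noHT")
  scores <- sub$gail_lp + 0.3 * sub$prs
  d0 <- delta_auc(scores, scores, sub$is_case, sub$age_at_draw,
                  n_boot = 100, seed = 2)
  expect_equal(d0$delta_x100, 0)
  expect_true(d0$ci95[1] <= 0 && d0$ci95[2] >= 0)
  # monotone transform: rank invariance makes the delta exactly zero
  d1 <- delta_auc(scores, exp(scores), sub$is_case, sub$age_at_draw,
                  n_boot = 100, seed = 2)
  expect_equal(d1$delta_x100, 0)
  expect_error(delta_auc(scores, scores, sub$is_case, sub$age_at_draw,
                         n_boot = 50), "at least 100")
})

test_that("adding a null biomarker does not move the AUC materially", {
  set.seed(76)
  reps <- 10
  ok <- 0
  panel <- test_panel()
  for (r in seq_len(reps)) {
    cfg <- generator_config(panel, baseline_logit = -0.7, seed = 300 + r)
    pop <- generate_population(cfg, 4500)
    pop <- score_dataset(pop, panel)
    pop$noise <- rnorm(nrow(pop))
    base <- fit_augmented_model(pop, "gail_lp", "prs", subgroup = "all")
    lp_b <- linear_predictor(base, pop)
    # augment with pure noise via a manual refit
    fit <- glm(is_case ~ lp_b + noise, binomial(), data = pop)
    lp_a <- predict(fit, type = "link")
    d <- age_adjusted_auc(lp_a, pop$is_case, pop$age_at_draw)$auc_x100 -
      age_adjusted_auc(lp_b, pop$is_case, pop$age_at_draw)$auc_x100
    if (abs(d) < 1.0) ok <- ok + 1
  }
  expect_gte(ok, 9)
})

test_that("NRI counts movers across the risk threshold", {
  out <- nri(old_risks = c(0.01, 0.01, 0.03, 0.03, 0.01),
             new_risks = c(0.03, 0.01, 0.03, 0.01, 0.01),
             outcomes = c(TRUE, TRUE, TRUE, FALSE, FALSE))
  expect_equal(out$case_component, 1 / 3)
  expect_equal(out$control_component, 1 / 2)
  expect_equal(out$total, 5 / 6)
  # new = old -> exactly zero
  r <- runif(50, 0, 0.1)
  oc <- rep(c(TRUE, FALSE), 25)
  expect_equal(nri(r, r, oc)$total, 0)
  expect_error(nri(r, r, rep(TRUE, 50)), "both cases")
  expect_error(nri(c(1.2, r[-1]), r, oc), "\\[0, 1\\]")
})

test_that("NRI components match a contingency-table oracle", {
  set.seed(77)
  for (i in 1:25) {
    n <- 200
    old <- runif(n, 0, 0.06)
    new <- pmin(pmax(old + rnorm(n, 0, 0.01), 0), 1)
    oc <- runif(n) < 0.4
    out <- nri(old, new, oc)
    thr <- out$threshold
    tab1 <- table(factor(old[oc] >= thr, c(FALSE, TRUE)),
                  factor(new[oc] >= thr, c(FALSE, TRUE)))
    tab0 <- table(factor(old[!oc] >= thr, c(FALSE, TRUE)),
                  factor(new[!oc] >= thr, c(FALSE, TRUE)))
    expect_equal(out$case_component,
                 (tab1["FALSE", "TRUE"] - tab1["TRUE", "FALSE"]) / sum(tab1))
    expect_equal(out$control_component,
                 (tab0["TRUE", "FALSE"] - tab0["FALSE", "TRUE"]) / sum(tab0))
  }
})

test_that("cross-validation is deterministic and near-null for noise scores", {
  co <- shared_cohort()
  ds <- co$dataset
  cv1 <- cross_validate(ds, "gail_lp", c("prs", "md"),
                        subgroup = "all", k = 5, seed = 21)
  cv2 <- cross_validate(ds, "gail_lp", c("prs", "md"),
                        subgroup = "all", k = 5, seed = 21)
  expect_identical(cv1, cv2)
  expect_gt(cv1$train_delta_x100, 0)
  # a pure-noise "biomarker" adds nothing out of sample
  set.seed(22)
  ds$md_percent <- runif(nrow(ds), 1, 99)  # noise replaces MD
  cv0 <- cross_validate(ds, "gail_lp", "md", subgroup = "all", k = 5,
                        seed = 23)
  expect_lt(abs(cv0$validation_delta_x100), 2)
  expect_error(cross_validate(ds, "gail_lp", "md", k = 1), "at least 2")
})
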