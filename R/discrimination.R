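# Discrimination statistics: pairwise-concordance AUC with stratum variance,
# age-adjusted AUC by fixed-effect inverse-variance meta-analysis of
# age-stratum AUCs, bootstrap delta-AUC inference, two-category net
# reclassification improvement, and k-fold cross-validation.

# Rank-based AUC: P(case score > control score) + 0.5 * P(tie).
auc_rank <- function(case_scores, control_scores) {
  nc <- length(case_scores)
  nn <- length(control_scores)
  r <- rank(c(case_scores, control_scores), ties.method = "average")
  (sum(r[seq_len(nc)]) - nc * (nc + 1) / 2) / (nc * nn)
}

# Hanley-McNeil variance of an AUC estimate. A is clipped away from 0/1 for
# the variance computation only, so perfectly separated strata still receive
# a finite (small) variance rather than an infinite meta-analysis weight.
hanley_variance <- function(auc, nc, nn) {
  eps <- 0.5 / (nc * nn)
  a <- min(max(auc, eps), 1 - eps)
  q1 <- a / (2 - a)
  q2 <- 2 * a^2 / (1 + a)
  (a * (1 - a) + (nc - 1) * (q1 - a^2) + (nn - 1) * (q2 - a^2)) / (nc * nn)
}

# DeLong variance via placement values.
delong_variance <- function(case_scores, control_scores) {
  nc <- length(case_scores)
  nn <- length(control_scores)
  # placement of each case among controls and vice versa
  v10 <- vapply(case_scores, function(s)
    mean((s > control_scores) + 0.5 * (s == control_scores)), numeric(1))
  v01 <- vapply(control_scores, function(s)
    mean((case_scores > s) + 0.5 * (case_scores == s)), numeric(1))
  s10 <- if (nc > 1) stats::var(v10) else 0
  s01 <- if (nn > 1) stats::var(v01) else 0
  s10 / nc + s01 / nn
}

#' AUC over all case-control score pairs
#'
#' Estimates `P(case score > control score) + 0.5 * P(tie)` (the
#' concordance / Mann-Whitney form of the AUC) with a sampling variance by the
#' Hanley-McNeil estimator (default) or DeLong's method.
#'
#' @param case_scores,control_scores numeric score vectors (each non-empty).
#' @param variance `"hanley"` or `"delong"`.
#' @return An object of class `stratum_auc`: list with `auc`, `variance`,
#'   `n_case`, `n_control`.
#' @export
#' @examples
#' auc_concordance(c(0.9, 0.4), c(0.7, 0.1))  # 3 of 4 pairs concordant
auc_concordance <- function(case_scores, control_scores,
                            variance = c("hanley", "delong")) {
  variance <- match.arg(variance)
  case_scores <- case_scores[!is.na(case_scores)]
  control_scores <- control_scores[!is.na(control_scores)]
  if (!length(case_scores) || !length(control_scores)) {
    stop("need at least one case and one control score", call. = FALSE)
  }
  a <- auc_rank(case_scores, control_scores)
  v <- if (variance == "hanley") {
    hanley_variance(a, length(case_scores), length(control_scores))
  } else {
    max(delong_variance(case_scores, control_scores),
        hanley_variance(a, length(case_scores), length(control_scores)) * 1e-6)
  }
  structure(list(auc = a, variance = v, n_case = length(case_scores),
                 n_control = length(control_scores)),
            class = "stratum_auc")
}

#' @export
print.stratum_auc <- function(x, ...) {
  cat(sprintf("AUC = %.4f (SE %.4f; %d cases / %d controls)\n",
              x$auc, sqrt(x$variance), x$n_case, x$n_control))
  invisible(x)
}

#' Age-adjusted AUC by meta-analysis of age-stratum AUCs
#'
#' Computes the AUC separately within each age band and combines the stratum
#' estimates by fixed-effect inverse-variance weighting, removing age's
#' contribution to discrimination (appropriate for age-matched case-control
#' data). Strata lacking cases or controls are excluded with a message. The
#' combined AUC is reported multiplied by 100.
#'
#' @param scores numeric risk scores.
#' @param is_case logical case indicator, same length.
#' @param age ages in years, same length.
#' @param bands age bands (see [default_age_bands()]).
#' @param variance stratum variance estimator, `"hanley"` or `"delong"`.
#' @param scale `"auc"` (default) combines on the AUC scale; `"logit"`
#'   meta-analyses logit-transformed stratum AUCs and back-transforms.
#' @return An object of class `auc_summary`: `auc_x100`, `ci95` (length 2),
#'   `variance_x100sq`, and a per-stratum data frame `strata`.
#' @export
age_adjusted_auc <- function(scores, is_case, age, bands = default_age_bands(),
                             variance = c("hanley", "delong"),
                             scale = c("auc", "logit")) {
  variance <- match.arg(variance)
  scale <- match.arg(scale)
  stopifnot(length(scores) == length(is_case), length(scores) == length(age))
  band <- age_band(age, bands)
  strata <- list()
  for (b in levels(band)) {
    idx <- which(band == b)
    cs <- scores[idx][is_case[idx]]
    ns <- scores[idx][!is_case[idx]]
    if (!length(cs) || !length(ns)) {
      if (length(idx)) message("age band ", b, " excluded: only one group")
      next
    }
    s <- auc_concordance(cs, ns, variance)
    strata[[b]] <- data.frame(stratum = b, auc = s$auc, variance = s$variance,
                              n_case = s$n_case, n_control = s$n_control,
                              stringsAsFactors = FALSE)
  }
  if (!length(strata)) stop("no age stratum contains both cases and controls",
                            call. = FALSE)
  st <- do.call(rbind, strata)
  rownames(st) <- NULL
  if (scale == "auc") {
    w <- 1 / st$variance
    combined <- sum(w * st$auc) / sum(w)
    v <- 1 / sum(w)
  } else {
    eps <- 1e-6
    la <- logit(pmin(pmax(st$auc, eps), 1 - eps))
    lv <- st$variance / (st$auc * (1 - st$auc))^2
    w <- 1 / lv
    lcomb <- sum(w * la) / sum(w)
    lvar <- 1 / sum(w)
    combined <- inv_logit(lcomb)
    # delta-method back-transform of the variance
    v <- lvar * (combined * (1 - combined))^2
  }
  ci <- pmin(pmax(100 * (combined + c(-1.96, 1.96) * sqrt(v)), 0), 100)
  structure(list(auc_x100 = 100 * combined, ci95 = ci,
                 variance_x100sq = 1e4 * v, strata = st, scale = scale),
            class = "auc_summary")
}

#' @export
print.auc_summary <- function(x, ...) {
  cat(sprintf("Age-adjusted AUC = %.1f (95%% CI %.1f-%.1f), %d age strata\n",
              x$auc_x100, x$ci95[1], x$ci95[2], nrow(x$strata)))
  invisible(x)
}

#' Change in age-adjusted AUC with bootstrap inference
#'
#' Point estimate: difference of the age-adjusted AUCs of two score vectors on
#' the same subjects. Confidence interval and p-value come from a stratified
#' paired bootstrap: within every age band, cases and controls are resampled
#' with replacement and both scores are carried along, preserving the
#' within-subject pairing and the age-matched structure.
#'
#' @param scores_base,scores_augmented score vectors on identical subjects.
#' @param is_case logical case indicator.
#' @param age ages in years.
#' @param bands age bands.
#' @param n_boot bootstrap replicates (at least 100).
#' @param seed integer seed.
#' @param variance stratum AUC variance estimator.
#' @return An object of class `delta_auc`: `delta_x100`, `ci95`, `p_value`,
#'   plus the two `auc_summary` objects.
#' @export
delta_auc <- function(scores_base, scores_augmented, is_case, age,
                      bands = default_age_bands(), n_boot = 1000, seed = 1,
                      variance = c("hanley", "delong")) {
  variance <- match.arg(variance)
  if (n_boot < 100) stop("n_boot must be at least 100", call. = FALSE)
  stopifnot(length(scores_base) == length(scores_augmented))
  base <- age_adjusted_auc(scores_base, is_case, age, bands, variance)
  aug <- age_adjusted_auc(scores_augmented, is_case, age, bands, variance)
  point <- aug$auc_x100 - base$auc_x100

  band <- age_band(age, bands)
  cells <- list()
  for (b in levels(band)) {
    ic <- which(band == b & is_case)
    in_ <- which(band == b & !is_case)
    if (length(ic) && length(in_)) cells[[b]] <- list(case = ic, ctrl = in_)
  }
  set.seed(stage_seed(seed, "delta_auc_boot"))
  boot <- numeric(n_boot)
  for (r in seq_len(n_boot)) {
    num_b <- den_b <- num_a <- den_a <- 0
    for (cell in cells) {
      ci <- cell$case[sample.int(length(cell$case), replace = TRUE)]
      ni <- cell$ctrl[sample.int(length(cell$ctrl), replace = TRUE)]
      ab <- auc_rank(scores_base[ci], scores_base[ni])
      aa <- auc_rank(scores_augmented[ci], scores_augmented[ni])
      vb <- hanley_variance(ab, length(ci), length(ni))
      va <- hanley_variance(aa, length(ci), length(ni))
      num_b <- num_b + ab / vb; den_b <- den_b + 1 / vb
      num_a <- num_a + aa / va; den_a <- den_a + 1 / va
    }
    boot[r] <- 100 * (num_a / den_a - num_b / den_b)
  }
  ci95 <- unname(stats::quantile(boot, c(0.025, 0.975), type = 7))
  sd_b <- stats::sd(boot)
  p <- if (sd_b > 0) 2 * stats::pnorm(-abs(point) / sd_b) else
    as.numeric(point == 0)
  structure(list(delta_x100 = point, ci95 = ci95, p_value = p,
                 auc_base = base, auc_augmented = aug, n_boot = n_boot),
            class = "delta_auc")
}

#' @export
print.delta_auc <- function(x, ...) {
  cat(sprintf(
    "AUC %.1f -> %.1f; change %.1f (95%% CI %.1f-%.1f), p = %.3g [%d bootstrap]\n",
    x$auc_base$auc_x100, x$auc_augmented$auc_x100, x$delta_x100,
    x$ci95[1], x$ci95[2], x$p_value, x$n_boot))
  invisible(x)
}

#' Two-category net reclassification improvement
#'
#' With a single absolute-risk cutoff (default 2.27 percent, twice the
#' population-average 5-year risk), the NRI is the net proportion of cases
#' reclassified upward by the new model plus the net proportion of non-cases
#' reclassified downward. The confidence interval uses the asymptotic variance
#' of the two components.
#'
#' @param old_risks,new_risks absolute risks in `[0, 1]` from the old and new
#'   model, same subjects.
#' @param outcomes logical (or 0/1) case indicator.
#' @param threshold risk cutoff defining the high-risk category.
#' @return An object of class `nri_result`: `case_component`,
#'   `control_component`, `total`, `ci95`, `threshold`.
#' @export
#' @examples
#' nri(old_risks = c(0.01, 0.01, 0.03, 0.03, 0.01),
#'     new_risks = c(0.03, 0.01, 0.03, 0.01, 0.01),
#'     outcomes = c(TRUE, TRUE, TRUE, FALSE, FALSE))
nri <- function(old_risks, new_risks, outcomes,
                threshold = threshold_twice_average_risk) {
  outcomes <- as.logical(outcomes)
  if (any(old_risks < 0 | old_risks > 1 | new_risks < 0 | new_risks > 1,
          na.rm = TRUE)) {
    stop("risks must lie in [0, 1]", call. = FALSE)
  }
  if (!any(outcomes) || all(outcomes)) {
    stop("need both cases and non-cases", call. = FALSE)
  }
  hi_old <- old_risks >= threshold
  hi_new <- new_risks >= threshold
  up <- hi_new & !hi_old
  down <- !hi_new & hi_old
  n1 <- sum(outcomes)
  n0 <- sum(!outcomes)
  p_up1 <- mean(up[outcomes]);   p_dn1 <- mean(down[outcomes])
  p_up0 <- mean(up[!outcomes]);  p_dn0 <- mean(down[!outcomes])
  case_comp <- p_up1 - p_dn1
  ctrl_comp <- p_dn0 - p_up0
  v1 <- (p_up1 + p_dn1 - case_comp^2) / n1
  v0 <- (p_up0 + p_dn0 - ctrl_comp^2) / n0
  total <- case_comp + ctrl_comp
  ci <- total + c(-1.96, 1.96) * sqrt(v1 + v0)
  structure(list(case_component = case_comp, control_component = ctrl_comp,
                 total = total, ci95 = ci, threshold = threshold,
                 n_case = n1, n_control = n0),
            class = "nri_result")
}

#' @export
print.nri_result <- function(x, ...) {
  cat(sprintf(
    "NRI = %.3f (95%% CI %.3f-%.3f) at %.2f%%: cases %+0.3f, non-cases %+0.3f\n",
    x$total, x$ci95[1], x$ci95[2], 100 * x$threshold,
    x$case_component, x$control_component))
  invisible(x)
}

#' k-fold cross-validated change in age-adjusted AUC
#'
#' Assesses over-fitting of the augmented model: folds are stratified on case
#' status and age band; in each fold the base and augmented logistic models
#' are fitted on the remaining k-1 folds and the change in age-adjusted AUC is
#' evaluated on both the training and the held-out fold. Similar training and
#' validation changes indicate little over-fitting.
#'
#' @param dataset subject data frame (post-imputation).
#' @param base_score base score column name.
#' @param biomarkers biomarkers to add, as in [fit_augmented_model()].
#' @param subgroup analysis subgroup.
#' @param k number of folds (>= 2).
#' @param seed integer seed; identical seed gives identical fold assignment.
#' @param bands age bands.
#' @return List with `train_delta_x100`, `validation_delta_x100` (means across
#'   folds) and a per-fold data frame `folds`.
#' @export
cross_validate <- function(dataset, base_score, biomarkers, subgroup = "all",
                           k = 10, seed = 1, bands = default_age_bands()) {
  if (k < 2) stop("k must be at least 2", call. = FALSE)
  check_biomarker_policy(subgroup, biomarkers)
  dd <- subgroup_subset(dataset, subgroup)
  dd <- augment_design(dd, base_score, biomarkers)
  vars <- c(".base", paste0(".bm_", biomarkers, recycle0 = TRUE))
  dd <- dd[stats::complete.cases(dd[, c("is_case", "age_at_draw", vars)]), ,
           drop = FALSE]
  set.seed(stage_seed(seed, "cv_folds"))
  band <- age_band(dd$age_at_draw, bands)
  fold <- integer(nrow(dd))
  for (cell in split(seq_len(nrow(dd)), list(dd$is_case, band), drop = TRUE)) {
    fold[cell[sample.int(length(cell))]] <-
      rep_len(sample.int(k), length(cell))
  }
  if (any(tapply(dd$is_case, fold, sum) == 0)) {
    stop("a fold contains no cases; reduce k or enlarge the dataset",
         call. = FALSE)
  }
  res <- data.frame(fold = seq_len(k), train_delta = NA_real_,
                    validation_delta = NA_real_)
  for (f in seq_len(k)) {
    tr <- dd[fold != f, , drop = FALSE]
    te <- dd[fold == f, , drop = FALSE]
    m_base <- fit_augmented_model(tr, base_score, character(0),
                                  subgroup = "all", bands = bands)
    m_aug <- fit_augmented_model(tr, base_score, biomarkers,
                                 subgroup = "all", bands = bands)
    for (part in c("train", "validation")) {
      pd <- if (part == "train") tr else te
      lp_b <- linear_predictor(m_base, pd)
      lp_a <- linear_predictor(m_aug, pd)
      d <- age_adjusted_auc(lp_a, pd$is_case, pd$age_at_draw, bands)$auc_x100 -
        age_adjusted_auc(lp_b, pd$is_case, pd$age_at_draw, bands)$auc_x100
      res[[paste0(part, "_delta")]][f] <- d
    }
  }
  list(train_delta_x100 = mean(res$train_delta),
       validation_delta_x100 = mean(res$validation_delta),
       folds = res)
}
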