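# Age-adjusted unconditional logistic augmentation of a base risk score with
# continuous biomarkers, per menopausal/HT subgroup, and exposure odds ratios.

biomarker_columns <- list(
  prs = list(col = "prs", scale = "identity", label = "PRS"),
  md = list(col = "md_percent", scale = "identity", label = "MD"),
  t = list(col = "t_level", scale = "log", label = "T"),
  e1s = list(col = "e1s_level", scale = "log", label = "E1S"),
  prl = list(col = "prl_level", scale = "log", label = "PRL")
)

# Hormone policy: which hormones may enter the model in each subgroup.
# Hormone-breast cancer associations differ by menopausal status and HT use,
# so hormones are evaluated only in the relevant subgroups.
allowed_hormones <- list(
  premeno = character(0),
  postmeno_noHT = c("t", "e1s", "prl"),
  postmeno_HT = "prl",
  all = c("t", "e1s", "prl")
)

#' Check a subgroup's biomarker policy
#'
#' Hormones may be added only where they are informative: testosterone,
#' estrone sulfate and prolactin for postmenopausal women not using hormone
#' therapy (and in the pooled all-women analysis); prolactin only for
#' postmenopausal women using hormone therapy; no hormones for premenopausal
#' women. PRS and MD are allowed everywhere.
#'
#' @param subgroup one of `"premeno"`, `"postmeno_noHT"`, `"postmeno_HT"`,
#'   `"all"`.
#' @param biomarkers character vector drawn from
#'   `c("prs", "md", "t", "e1s", "prl")`.
#' @return Invisibly `TRUE`; errors on a policy violation.
#' @export
check_biomarker_policy <- function(subgroup, biomarkers) {
  subgroup <- match.arg(subgroup, c("premeno", "postmeno_noHT", "postmeno_HT",
                                    "all"))
  unknown <- setdiff(biomarkers, names(biomarker_columns))
  if (length(unknown)) {
    stop("unknown biomarker(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  hormones <- intersect(biomarkers, c("t", "e1s", "prl"))
  bad <- setdiff(hormones, allowed_hormones[[subgroup]])
  if (length(bad)) {
    stop("policy violation: hormone(s) ", paste(bad, collapse = ", "),
         " not evaluated in subgroup '", subgroup, "'", call. = FALSE)
  }
  invisible(TRUE)
}

#' Subset a dataset to an analysis subgroup
#'
#' @param dataset subject data frame with `menopausal_status` and `ht_use`.
#' @param subgroup `"premeno"`, `"postmeno_noHT"`, `"postmeno_HT"` or `"all"`.
#' @return The subgroup rows.
#' @export
subgroup_subset <- function(dataset, subgroup) {
  subgroup <- match.arg(subgroup, c("premeno", "postmeno_noHT", "postmeno_HT",
                                    "all"))
  switch(subgroup,
         all = dataset,
         premeno = dataset[dataset$menopausal_status == "pre", , drop = FALSE],
         postmeno_noHT = dataset[dataset$menopausal_status == "post" &
                                   !dataset$ht_use, , drop = FALSE],
         postmeno_HT = dataset[dataset$menopausal_status == "post" &
                                 dataset$ht_use, , drop = FALSE])
}

#' Restrict to estrogen-receptor-positive cases
#'
#' Drops cases whose ER status is negative or unknown; keeps every control.
#'
#' @param dataset subject data frame with `is_case` and `er_status`.
#' @return The restricted data frame.
#' @export
restrict_er_positive <- function(dataset) {
  keep <- !dataset$is_case |
    (!is.na(dataset$er_status) & dataset$er_status == "positive")
  dataset[keep, , drop = FALSE]
}

# Build the derived design columns used by augmented models: `.base` for the
# base score and `.bm_<name>` per biomarker (hormones log-transformed).
augment_design <- function(dataset, base_score, biomarkers) {
  if (!is.null(base_score)) {
    if (!base_score %in% names(dataset)) {
      stop("no base score column named '", base_score, "'", call. = FALSE)
    }
    dataset$.base <- dataset[[base_score]]
  }
  for (bm in biomarkers) {
    info <- biomarker_columns[[bm]]
    if (!info$col %in% names(dataset)) {
      stop("missing biomarker column '", info$col, "'", call. = FALSE)
    }
    v <- dataset[[info$col]]
    if (info$scale == "log") {
      if (any(v <= 0, na.rm = TRUE)) {
        stop("non-positive values in ", info$col, " cannot be log-transformed",
             call. = FALSE)
      }
      v <- log(v)
    }
    dataset[[paste0(".bm_", bm)]] <- v
  }
  dataset
}

#' Fit an age-adjusted augmented logistic model
#'
#' Unconditional logistic regression of case status on a base risk score, age
#' (entered as 5-year band indicators) and the requested continuous
#' biomarkers; hormones are log-transformed. The subgroup's hormone policy is
#' enforced. Perfectly collinear biomarker terms are dropped with a warning;
#' non-convergence or apparent separation is an error.
#'
#' @param dataset subject data frame (post-imputation) with an `is_case`
#'   column.
#' @param base_score name of the base score column (e.g. a Gail log relative
#'   risk or a Rosner-Colditz linear predictor), or `NULL` for a
#'   biomarkers-plus-age model.
#' @param biomarkers character vector among `c("prs","md","t","e1s","prl")`.
#' @param subgroup analysis subgroup; the data are subset accordingly.
#' @param er_positive_only restrict cases to ER-positive tumors.
#' @param bands age bands for the age adjustment, see [default_age_bands()].
#' @return An object of class `augmented_model` with the fitted `glm`, a
#'   coefficient table (`term`, `beta`, `se`), counts and the log-likelihood.
#' @export
fit_augmented_model <- function(dataset, base_score, biomarkers = character(0),
                                subgroup = "all", er_positive_only = FALSE,
                                bands = default_age_bands()) {
  check_biomarker_policy(subgroup, biomarkers)
  dd <- subgroup_subset(dataset, subgroup)
  if (er_positive_only) dd <- restrict_er_positive(dd)
  dd <- augment_design(dd, base_score, biomarkers)
  vars <- c(if (!is.null(base_score)) ".base",
            paste0(".bm_", biomarkers, recycle0 = TRUE))
  dd$.ageband <- droplevels(age_band(dd$age_at_draw, bands))
  use <- stats::complete.cases(dd[, c("is_case", vars), drop = FALSE])
  dd <- dd[use, , drop = FALSE]
  if (!any(dd$is_case) || all(dd$is_case)) {
    stop("subgroup '", subgroup, "' needs both cases and controls",
         call. = FALSE)
  }
  rhs <- c(vars, if (nlevels(dd$.ageband) > 1) ".ageband")
  fml <- stats::reformulate(rhs, response = "is_case")
  fit <- stats::glm(fml, family = stats::binomial(), data = dd)
  if (!fit$converged) {
    stop("logistic fit did not converge (subgroup ", subgroup, ", n=",
         nrow(dd), ")", call. = FALSE)
  }
  cf <- stats::coef(fit)
  dropped <- names(cf)[is.na(cf)]
  if (length(dropped)) {
    warning("dropped aliased (collinear) term(s): ",
            paste(dropped, collapse = ", "), call. = FALSE)
  }
  cf_ok <- cf[!is.na(cf)]
  se <- sqrt(diag(stats::vcov(fit)))[names(cf_ok)]
  # separation check on the substantive terms only; a sparse age-band
  # indicator may legitimately blow up without harming the risk ordering
  subst <- names(cf_ok) %in% vars
  if (any(abs(cf_ok[subst]) > 15 & se[subst] > 10)) {
    bad <- names(cf_ok)[subst][abs(cf_ok[subst]) > 15 & se[subst] > 10]
    stop("apparent separation: |coefficient| > 15 with huge SE for ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  coef_table <- data.frame(term = names(cf_ok), beta = unname(cf_ok),
                           se = unname(se), stringsAsFactors = FALSE)
  structure(
    list(subgroup = subgroup, base_score = base_score, biomarkers = biomarkers,
         fit = fit, coefficients = coef_table,
         n_case = sum(dd$is_case), n_control = sum(!dd$is_case),
         loglik = as.numeric(stats::logLik(fit)), converged = fit$converged,
         dropped = dropped, bands = bands),
    class = "augmented_model"
  )
}

#' @export
print.augmented_model <- function(x, ...) {
  cat("Augmented logistic model [", x$subgroup, "]: ",
      if (is.null(x$base_score)) "(no base score)" else x$base_score,
      if (length(x$biomarkers)) paste(" +", paste(x$biomarkers, collapse = " + "))
      else "", "\n", sep = "")
  cat("  n =", x$n_case, "cases /", x$n_control, "controls; logLik =",
      format(x$loglik, digits = 6), "\n")
  bm <- x$coefficients[grepl("^\\.(base|bm_)", x$coefficients$term), ]
  if (nrow(bm)) {
    bm$term <- sub("^\\.bm_", "", sub("^\\.base$", x$base_score %||% "base",
                                      bm$term))
    print(format(bm, digits = 4), row.names = FALSE)
  }
  invisible(x)
}

#' Linear predictor of an augmented model on new subjects
#'
#' @param model an [fit_augmented_model()] object.
#' @param newdata subject data frame; must contain every model covariate
#'   (post-imputation) without missing values.
#' @return Numeric vector of linear predictors (log-odds scale).
#' @export
linear_predictor <- function(model, newdata) {
  stopifnot(inherits(model, "augmented_model"))
  dd <- augment_design(newdata, model$base_score, model$biomarkers)
  vars <- c(if (!is.null(model$base_score)) ".base",
            paste0(".bm_", model$biomarkers, recycle0 = TRUE))
  if (".ageband" %in% colnames(model$fit$model)) {
    dd$.ageband <- factor(age_band(dd$age_at_draw, model$bands),
                          levels = levels(model$fit$model$.ageband))
    if (anyNA(dd$.ageband)) {
      stop("newdata contains ages outside the fitted age bands", call. = FALSE)
    }
  }
  if (anyNA(dd[, vars, drop = FALSE])) {
    stop("missing covariate value(s) in newdata", call. = FALSE)
  }
  lp <- stats::predict(model$fit, newdata = dd, type = "link")
  unname(lp)
}

#' Exposure odds ratios with 95 percent confidence intervals
#'
#' Unconditional logistic regression of case status on a single exposure,
#' adjusting for the matching factors (age bands, menopausal status, hormone
#' therapy use). The exposure enters either continuously - standardised per
#' control SD on its analysis scale (hormones log-transformed) - or as
#' quartile categories cut at the control distribution's quartiles (odds
#' ratios for Q2-Q4 versus Q1).
#'
#' @param dataset subject data frame.
#' @param exposure a biomarker name (`"prs"`, `"md"`, `"t"`, `"e1s"`, `"prl"`)
#'   or any numeric column name.
#' @param form `"continuous"` or `"control_quartiles"`.
#' @param subgroup analysis subgroup (default all women).
#' @return A data frame of class `or_table` with columns `term`, `or`,
#'   `ci_lo`, `ci_hi`, `beta`, `se`.
#' @export
fit_relative_risks <- function(dataset, exposure,
                               form = c("continuous", "control_quartiles"),
                               subgroup = "all") {
  form <- match.arg(form)
  dd <- subgroup_subset(dataset, subgroup)
  if (exposure %in% names(biomarker_columns)) {
    dd <- augment_design(dd, NULL, exposure)
    x <- dd[[paste0(".bm_", exposure)]]
  } else {
    if (!exposure %in% names(dataset)) {
      stop("no exposure column named '", exposure, "'", call. = FALSE)
    }
    x <- dd[[exposure]]
  }
  ok <- !is.na(x)
  dd <- dd[ok, , drop = FALSE]
  x <- x[ok]
  dd$.ageband <- droplevels(age_band(dd$age_at_draw))
  adj <- c(if (nlevels(dd$.ageband) > 1) ".ageband",
           if (length(unique(dd$menopausal_status)) > 1) "menopausal_status",
           if (length(unique(dd$ht_use)) > 1) "ht_use")

  if (form == "continuous") {
    ux <- sort(unique(x))
    binary <- length(ux) == 2 && all(ux %in% c(0, 1))
    if (binary) {
      dd$.x <- x  # binary exposure: OR per unit, no standardisation
      term_label <- "exposed vs unexposed"
    } else {
      ctrl <- x[!dd$is_case]
      s <- stats::sd(ctrl)
      if (!is.finite(s) || s == 0) stop("degenerate exposure in controls",
                                        call. = FALSE)
      dd$.x <- (x - mean(ctrl)) / s
      term_label <- "per control SD"
    }
    fml <- stats::reformulate(c(".x", adj), response = "is_case")
    fit <- stats::glm(fml, family = stats::binomial(), data = dd)
    b <- stats::coef(fit)[".x"]
    se <- sqrt(diag(stats::vcov(fit)))[".x"]
    out <- data.frame(term = term_label, or = exp(b),
                      ci_lo = exp(b - 1.96 * se), ci_hi = exp(b + 1.96 * se),
                      beta = unname(b), se = unname(se),
                      stringsAsFactors = FALSE)
  } else {
    cat4 <- quartile_categorize(x, x[!dd$is_case])
    tab <- table(dd$is_case, cat4)
    if (ncol(tab) < 4 || any(tab == 0)) {
      stop("empty quartile cell: cannot estimate quartile odds ratios",
           call. = FALSE)
    }
    dd$.q <- factor(cat4, levels = 1:4)
    fml <- stats::reformulate(c(".q", adj), response = "is_case")
    fit <- stats::glm(fml, family = stats::binomial(), data = dd)
    idx <- paste0(".q", 2:4)
    b <- stats::coef(fit)[idx]
    se <- sqrt(diag(stats::vcov(fit)))[idx]
    out <- data.frame(term = paste0("Q", 2:4, " vs Q1"), or = exp(b),
                      ci_lo = exp(b - 1.96 * se), ci_hi = exp(b + 1.96 * se),
                      beta = unname(b), se = unname(se),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out$n_case <- sum(dd$is_case)
  out$n_control <- sum(!dd$is_case)
  class(out) <- c("or_table", "data.frame")
  out
}

#' @export
print.or_table <- function(x, ...) {
  cat("Odds ratios (", x$n_case[1], "cases /", x$n_control[1], "controls )\n")
  df <- data.frame(term = x$term,
                   OR = sprintf("%.2f", x$or),
                   `95% CI` = sprintf("(%.2f-%.2f)", x$ci_lo, x$ci_hi),
                   check.names = FALSE)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Export augmented-model coefficients
#'
#' Writes a coefficient table (subgroup x model x term x beta x SE) as CSV
#' and JSON for audit, in the shape of a supplementary beta-coefficient table.
#'
#' @param models list of [fit_augmented_model()] objects.
#' @param path_csv,path_json output paths (either may be `NULL` to skip).
#' @return The combined coefficient data frame, invisibly.
#' @export
export_coefficients <- function(models, path_csv = NULL, path_json = NULL) {
  rows <- lapply(models, function(m) {
    ct <- m$coefficients
    ct$term <- sub("^\\.bm_", "", sub("^\\.base$",
                                      m$base_score %||% "base", ct$term))
    data.frame(subgroup = m$subgroup,
               model = paste(c(m$base_score %||% "none", m$biomarkers),
                             collapse = "+"),
               term = ct$term, beta = ct$beta, se = ct$se,
               n_case = m$n_case, n_control = m$n_control,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(path_csv)) utils::write.csv(out, path_csv, row.names = FALSE)
  if (!is.null(path_json)) {
    jsonlite::write_json(out, path_json, auto_unbox = TRUE, digits = NA)
  }
  invisible(out)
}
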