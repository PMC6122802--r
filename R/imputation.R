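# Stochastic regression imputation of missing biomarkers.
#
# Missing mammographic density and hormone values are filled from an ordinary
# least squares fit on the measured subset (outcome transformed: hormones on
# the log scale, MD on the logit of the percent), with normal residual error
# added to every predicted value so the imputed values carry the residual
# spread of the measured data rather than collapsing onto the regression line.

#' Fit a biomarker imputation model on the measured subset
#'
#' Ordinary least squares of the transformed outcome (log for hormones,
#' logit of percent/100 for mammographic density) on the given predictors,
#' using only subjects with a measured outcome. Case status belongs among the
#' predictors so that imputed values preserve case-control differences.
#'
#' @param dataset subject data frame.
#' @param outcome name of the biomarker column (`"md_percent"`, `"t_level"`,
#'   `"e1s_level"` or `"prl_level"`).
#' @param predictors character vector of predictor columns; defaults to age,
#'   BMI, menopausal status, hormone therapy use, case status, alcohol and
#'   parity. The set is configuration, not a package constant.
#' @param transform `"log"` or `"logit_percent"`; chosen automatically from
#'   the outcome name if not given.
#' @return An object of class `imputation_model` holding the fitted `lm`, the
#'   coefficient vector and the residual standard deviation.
#' @export
fit_imputation_model <- function(dataset, outcome,
                                 predictors = c("age_at_draw", "bmi",
                                                "menopausal_status", "ht_use",
                                                "is_case", "alcohol", "parity"),
                                 transform = NULL) {
  if (!outcome %in% names(dataset)) {
    stop("no column named '", outcome, "'", call. = FALSE)
  }
  if (is.null(transform)) {
    transform <- if (outcome == "md_percent") "logit_percent" else "log"
  }
  transform <- match.arg(transform, c("log", "logit_percent"))
  miss <- setdiff(predictors, names(dataset))
  if (length(miss)) {
    stop("missing predictor column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  measured <- !is.na(dataset[[outcome]])
  if (sum(measured) < 30) {
    stop("need at least 30 measured values to fit an imputation model ",
         "(have ", sum(measured), ")", call. = FALSE)
  }
  dd <- dataset[measured, c(outcome, predictors), drop = FALSE]
  if (anyNA(dd[predictors])) {
    stop("predictors must be complete on the measured subset", call. = FALSE)
  }
  y <- if (transform == "log") {
    if (any(dd[[outcome]] <= 0)) stop("log transform needs positive values",
                                      call. = FALSE)
    log(dd[[outcome]])
  } else {
    p <- dd[[outcome]] / 100
    if (any(p <= 0 | p >= 1)) p <- pmin(pmax(p, 1e-4), 1 - 1e-4)
    logit(p)
  }
  dd$.y <- y
  fml <- stats::reformulate(predictors, response = ".y")
  fit <- stats::lm(fml, data = dd)
  cf <- stats::coef(fit)
  if (anyNA(cf)) {
    stop("singular design; collinear term(s): ",
         paste(names(cf)[is.na(cf)], collapse = ", "), call. = FALSE)
  }
  structure(
    list(outcome = outcome, predictors = predictors, transform = transform,
         fit = fit, coefficients = cf,
         residual_sd = stats::sigma(fit), n_measured = sum(measured)),
    class = "imputation_model"
  )
}

#' @export
print.imputation_model <- function(x, ...) {
  cat("Imputation model for", x$outcome, "(", x$transform, "scale )\n")
  cat("  fitted on", x$n_measured, "measured subjects; residual SD =",
      format(x$residual_sd, digits = 4), "\n")
  cat("  predictors:", paste(x$predictors, collapse = ", "), "\n")
  invisible(x)
}

#' Serialise an imputation model to JSON for audit
#'
#' @param model an [fit_imputation_model()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_imputation_model <- function(model, path) {
  stopifnot(inherits(model, "imputation_model"))
  jsonlite::write_json(
    list(outcome = model$outcome, transform = model$transform,
         predictors = model$predictors,
         coefficients = as.list(model$coefficients),
         residual_sd = model$residual_sd, n_measured = model$n_measured),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Impute missing biomarker values with stochastic residual error
#'
#' Each missing value is filled with the back-transformed sum of the linear
#' prediction and a normal error draw with the model's residual standard
#' deviation. Measured values are never overwritten. A logical
#' `<outcome>_imputed` column records which values were filled. Subjects with
#' an incomplete predictor set are left missing with a message.
#'
#' @param dataset subject data frame.
#' @param model an [fit_imputation_model()] object.
#' @param seed integer seed; the same seed reproduces the same filled values.
#' @return The dataset with filled values and the imputation flag column.
#' @export
impute_missing <- function(dataset, model, seed) {
  stopifnot(inherits(model, "imputation_model"))
  outcome <- model$outcome
  flag_col <- paste0(outcome, "_imputed")
  dataset[[flag_col]] <- FALSE
  todo <- which(is.na(dataset[[outcome]]))
  if (!length(todo)) return(dataset)
  pred_ok <- stats::complete.cases(dataset[todo, model$predictors, drop = FALSE])
  if (any(!pred_ok)) {
    message(sum(!pred_ok), " subject(s) left missing for ", outcome,
            ": incomplete predictors")
  }
  todo <- todo[pred_ok]
  if (!length(todo)) return(dataset)
  set.seed(stage_seed(seed, paste0("impute_", outcome)))
  mu <- stats::predict(model$fit, newdata = dataset[todo, , drop = FALSE])
  eps <- stats::rnorm(length(todo), 0, model$residual_sd)
  filled <- if (model$transform == "log") {
    exp(mu + eps)
  } else {
    100 * inv_logit(mu + eps)
  }
  dataset[[outcome]][todo] <- filled
  dataset[[flag_col]][todo] <- TRUE
  dataset
}
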