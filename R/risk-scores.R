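# Relative-risk scores: modified Gail score and a simplified
# Rosner-Colditz-style log-incidence score, both driven by coefficient files
# (the coefficients are data, not code).

# ---- covariate transform registry -------------------------------------------

# Each transform maps the subject data frame to a numeric design column.
# Transforms that need more than one field (birth index, menopausal
# durations) read the full row.
transform_registry <- list(
  identity = function(df, cov, params) df[[cov]],
  binary = function(df, cov, params) as.numeric(as.logical(df[[cov]])),
  center = function(df, cov, params) df[[cov]] - params$center,
  log_center = function(df, cov, params) log(df[[cov]]) - log(params$center),
  age_ge_50 = function(df, cov, params) as.numeric(df[[cov]] >= 50),
  # Gail category codings
  gail_menarche_cat = function(df, cov, params) {
    x <- df[[cov]]
    ifelse(x >= 14, 0, ifelse(x >= 12, 1, 2))
  },
  gail_biopsy_cat = function(df, cov, params) pmin(df[[cov]], 2),
  gail_ageflb_cat = function(df, cov, params) {
    x <- df[[cov]]
    ifelse(is.na(x), 2,  # nulliparous coded with the 25-29 category
           ifelse(x < 20, 0, ifelse(x < 25, 1, ifelse(x < 30, 2, 3))))
  },
  # Rosner-Colditz reproductive-timeline terms
  birth_index = function(df, cov, params) {
    end <- pmin(df$age_at_draw,
                ifelse(is.na(df$age_menopause), Inf, df$age_menopause))
    vapply(seq_len(nrow(df)), function(i) {
      ba <- parse_birth_ages(df$birth_ages[i])
      if (!length(ba)) return(0)
      sum(pmax(end[i] - ba, 0))
    }, numeric(1))
  },
  premeno_duration = function(df, cov, params) {
    end <- pmin(df$age_at_draw,
                ifelse(is.na(df$age_menopause), Inf, df$age_menopause))
    pmax(end - df$age_menarche, 0)
  },
  postmeno_duration = function(df, cov, params) {
    ifelse(df$menopausal_status == "post" & !is.na(df$age_menopause),
           pmax(df$age_at_draw - df$age_menopause, 0), 0)
  }
)

needs_fields <- list(
  birth_index = c("birth_ages", "age_at_draw", "age_menopause"),
  premeno_duration = c("age_at_draw", "age_menopause", "age_menarche"),
  postmeno_duration = c("menopausal_status", "age_menopause", "age_at_draw")
)

eval_transform <- function(df, covariate, transform, params = NULL) {
  fn <- transform_registry[[transform]]
  if (is.null(fn)) stop("unknown transform '", transform, "'", call. = FALSE)
  need <- needs_fields[[transform]]
  if (is.null(need)) need <- covariate
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("missing required factor(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  fn(df, covariate, params)
}

# ---- model specifications ---------------------------------------------------

#' Read a risk model specification from JSON
#'
#' A risk model specification maps transformed covariates to log relative risk
#' coefficients. The package ships two: `gail_modified.json` (the modified Gail
#' score with binary family history and no atypical-hyperplasia term, using the
#' published category coefficients) and `rosner_colditz_simplified.json` (a
#' simplified log-incidence score with illustrative default coefficients; the
#' exact published functional forms live in prior literature and are exposed
#' here as configurable transforms).
#'
#' @param path path to a JSON file with fields `model_name`, `terms`
#'   (list of `{covariate, transform, coef, params?, condition?}`) and
#'   optional `interactions` (list of `{covariates, transforms, coef}`).
#' @return An object of class `risk_model_spec`.
#' @export
#' @examples
#' spec <- read_model_spec(bcriskaug_extdata("gail_modified.json"))
#' spec$model_name
read_model_spec <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  if (is.null(raw$model_name) || is.null(raw$terms)) {
    stop("model spec needs 'model_name' and 'terms'", call. = FALSE)
  }
  for (tm in raw$terms) {
    if (is.null(tm$covariate) || is.null(tm$transform) || is.null(tm$coef)) {
      stop("each term needs covariate, transform and coef", call. = FALSE)
    }
    if (is.null(transform_registry[[tm$transform]])) {
      stop("term uses unknown transform '", tm$transform, "'", call. = FALSE)
    }
  }
  structure(list(model_name = raw$model_name, terms = raw$terms,
                 interactions = raw$interactions %||% list()),
            class = "risk_model_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.risk_model_spec <- function(x, ...) {
  cat("Risk model spec '", x$model_name, "': ", length(x$terms), " terms, ",
      length(x$interactions), " interactions\n", sep = "")
  for (tm in x$terms) {
    cat(sprintf("  %-18s %-18s coef=%+.5f%s\n", tm$covariate, tm$transform,
                tm$coef,
                if (!is.null(tm$condition)) paste0(" [", tm$condition, "]") else ""))
  }
  invisible(x)
}

# Evaluate the linear predictor of a spec over a subject data frame.
model_linear_predictor <- function(df, spec) {
  stopifnot(inherits(spec, "risk_model_spec"))
  lp <- numeric(nrow(df))
  for (tm in spec$terms) {
    v <- eval_transform(df, tm$covariate, tm$transform, tm$params)
    if (!is.null(tm$condition)) {
      if (tm$condition == "postmenopausal") {
        v <- v * as.numeric(df$menopausal_status == "post")
      } else stop("unknown term condition '", tm$condition, "'", call. = FALSE)
    }
    lp <- lp + tm$coef * v
  }
  for (ia in spec$interactions) {
    v <- rep(1, nrow(df))
    for (j in seq_along(ia$covariates)) {
      v <- v * eval_transform(df, ia$covariates[[j]], ia$transforms[[j]], NULL)
    }
    lp <- lp + ia$coef * v
  }
  lp
}

#' Modified Gail relative risk
#'
#' Computes the relative risk `exp(linear predictor)` of the modified Gail
#' score: categorical age at menarche, number of breast biopsies (with an
#' age-at-least-50 interaction), age at first birth (with a family-history
#' interaction) and binary family history. The reference woman (menarche at 14
#' or later, no biopsies, first birth before 20, no family history) has
#' relative risk 1.
#'
#' @param profile data frame of subjects (one or more rows) with the fields
#'   `age_menarche`, `n_biopsies`, `age_first_birth`, `family_history`,
#'   `age_at_draw`.
#' @param spec a [read_model_spec()] object; defaults to the shipped modified
#'   Gail coefficients.
#' @return Numeric vector of relative risks.
#' @export
#' @examples
#' ref <- data.frame(age_menarche = 14, n_biopsies = 0, age_first_birth = 19,
#'                   family_history = FALSE, age_at_draw = 45)
#' compute_gail_rr(ref)  # 1
compute_gail_rr <- function(profile,
                            spec = read_model_spec(
                              bcriskaug_extdata("gail_modified.json"))) {
  exp(model_linear_predictor(profile, spec))
}

#' Simplified Rosner-Colditz-style log-incidence score
#'
#' Returns the linear predictor of a simplified Rosner-Colditz-style model:
#' age at menarche, birth index, family history, benign breast disease
#' history, premenopausal and postmenopausal durations, hormone therapy use,
#' BMI (postmenopausal), height and alcohol intake. Coefficients come from the
#' spec file and are user configuration, not package constants. All factors at
#' their reference values give 0.
#'
#' @param profile data frame of subjects.
#' @param spec a [read_model_spec()]; defaults to the shipped simplified
#'   coefficient file.
#' @return Numeric vector of log-incidence linear predictors.
#' @export
compute_rc_score <- function(profile,
                             spec = read_model_spec(
                               bcriskaug_extdata("rosner_colditz_simplified.json"))) {
  model_linear_predictor(profile, spec)
}

#' Birth index: cumulative woman-years of exposure since each birth
#'
#' Defined here as the sum over live births of the years elapsed from the
#' birth to the earlier of the current age and the age at menopause. This is
#' one concrete reading of a "combination of number of children and birth
#' spacing"; it is isolated in this function so an alternative convention can
#' be swapped in.
#'
#' @param birth_ages numeric vector of ages at each birth.
#' @param current_age age at evaluation.
#' @param age_menopause age at menopause, or `NA` if premenopausal.
#' @return A single non-negative number of woman-years.
#' @export
#' @examples
#' birth_index(c(25, 28), current_age = 40)  # (40-25) + (40-28) = 27
birth_index <- function(birth_ages, current_age, age_menopause = NA) {
  end <- min(current_age, if (is.na(age_menopause)) Inf else age_menopause)
  if (!length(birth_ages)) return(0)
  sum(pmax(end - birth_ages, 0))
}

#' Quartile categories from the control distribution
#'
#' Cut points are the 25th, 50th and 75th percentiles of the control values
#' (type-7 linear interpolation). Categories are left-closed: a value equal to
#' a cut point falls in the lower category.
#'
#' @param values numeric vector to categorise (cases and controls alike).
#' @param control_values numeric control-only values defining the cut points.
#' @return Integer categories in `{1, 2, 3, 4}`; `NA` values stay `NA`.
#' @export
#' @examples
#' quartile_categorize(c(2.5, 8.5), control_values = 1:8)
quartile_categorize <- function(values, control_values) {
  cv <- control_values[!is.na(control_values)]
  if (length(cv) < 4) stop("need at least 4 non-missing control values",
                           call. = FALSE)
  q <- stats::quantile(cv, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  if (q[1] == q[3]) stop("control values are (nearly) all identical: ",
                         "quartile cut points degenerate", call. = FALSE)
  out <- 1L + (values > q[1]) + (values > q[2]) + (values > q[3])
  as.integer(out)
}
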