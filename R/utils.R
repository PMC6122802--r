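# Internal helpers shared across modules.

logit <- function(p) log(p / (1 - p))

inv_logit <- function(x) stats::plogis(x)

# Population (n-denominator) standard deviation.
pop_sd <- function(x) {
  x <- x[!is.na(x)]
  sqrt(mean((x - mean(x))^2))
}

#' Derive a per-stage random seed from a root seed
#'
#' All stochastic stages of the pipeline draw their seed deterministically from
#' a single root seed and a stage label, so that an identical configuration and
#' root seed reproduce an identical run while stages remain independent.
#'
#' @param root integer root seed.
#' @param stage character stage label (e.g. `"generate"`, `"impute"`).
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @export
#' @examples
#' stage_seed(42, "generate")
stage_seed <- function(root, stage) {
  stopifnot(is.numeric(root), length(root) == 1, is.character(stage))
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(root) * 69069 + h * 2654435) %% (2^31 - 1))
}

# Truncated normal draws by inverse CDF (exact, vectorised).
rnorm_trunc <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  pl <- stats::pnorm(lower, mean, sd)
  pu <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, pl, pu), mean, sd)
}

# Log-normal parameterised by median and 10th percentile.
# p90 = median^2 / p10 follows from the symmetry of the normal on the log scale.
lnorm_from_quantiles <- function(median, p10) {
  stopifnot(median > 0, p10 > 0, p10 < median)
  meanlog <- log(median)
  sdlog <- (log(median) - log(p10)) / stats::qnorm(0.9)
  list(meanlog = meanlog, sdlog = sdlog)
}

#' Absolute 5-year risk threshold: twice the population average
#'
#' The general-population average 5-year risk of invasive breast cancer is
#' about 1.135 percent, so twice the average is 2.27 percent. Reclassification
#' analyses use this single cutoff (at or above 2.27 percent versus below) to
#' define the high-risk category.
#'
#' @format A length-one numeric, `0.0227`.
#' @export
threshold_twice_average_risk <- 0.0227

#' Default five-year age bands
#'
#' Age bands used for age-stratified AUC computation, fold stratification and
#' age adjustment in logistic models: under 40, then 5-year bands to 65 and
#' over.
#'
#' @return A list with `breaks` (numeric, for [base::cut()]) and `labels`.
#' @export
#' @examples
#' default_age_bands()$labels
default_age_bands <- function() {
  list(
    breaks = c(-Inf, 40, 45, 50, 55, 60, 65, Inf),
    labels = c("<40", "40-44", "45-49", "50-54", "55-59", "60-64", "65+")
  )
}

# Cut ages into bands; returns a factor.
age_band <- function(age, bands = default_age_bands()) {
  cut(age, breaks = bands$breaks, labels = bands$labels, right = FALSE)
}

#' Path to a file shipped with the package
#'
#' Convenience wrapper around [base::system.file()] for the plain-text
#' configuration and reference files under `extdata/`.
#'
#' @param name file name under `extdata/`.
#' @return Absolute path to the file.
#' @export
#' @examples
#' bcriskaug_extdata("gail_modified.json")
bcriskaug_extdata <- function(name) {
  path <- system.file("extdata", name, package = "bcriskaug")
  if (!nzchar(path)) stop("no extdata file named '", name, "'", call. = FALSE)
  path
}
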