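# Synthetic source population and nested case-control sampling.
#
# The generator emulates the marginal structure of a cohort of middle-aged
# women (ages 25-75) with questionnaire risk factors, genotypes at a panel of
# independent breast-cancer SNPs, percent mammographic density, and three
# circulating hormones, and assigns incident invasive disease from a
# multiplicative (logistic) risk model with configurable planted effects.

default_marginal_params <- function() {
  list(
    age = list(mean = 52, sd = 8, min = 25, max = 75),
    age_menarche = list(mean = 12.5, sd = 1.4, min = 9, max = 17),
    age_menopause = list(mean = 51.1, sd = 4.5, min = 38, max = 60),
    prob_parous = 0.94,
    parity_probs = c(`1` = 0.15, `2` = 0.40, `3` = 0.30, `4` = 0.15),
    age_first_birth = list(mean = 25.5, sd = 3.7, min = 16, max = 40),
    birth_spacing_mean = 2.5,
    family_history_prev = 0.11,
    bbd_prev = 0.42,
    bmi = list(mean = 25.5, sd = 4.5, min = 16, max = 55),
    height = list(mean = 164, sd = 6, min = 140, max = 190),
    alcohol = list(prob_drinker = 0.55, meanlog = log(5), sdlog = 1),
    prob_ht_given_post = 0.53,
    # hormone marginals in controls: median and 10th percentile, log-normal
    e1s = list(median = 562, p10 = 240),    # pmol/l
    t = list(median = 0.66, p10 = 0.34),    # nmol/l
    prl = list(median = 9.7, p10 = 5.5),    # ug/l
    # percent mammographic density: logit-normal, location/scale of the latent
    # normal chosen so the control mean is ~28.7 percent (sd ~16.4)
    md = list(mu = -1.0615, sigma = 0.9),
    # NULL = menopausal status follows age vs age at menopause;
    # "post"/"pre" restricts the generated population to one stratum
    force_menopausal = NULL,
    force_ht = NULL
  )
}

default_planted_log_or <- function() {
  # Continuous covariates: log OR per SD on the analysis scale (PRS raw,
  # MD percent, hormones log-transformed). Binary covariates: per-unit log OR.
  # Defaults reproduce the case/control separations of the source tables:
  # PRS 0.34 SD, MD ~4.6 percentage points (~0.28 SD), E1S/T/PRL log-scale
  # shifts of ~0.38/0.20/0.20 SD, family history OR ~1.66, benign breast
  # disease OR ~1.38.
  c(
    prs = 0.34,
    md = 0.28,
    e1s = 0.38,
    t = 0.20,
    prl = 0.20,
    alcohol = 0.075,
    family_history = log((0.17 / 0.83) / (0.11 / 0.89)),
    bbd = log((0.50 / 0.50) / (0.42 / 0.58))
  )
}

#' Configuration of the synthetic cohort generator
#'
#' Bundles the SNP panel, planted per-covariate effects, marginal distribution
#' parameters, matching design, biomarker missingness rates and root seed that
#' define one synthetic study. Identical configuration and seed yield an
#' identical dataset.
#'
#' @param snp_panel a [snp_panel()] used to simulate genotypes (independent
#'   SNPs in Hardy-Weinberg proportions) and compute the true PRS.
#' @param planted_log_or named numeric vector of log odds ratios entering the
#'   case-status model. Continuous covariates (`prs`, `md`, `e1s`, `t`, `prl`,
#'   `alcohol`) are per SD on the analysis scale (hormones log-transformed,
#'   MD on the percent scale); binary covariates (`family_history`, `bbd`)
#'   are per unit. Defaults emulate the case/control separations observed in
#'   a large nursing cohort.
#' @param marginal_params list of marginal distribution parameters; see
#'   `default_marginal_params()` in the package source for the full set.
#'   Entries supplied here override the defaults entry-wise.
#' @param controls_per_case named numeric: matched controls per case, by
#'   matching subgroup (`postmeno_noHT` and `other`). The default matches two
#'   controls per postmenopausal case not using hormone therapy and one
#'   otherwise.
#' @param missingness_rates named probabilities of a missing value for each
#'   biomarker column.
#' @param baseline_logit intercept of the logistic case-status model; the
#'   default gives a population case fraction of roughly 10 percent.
#' @param er_positive_fraction,er_unknown_fraction distribution of estrogen
#'   receptor status among cases.
#' @param seed integer root seed (mandatory).
#' @return An object of class `generator_config`.
#' @seealso [generate_population()], [sample_nested_case_control()],
#'   [apply_missingness()]
#' @export
#' @examples
#' panel <- read_snp_panel(bcriskaug_extdata("snp_panel_synthetic.csv"))
#' cfg <- generator_config(panel, seed = 1)
generator_config <- function(snp_panel,
                             planted_log_or = default_planted_log_or(),
                             marginal_params = list(),
                             controls_per_case = c(postmeno_noHT = 2, other = 1),
                             missingness_rates = c(md_percent = 0.30,
                                                   t_level = 0.35,
                                                   e1s_level = 0.35,
                                                   prl_level = 0.30),
                             baseline_logit = -2.4,
                             er_positive_fraction = 0.75,
                             er_unknown_fraction = 0.10,
                             seed) {
  stopifnot(inherits(snp_panel, "snp_panel"))
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1) {
    stop("a single integer 'seed' is mandatory", call. = FALSE)
  }
  mp <- default_marginal_params()
  if (length(marginal_params)) {
    unknown <- setdiff(names(marginal_params), names(mp))
    if (length(unknown)) {
      stop("unknown marginal_params entries: ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    mp[names(marginal_params)] <- marginal_params
  }
  base <- default_planted_log_or()
  known <- names(base)
  unknown <- setdiff(names(planted_log_or), known)
  if (length(unknown)) {
    stop("planted_log_or names a covariate with no generated marginal: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  b <- base * 0
  b[names(planted_log_or)] <- planted_log_or
  if (any(!is.finite(b))) stop("planted log ORs must be finite", call. = FALSE)
  if (any(missingness_rates < 0 | missingness_rates > 1)) {
    stop("missingness rates must lie in [0, 1]", call. = FALSE)
  }
  structure(
    list(
      snp_panel = snp_panel,
      planted_log_or = b,
      marginal_params = mp,
      controls_per_case = controls_per_case,
      missingness_rates = missingness_rates,
      baseline_logit = baseline_logit,
      er_positive_fraction = er_positive_fraction,
      er_unknown_fraction = er_unknown_fraction,
      seed = as.integer(seed)
    ),
    class = "generator_config"
  )
}

#' @export
print.generator_config <- function(x, ...) {
  cat("Synthetic cohort generator configuration\n")
  cat("  SNP panel:", nrow(x$snp_panel), "variants\n")
  nz <- x$planted_log_or[x$planted_log_or != 0]
  cat("  planted log ORs:",
      if (length(nz)) paste(names(nz), format(nz, digits = 3), sep = "=",
                            collapse = ", ") else "none", "\n")
  cat("  controls per case:",
      paste(names(x$controls_per_case), x$controls_per_case, sep = "=",
            collapse = ", "), "\n")
  cat("  seed:", x$seed, "\n")
  invisible(x)
}

# Theoretical mean/sd of 100*plogis(N(mu, sigma)) by quadrature, for
# standardising the MD effect without reference to the generated sample.
md_theoretical_moments <- function(mu, sigma) {
  m <- stats::integrate(function(x) 100 * stats::plogis(x) * stats::dnorm(x, mu, sigma),
                        -Inf, Inf)$value
  v <- stats::integrate(function(x) (100 * stats::plogis(x) - m)^2 * stats::dnorm(x, mu, sigma),
                        -Inf, Inf)$value
  c(mean = m, sd = sqrt(v))
}

# Theoretical mean/sd of the zero-inflated log-normal alcohol marginal.
alcohol_theoretical_moments <- function(p) {
  m1 <- exp(p$meanlog + p$sdlog^2 / 2)
  v1 <- (exp(p$sdlog^2) - 1) * exp(2 * p$meanlog + p$sdlog^2)
  mean <- p$prob_drinker * m1
  var <- p$prob_drinker * (v1 + m1^2) - mean^2
  c(mean = mean, sd = sqrt(var))
}

#' Generate a synthetic source population
#'
#' Draws `n` women with epidemiologic risk factors, genotypes, percent
#' mammographic density and hormone levels from the configured marginals, then
#' assigns incident case status from a logistic model whose linear predictor
#' sums the planted log odds ratios over the (standardised, where continuous)
#' covariates. The true linear predictor of every subject is retained in the
#' `true_lp` column for oracle checks.
#'
#' Genotypes are simulated as independent binomial(2, risk allele frequency)
#' counts (Hardy-Weinberg proportions, no linkage disequilibrium). Hormones
#' are log-normal, calibrated from (median, 10th percentile); MD is
#' logit-normal mapped to the 0-100 percent scale.
#'
#' @param config a [generator_config()].
#' @param n number of subjects (>= 1).
#' @return A data frame with one row per subject: identifiers, risk factors,
#'   per-SNP genotype columns `g_<rsid>`, biomarker columns (`md_percent`,
#'   `t_level`, `e1s_level`, `prl_level`), `is_case`, `er_status` and
#'   `true_lp`.
#' @export
#' @examples
#' panel <- snp_panel(paste0("rs", 1:5), rep("A", 5),
#'                    rep(0.3, 5), rep(1.1, 5))
#' pop <- generate_population(generator_config(panel, seed = 7), n = 200)
#' table(pop$is_case)
generate_population <- function(config, n) {
  stopifnot(inherits(config, "generator_config"), n >= 1)
  mp <- config$marginal_params
  beta <- config$planted_log_or
  set.seed(stage_seed(config$seed, "generate_population"))

  subject_id <- sprintf("S%07d", seq_len(n))
  cohort <- ifelse(stats::runif(n) < 2 / 3, "NHS-like", "NHSII-like")

  age <- rnorm_trunc(n, mp$age$mean, mp$age$sd, mp$age$min, mp$age$max)
  menop_latent <- rnorm_trunc(n, mp$age_menopause$mean, mp$age_menopause$sd,
                              mp$age_menopause$min, mp$age_menopause$max)
  if (!is.null(mp$force_menopausal)) {
    if (identical(mp$force_menopausal, "post")) {
      age <- pmax(age, mp$age_menopause$min + 1)
      # redraw the latent menopause age below the attained age
      menop_latent <- rnorm_trunc(n, mp$age_menopause$mean, mp$age_menopause$sd,
                                  mp$age_menopause$min,
                                  pmin(age, mp$age_menopause$max))
    } else if (identical(mp$force_menopausal, "pre")) {
      age <- pmin(age, menop_latent - 0.5)
    } else stop("force_menopausal must be NULL, 'pre' or 'post'", call. = FALSE)
  }
  postmeno <- age > menop_latent
  menopausal_status <- ifelse(postmeno, "post", "pre")
  ht_use <- postmeno & (stats::runif(n) < mp$prob_ht_given_post)
  if (!is.null(mp$force_ht)) ht_use <- postmeno & isTRUE(mp$force_ht)

  age_menarche <- round(rnorm_trunc(n, mp$age_menarche$mean, mp$age_menarche$sd,
                                    mp$age_menarche$min, mp$age_menarche$max))
  parous <- stats::runif(n) < mp$prob_parous
  parity <- ifelse(parous,
                   as.integer(sample(names(mp$parity_probs), n, TRUE,
                                     mp$parity_probs)),
                   0L)
  afb <- rnorm_trunc(n, mp$age_first_birth$mean, mp$age_first_birth$sd,
                     mp$age_first_birth$min, mp$age_first_birth$max)
  afb <- pmin(afb, age - 1)  # first birth precedes blood draw
  birth_ages <- vector("list", n)
  for (i in which(parous)) {
    gaps <- 1 + stats::rexp(parity[i] - 1, rate = 1 / (mp$birth_spacing_mean - 1))
    ba <- afb[i] + cumsum(c(0, gaps))
    ba <- round(ba[ba < age[i]], 1)
    birth_ages[[i]] <- ba
    parity[i] <- length(ba)
  }
  age_first_birth <- ifelse(parous, round(afb, 1), NA_real_)

  family_history <- stats::runif(n) < mp$family_history_prev
  bbd_history <- stats::runif(n) < mp$bbd_prev
  n_biopsies <- ifelse(bbd_history,
                       1L + stats::rbinom(n, 1, 0.3),
                       0L)
  bmi <- rnorm_trunc(n, mp$bmi$mean, mp$bmi$sd, mp$bmi$min, mp$bmi$max)
  height <- rnorm_trunc(n, mp$height$mean, mp$height$sd, mp$height$min,
                        mp$height$max)
  alcohol <- ifelse(stats::runif(n) < mp$alcohol$prob_drinker,
                    stats::rlnorm(n, mp$alcohol$meanlog, mp$alcohol$sdlog),
                    0)

  # genotypes: independent SNPs in Hardy-Weinberg proportions
  panel <- config$snp_panel
  m <- nrow(panel)
  geno <- matrix(stats::rbinom(n * m, 2,
                               rep(panel$risk_allele_freq, each = n)),
                 nrow = n, ncol = m)
  colnames(geno) <- paste0("g_", panel$rsid)
  prs_raw <- compute_prs(geno, panel)
  # theoretical moments of the raw PRS under HWE
  prs_mean <- sum(2 * panel$risk_allele_freq * panel$weight)
  prs_sd <- sqrt(sum(2 * panel$risk_allele_freq * (1 - panel$risk_allele_freq) *
                       panel$weight^2))

  hq <- lapply(mp[c("e1s", "t", "prl")],
               function(p) lnorm_from_quantiles(p$median, p$p10))
  e1s_level <- stats::rlnorm(n, hq$e1s$meanlog, hq$e1s$sdlog)
  t_level <- stats::rlnorm(n, hq$t$meanlog, hq$t$sdlog)
  prl_level <- stats::rlnorm(n, hq$prl$meanlog, hq$prl$sdlog)
  md_percent <- 100 * stats::plogis(stats::rnorm(n, mp$md$mu, mp$md$sigma))
  mdm <- md_theoretical_moments(mp$md$mu, mp$md$sigma)
  alcm <- alcohol_theoretical_moments(mp$alcohol)

  standardise <- function() cbind(
    prs = (prs_raw - prs_mean) / prs_sd,
    md = (md_percent - mdm["mean"]) / mdm["sd"],
    e1s = (log(e1s_level) - hq$e1s$meanlog) / hq$e1s$sdlog,
    t = (log(t_level) - hq$t$meanlog) / hq$t$sdlog,
    prl = (log(prl_level) - hq$prl$meanlog) / hq$prl$sdlog,
    alcohol = (alcohol - alcm["mean"]) / alcm["sd"],
    family_history = as.numeric(family_history),
    bbd = as.numeric(bbd_history)
  )
  # The configured biomarker marginals describe CONTROLS. Under planted
  # effects, controls sit below the population location by about
  # (case fraction) x (planted per-SD log OR) standard deviations, so
  # pre-compensate the hormone and MD locations by that amount. The planted
  # effects themselves stay expressed per configured SD.
  z <- standardise()
  p_hat <- mean(stats::plogis(config$baseline_logit +
                                drop(z %*% beta[colnames(z)])))
  e1s_level <- e1s_level * exp(hq$e1s$sdlog * p_hat * beta[["e1s"]])
  t_level <- t_level * exp(hq$t$sdlog * p_hat * beta[["t"]])
  prl_level <- prl_level * exp(hq$prl$sdlog * p_hat * beta[["prl"]])
  md_percent <- pmin(pmax(md_percent + mdm["sd"] * p_hat * beta[["md"]],
                          0.01), 99.99)
  z <- standardise()
  true_lp <- config$baseline_logit + drop(z %*% beta[colnames(z)])
  is_case <- stats::runif(n) < stats::plogis(true_lp)

  er_status <- rep(NA_character_, n)
  u <- stats::runif(n)
  er_status[is_case] <- ifelse(
    u[is_case] < config$er_positive_fraction, "positive",
    ifelse(u[is_case] < config$er_positive_fraction + config$er_unknown_fraction,
           "unknown", "negative"))

  out <- data.frame(
    subject_id = subject_id,
    cohort = cohort,
    is_case = is_case,
    er_status = er_status,
    age_at_draw = round(age, 2),
    menopausal_status = menopausal_status,
    ht_use = ht_use,
    age_menarche = age_menarche,
    age_first_birth = age_first_birth,
    parity = parity,
    birth_ages = vapply(birth_ages, function(b)
      if (length(b)) paste(b, collapse = ";") else "", character(1)),
    family_history = family_history,
    n_biopsies = n_biopsies,
    bbd_history = bbd_history,
    bmi = round(bmi, 2),
    height = round(height, 1),
    alcohol = round(alcohol, 2),
    age_menopause = ifelse(postmeno, round(menop_latent, 1), NA_real_),
    stringsAsFactors = FALSE
  )
  out <- cbind(out, as.data.frame(geno))
  out$md_percent <- md_percent
  out$t_level <- t_level
  out$e1s_level <- e1s_level
  out$prl_level <- prl_level
  out$true_lp <- true_lp
  out
}

#' Draw a matched nested case-control sample
#'
#' Emulates risk-set sampling within a cohort: every case is matched, without
#' replacement, to controls of the same menopausal status and hormone-therapy
#' use whose age is within one year. Postmenopausal cases not using hormone
#' therapy receive two controls; all other cases receive one. Cases whose
#' matching cell is exhausted are dropped with a warning.
#'
#' @param population data frame from [generate_population()].
#' @param config the [generator_config()] (provides `controls_per_case`).
#' @return Data frame of the selected cases and controls with a `match_id`
#'   column identifying each matched set. The number of dropped cases is
#'   attached as attribute `n_dropped`.
#' @export
sample_nested_case_control <- function(population, config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(stage_seed(config$seed, "sample_ncc"))
  cases <- which(population$is_case)
  empty <- population[0, , drop = FALSE]
  empty$match_id <- character(0)
  if (!length(cases)) return(empty)

  cell_of <- paste(population$menopausal_status, population$ht_use)
  keep_rows <- integer(0)
  match_ids <- character(0)
  n_dropped <- 0L

  for (cell in unique(cell_of[cases])) {
    cell_cases <- cases[cell_of[cases] == cell]
    cell_cases <- cell_cases[sample.int(length(cell_cases))]
    ctrl <- which(!population$is_case & cell_of == cell)
    ord <- order(population$age_at_draw[ctrl])
    ctrl <- ctrl[ord]
    ctrl_age <- population$age_at_draw[ctrl]
    used <- logical(length(ctrl))
    post_noht <- grepl("^post FALSE$", cell)
    k <- if (post_noht) config$controls_per_case[["postmeno_noHT"]]
         else config$controls_per_case[["other"]]
    for (cs in cell_cases) {
      a <- population$age_at_draw[cs]
      lo <- findInterval(a - 1, ctrl_age, left.open = TRUE) + 1
      hi <- findInterval(a + 1, ctrl_age)
      cand <- if (hi >= lo) (lo:hi)[!used[lo:hi]] else integer(0)
      if (length(cand) < k) {
        n_dropped <- n_dropped + 1L
        next
      }
      pick <- if (length(cand) == 1) cand else sample(cand, k)
      pick <- pick[seq_len(k)]
      used[pick] <- TRUE
      mid <- population$subject_id[cs]
      keep_rows <- c(keep_rows, cs, ctrl[pick])
      match_ids <- c(match_ids, rep(mid, 1 + k))
    }
  }
  if (n_dropped > 0) {
    warning(n_dropped, " case(s) dropped: matching cell exhausted",
            call. = FALSE)
  }
  out <- population[keep_rows, , drop = FALSE]
  out$match_id <- match_ids
  rownames(out) <- NULL
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Apply missingness to biomarker columns
#'
#' Masks biomarker values as missing at the configured per-biomarker rates.
#' The default mechanism is missing completely at random (MCAR); an optional
#' missing-at-random mechanism tilts the missingness probability by
#' standardised age while preserving the approximate marginal rate.
#'
#' @param dataset subject data frame.
#' @param rates named probabilities, names matching biomarker columns
#'   (e.g. `md_percent`, `t_level`).
#' @param seed integer seed.
#' @param mechanism `"mcar"` (default) or `"mar_age"`.
#' @return The dataset with masked values set to `NA`.
#' @export
apply_missingness <- function(dataset, rates, seed,
                              mechanism = c("mcar", "mar_age")) {
  mechanism <- match.arg(mechanism)
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]", call. = FALSE)
  set.seed(stage_seed(seed, "apply_missingness"))
  n <- nrow(dataset)
  for (col in names(rates)) {
    if (!col %in% names(dataset)) {
      stop("no biomarker column named '", col, "'", call. = FALSE)
    }
    r <- rates[[col]]
    if (r == 0) next
    p <- if (mechanism == "mcar") rep(r, n) else {
      za <- as.numeric(scale(dataset$age_at_draw))
      stats::plogis(stats::qlogis(min(max(r, 1e-9), 1 - 1e-9)) + 0.5 * za)
    }
    if (r == 1) p <- rep(1, n)
    dataset[[col]][stats::runif(n) < p] <- NA
  }
  dataset
}

#' Write / read a subject table as CSV
#'
#' One row per subject, header as the field names, missing values encoded as
#' empty strings, genotypes as per-SNP columns `g_<rsid>`, multiple birth ages
#' separated by `;`.
#'
#' @param dataset subject data frame.
#' @param path file path.
#' @return `write_subject_table()` returns `path` invisibly;
#'   `read_subject_table()` returns the data frame with logical columns
#'   restored.
#' @export
write_subject_table <- function(dataset, path) {
  utils::write.csv(dataset, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_subject_table
#' @export
read_subject_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  for (col in intersect(c("is_case", "ht_use", "family_history", "bbd_history",
                          grep("_imputed$", names(df), value = TRUE)),
                        names(df))) {
    df[[col]] <- as.logical(df[[col]])
  }
  if ("birth_ages" %in% names(df)) {
    df$birth_ages[is.na(df$birth_ages)] <- ""
  }
  df
}

# Parse the ";"-separated birth_ages field into a numeric vector.
parse_birth_ages <- function(s) {
  if (is.na(s) || !nzchar(s)) return(numeric(0))
  as.numeric(strsplit(s, ";", fixed = TRUE)[[1]])
}
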