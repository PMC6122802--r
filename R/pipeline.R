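# End-to-end pipeline: generate -> score -> impute -> augment -> evaluate ->
# project, driven by a YAML run configuration. Every stage writes plain
# CSV/JSON artifacts so any stage can be rerun in isolation, and all
# randomness derives from the single root seed.

default_run_config <- function() {
  list(
    seed = 1,
    n_population = 20000,
    snp_panel = "builtin",
    gail_spec = "builtin",
    rc_spec = "builtin",
    incidence_table = "builtin",
    base_models = c("gail", "rc"),
    subgroups = c("premeno", "postmeno_noHT", "postmeno_HT", "all"),
    biomarker_combinations = list(
      premeno = list("prs", "md", c("prs", "md")),
      postmeno_noHT = list("prs", "md", c("t", "e1s", "prl"), c("prs", "md"),
                           c("prs", "t", "e1s", "prl"),
                           c("md", "t", "e1s", "prl"),
                           c("prs", "md", "t", "e1s", "prl")),
      postmeno_HT = list("prs", "md", "prl", c("prs", "md"), c("prs", "prl"),
                         c("md", "prl"), c("prs", "md", "prl")),
      all = list(c("prs", "md", "t", "e1s", "prl"))
    ),
    generator = list(),
    missingness_rates = list(md_percent = 0.30, t_level = 0.35,
                             e1s_level = 0.35, prl_level = 0.30),
    auc = list(variance = "hanley", n_boot = 200),
    cv = list(enabled = TRUE, k = 10),
    absolute_risk = list(at_age = 50, horizon = 5, threshold = 0.0227),
    er_positive = FALSE
  )
}

#' Read a pipeline run configuration
#'
#' Reads a YAML run configuration and merges it over the package defaults.
#' See `inst/extdata/demo_config.yaml` for a commented example.
#'
#' @param path YAML file path, or `NULL` for the defaults.
#' @return A named list of class `run_config`.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- default_run_config()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    for (nm in names(user)) {
      if (is.list(cfg[[nm]]) && is.list(user[[nm]]) &&
          !is.null(names(cfg[[nm]]))) {
        cfg[[nm]][names(user[[nm]])] <- user[[nm]]
      } else {
        cfg[[nm]] <- user[[nm]]
      }
    }
  }
  class(cfg) <- "run_config"
  cfg
}

resolve_builtin <- function(value, builtin_name) {
  if (identical(value, "builtin")) bcriskaug_extdata(builtin_name) else value
}

#' Validate a run configuration
#'
#' Checks the whole configuration and reports every problem at once: missing
#' files, invalid subgroups, hormone-policy violations in the requested
#' biomarker combinations, out-of-range rates, and insufficient bootstrap or
#' fold settings.
#'
#' @param config a [read_run_config()] list.
#' @return A list with `ok` (logical) and `errors` (character vector, empty
#'   when valid).
#' @export
validate_config <- function(config) {
  errors <- character(0)
  push <- function(msg) errors <<- c(errors, msg)
  if (is.null(config$seed) || !is.numeric(config$seed)) {
    push("seed: a numeric root seed is mandatory")
  }
  if (!is.numeric(config$n_population) || config$n_population < 100) {
    push("n_population: need at least 100 subjects")
  }
  for (key in c("snp_panel", "gail_spec", "rc_spec", "incidence_table")) {
    val <- config[[key]]
    if (is.null(val)) { push(paste0(key, ": missing path")); next }
    if (!identical(val, "builtin") && !file.exists(val)) {
      push(paste0(key, ": file not found: ", val))
    }
  }
  bad_sub <- setdiff(config$subgroups,
                     c("premeno", "postmeno_noHT", "postmeno_HT", "all"))
  if (length(bad_sub)) push(paste0("subgroups: unknown: ",
                                   paste(bad_sub, collapse = ", ")))
  for (sg in intersect(config$subgroups, names(config$biomarker_combinations))) {
    for (combo in config$biomarker_combinations[[sg]]) {
      res <- tryCatch({ check_biomarker_policy(sg, unlist(combo)); NULL },
                      error = function(e) conditionMessage(e))
      if (!is.null(res)) push(paste0("biomarker_combinations[", sg, "]: ", res))
    }
  }
  rates <- unlist(config$missingness_rates)
  if (any(rates < 0 | rates > 1)) push("missingness_rates: must lie in [0, 1]")
  if (!is.null(config$auc$n_boot) && config$auc$n_boot < 100) {
    push("auc$n_boot: at least 100 bootstrap replicates required")
  }
  if (isTRUE(config$cv$enabled) && config$cv$k < 2) push("cv$k: need k >= 2")
  th <- config$absolute_risk$threshold
  if (!is.null(th) && (th <= 0 || th >= 1)) {
    push("absolute_risk$threshold: must lie in (0, 1)")
  }
  list(ok = length(errors) == 0, errors = errors)
}

combo_label <- function(biomarkers) {
  labels <- vapply(biomarkers, function(b) biomarker_columns[[b]]$label,
                   character(1))
  paste("+", paste(labels, collapse = " + "))
}

#' Run the full analysis pipeline
#'
#' Orchestrates the stages: generate the synthetic source population and the
#' matched nested case-control sample; compute the PRS, Gail and
#' Rosner-Colditz scores; impute masked biomarkers; fit the augmented logistic
#' models per subgroup and biomarker combination; evaluate age-adjusted AUCs,
#' bootstrap AUC changes, the NRI of the richest model, and cross-validation;
#' and project 5-year absolute risk distributions for the Gail model among
#' postmenopausal women not using hormone therapy. Identical configuration and
#' seed produce identical outputs.
#'
#' Artifacts written to `outdir`: `dataset.csv`, `coefficients.csv/.json`,
#' `imputation_<biomarker>.json`, `discrimination.csv`, `nri.json`,
#' `risk_distribution.csv`, `summary.json` and `run.log`.
#'
#' @param config a [read_run_config()] configuration.
#' @param outdir output directory (created if needed).
#' @param quiet suppress progress messages.
#' @return Invisibly, a list with the main in-memory results (`dataset`,
#'   `discrimination`, `nri`, `risk_distributions`, `cv`, `summary`).
#' @export
run_pipeline <- function(config, outdir, quiet = FALSE) {
  chk <- validate_config(config)
  if (!chk$ok) {
    stop("invalid configuration:\n  ", paste(chk$errors, collapse = "\n  "),
         call. = FALSE)
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(outdir, "run.log")
  cat("", file = logf)
  say <- function(...) {
    line <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
    cat(line, "\n", file = logf, append = TRUE)
    if (!quiet) message(...)
  }
  say("bcriskaug ", as.character(utils::packageVersion("bcriskaug")),
      " | R ", R.version.string, " | root seed ", config$seed)

  # ---- generate --------------------------------------------------------------
  panel <- read_snp_panel(resolve_builtin(config$snp_panel,
                                          "snp_panel_synthetic.csv"))
  gen_args <- c(list(snp_panel = panel, seed = config$seed),
                config$generator)
  gcfg <- do.call(generator_config, gen_args)
  pop <- generate_population(gcfg, config$n_population)
  say("generated population n=", nrow(pop), " (", sum(pop$is_case), " cases)")
  ds <- sample_nested_case_control(pop, gcfg)
  say("nested case-control sample: ", sum(ds$is_case), " cases / ",
      sum(!ds$is_case), " controls (", attr(ds, "n_dropped"),
      " cases dropped)")
  ds <- apply_missingness(ds, unlist(config$missingness_rates), config$seed)

  # ---- score -----------------------------------------------------------------
  gail_spec <- read_model_spec(resolve_builtin(config$gail_spec,
                                               "gail_modified.json"))
  rc_spec <- read_model_spec(resolve_builtin(
    config$rc_spec, "rosner_colditz_simplified.json"))
  geno <- as.matrix(ds[, paste0("g_", panel$rsid), drop = FALSE])
  ds$prs <- standardize_prs(compute_prs(geno, panel))
  ds$gail_rr <- compute_gail_rr(ds, gail_spec)
  ds$gail_lp <- log(ds$gail_rr)
  ds$rc_score <- compute_rc_score(ds, rc_spec)
  say("scores computed: PRS standardised over ", nrow(ds), " participants; ",
      "mean Gail RR ", round(mean(ds$gail_rr), 3))

  # ---- impute ----------------------------------------------------------------
  for (bm in c("md_percent", "t_level", "e1s_level", "prl_level")) {
    if (!anyNA(ds[[bm]])) next
    im <- fit_imputation_model(ds, bm)
    write_imputation_model(im, file.path(outdir,
                                         paste0("imputation_", bm, ".json")))
    n_missing <- sum(is.na(ds[[bm]]))
    ds <- impute_missing(ds, im, config$seed)
    say("imputed ", n_missing, " missing ", bm, " values (residual SD ",
        round(im$residual_sd, 3), ")")
  }
  if (isTRUE(config$er_positive)) {
    ds <- restrict_er_positive(ds)
    say("restricted to ER+ cases: ", sum(ds$is_case), " cases retained")
  }
  write_subject_table(ds, file.path(outdir, "dataset.csv"))

  # ---- augment + evaluate ----------------------------------------------------
  base_cols <- c(gail = "gail_lp", rc = "rc_score")
  models <- list()
  rows <- list()
  for (bm_name in config$base_models) {
    base_col <- base_cols[[bm_name]]
    for (sg in config$subgroups) {
      sub <- subgroup_subset(ds, sg)
      if (sum(sub$is_case) < 10 || sum(!sub$is_case) < 10) {
        say("skipping subgroup ", sg, ": too few subjects")
        next
      }
      m_base <- fit_augmented_model(ds, base_col, character(0), subgroup = sg)
      lp_base <- linear_predictor(m_base, sub)
      auc_base <- age_adjusted_auc(lp_base, sub$is_case, sub$age_at_draw,
                                   variance = config$auc$variance)
      rows[[length(rows) + 1]] <- data.frame(
        base_model = bm_name, subgroup = sg, model = "base",
        n_case = m_base$n_case, n_control = m_base$n_control,
        auc = auc_base$auc_x100, auc_lo = auc_base$ci95[1],
        auc_hi = auc_base$ci95[2], delta = NA, delta_lo = NA, delta_hi = NA,
        p_value = NA, stringsAsFactors = FALSE)
      say(bm_name, " / ", sg, ": base AUC ", round(auc_base$auc_x100, 1),
          " (", m_base$n_case, " cases / ", m_base$n_control, " controls)")
      for (combo in config$biomarker_combinations[[sg]]) {
        combo <- unlist(combo)
        m_aug <- fit_augmented_model(ds, base_col, combo, subgroup = sg)
        models[[length(models) + 1]] <- m_aug
        lp_aug <- linear_predictor(m_aug, sub)
        d <- delta_auc(lp_base, lp_aug, sub$is_case, sub$age_at_draw,
                       n_boot = config$auc$n_boot,
                       seed = stage_seed(config$seed,
                                         paste(bm_name, sg,
                                               paste(combo, collapse = "+"))),
                       variance = config$auc$variance)
        rows[[length(rows) + 1]] <- data.frame(
          base_model = bm_name, subgroup = sg, model = combo_label(combo),
          n_case = m_aug$n_case, n_control = m_aug$n_control,
          auc = d$auc_augmented$auc_x100,
          auc_lo = d$auc_augmented$ci95[1], auc_hi = d$auc_augmented$ci95[2],
          delta = d$delta_x100, delta_lo = d$ci95[1], delta_hi = d$ci95[2],
          p_value = d$p_value, stringsAsFactors = FALSE)
        say(bm_name, " / ", sg, " ", combo_label(combo), ": AUC ",
            round(d$auc_augmented$auc_x100, 1), " (change ",
            round(d$delta_x100, 1), ")")
      }
    }
  }
  disc <- do.call(rbind, rows)
  utils::write.csv(disc, file.path(outdir, "discrimination.csv"),
                   row.names = FALSE)
  export_coefficients(models, file.path(outdir, "coefficients.csv"),
                      file.path(outdir, "coefficients.json"))

  # ---- project: absolute risk, NRI, CV (Gail, postmeno no-HT) ---------------
  inc <- read_incidence_table(resolve_builtin(
    config$incidence_table, "incidence_seer_like_synthetic.csv"))
  ar <- config$absolute_risk
  sub <- subgroup_subset(ds, "postmeno_noHT")
  nri_res <- NULL
  risk_dists <- NULL
  cv_res <- NULL
  if ("postmeno_noHT" %in% config$subgroups &&
      sum(sub$is_case) >= 10 && sum(!sub$is_case) >= 10 &&
      "gail" %in% config$base_models) {
    joint <- intersect(c("prs", "md", "t", "e1s", "prl"),
                       unique(unlist(config$biomarker_combinations$postmeno_noHT)))
    m_base <- fit_augmented_model(ds, "gail_lp", character(0),
                                  subgroup = "postmeno_noHT")
    m_joint <- fit_augmented_model(ds, "gail_lp", joint,
                                   subgroup = "postmeno_noHT")
    ctrl <- sub[!sub$is_case, , drop = FALSE]
    rr_base <- ctrl$gail_rr
    rr_joint <- exp(linear_predictor(m_joint, ctrl))
    bl_base <- calibrate_baseline_hazard(inc, rr_base, ctrl$age_at_draw)
    bl_joint <- calibrate_baseline_hazard(inc, rr_joint, ctrl$age_at_draw)
    rd_base <- risk_distribution(rr_base, bl_base, at_age = ar$at_age,
                                 horizon = ar$horizon,
                                 threshold = ar$threshold)
    rd_joint <- risk_distribution(rr_joint, bl_joint, at_age = ar$at_age,
                                  horizon = ar$horizon,
                                  threshold = ar$threshold)
    say("fraction of ", ar$at_age, "-year-old women at >= ",
        100 * ar$threshold, "% 5-year risk: base ",
        round(100 * rd_base$fraction_above_threshold, 2), "% vs augmented ",
        round(100 * rd_joint$fraction_above_threshold, 2), "%")
    curve <- data.frame(
      percentile = rd_base$percentile_curve$percentile,
      risk_base = rd_base$percentile_curve$risk,
      risk_augmented = rd_joint$percentile_curve$risk)
    utils::write.csv(curve, file.path(outdir, "risk_distribution.csv"),
                     row.names = FALSE)
    risk_dists <- list(base = rd_base, augmented = rd_joint)

    # NRI on the subgroup, each subject projected at her own age
    rr_all_base <- sub$gail_rr
    rr_all_joint <- exp(linear_predictor(m_joint, sub))
    risks_old <- project_absolute_risk(rr_all_base, sub$age_at_draw,
                                       ar$horizon, bl_base)
    risks_new <- project_absolute_risk(rr_all_joint, sub$age_at_draw,
                                       ar$horizon, bl_joint)
    nri_res <- nri(risks_old, risks_new, sub$is_case, ar$threshold)
    say("NRI (Gail vs Gail", combo_label(joint), "): ",
        round(nri_res$total, 3))
    jsonlite::write_json(
      list(total = nri_res$total, case_component = nri_res$case_component,
           control_component = nri_res$control_component,
           ci95 = nri_res$ci95, threshold = nri_res$threshold),
      file.path(outdir, "nri.json"), auto_unbox = TRUE, digits = NA)

    if (isTRUE(config$cv$enabled)) {
      cv_res <- cross_validate(ds, "gail_lp", joint,
                               subgroup = "postmeno_noHT", k = config$cv$k,
                               seed = config$seed)
      say("10-fold CV change in AUC: train ",
          round(cv_res$train_delta_x100, 1), " vs validation ",
          round(cv_res$validation_delta_x100, 1))
    }
  }

  summary <- list(
    seed = config$seed,
    n_case = sum(ds$is_case), n_control = sum(!ds$is_case),
    nri_total = if (!is.null(nri_res)) nri_res$total else NULL,
    fraction_above_threshold = if (!is.null(risk_dists)) {
      list(base = risk_dists$base$fraction_above_threshold,
           augmented = risk_dists$augmented$fraction_above_threshold)
    } else NULL,
    cv = if (!is.null(cv_res)) cv_res[c("train_delta_x100",
                                        "validation_delta_x100")] else NULL)
  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  say("pipeline complete")
  invisible(list(dataset = ds, discrimination = disc, nri = nri_res,
                 risk_distributions = risk_dists, cv = cv_res,
                 summary = summary))
}
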