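# Shared fixtures, built in code. The scored nested case-control cohort is
# cached so several test files can reuse it without regenerating.

.fixture_env <- new.env(parent = emptyenv())

test_panel <- function(n = 8, seed = 402) {
  set.seed(seed)
  snp_panel(
    rsid = sprintf("rs%03d", seq_len(n)),
    risk_allele = sample(c("A", "C", "G", "T"), n, TRUE),
    risk_allele_freq = round(runif(n, 0.1, 0.9), 2),
    odds_ratio = round(exp(abs(rnorm(n, 0, 0.1)) + 0.02), 3)
  )
}

full_panel <- function() {
  read_snp_panel(bcriskaug_extdata("snp_panel_synthetic.csv"))
}

# Score a nested case-control dataset: standardised PRS, Gail RR / log-RR,
# Rosner-Colditz score.
score_dataset <- function(ds, panel) {
  geno <- as.matrix(ds[, paste0("g_", panel$rsid), drop = FALSE])
  ds$prs <- standardize_prs(compute_prs(geno, panel))
  ds$gail_rr <- compute_gail_rr(ds)
  ds$gail_lp <- log(ds$gail_rr)
  ds$rc_score <- compute_rc_score(ds)
  ds
}

# A moderately sized scored cohort (~1,800 cases) shared across test files.
shared_cohort <- function() {
  if (!is.null(.fixture_env$cohort)) return(.fixture_env$cohort)
  panel <- full_panel()
  cfg <- generator_config(panel, seed = 901)
  pop <- generate_population(cfg, 16000)
  # a handful of cases in sparse age cells may be dropped; that is expected
  ds <- suppressWarnings(sample_nested_case_control(pop, cfg))
  ds <- score_dataset(ds, panel)
  .fixture_env$cohort <- list(panel = panel, config = cfg, population = pop,
                              dataset = ds)
  .fixture_env$cohort
}

# Reference Gail-factor profile: relative risk 1 by construction.
reference_profile <- function(n = 1) {
  data.frame(
    age_menarche = rep(14, n), n_biopsies = 0, age_first_birth = 19,
    family_history = FALSE, age_at_draw = 45
  )
}
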