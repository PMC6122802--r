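# Demo run configuration: a small end-to-end pipeline run (~1-2 minutes).
# Any field omitted here keeps its package default; paths given as "builtin"
# resolve to the files shipped under extdata/.
seed: 20260920
n_population: 12000

snp_panel: builtin          # synthetic 67-SNP panel
gail_spec: builtin          # modified Gail coefficients
rc_spec: builtin            # simplified Rosner-Colditz coefficients
incidence_table: builtin    # SEER-like synthetic composite incidence

base_models: [gail, rc]
subgroups: [premeno, postmeno_noHT, postmeno_HT, all]

# Biomarker combinations per subgroup follow the hormone policy:
# T/E1S/PRL only in postmenopausal non-HT users (and the pooled analysis),
# PRL only in postmenopausal HT users, no hormones in premenopausal women.
biomarker_combinations:
  premeno: [[prs], [md], [prs, md]]
  postmeno_noHT: [[prs], [md], [t, e1s, prl], [prs, md], [prs, md, t, e1s, prl]]
  postmeno_HT: [[prs], [md], [prl], [prs, md, prl]]
  all: [[prs, md, t, e1s, prl]]

missingness_rates:
  md_percent: 0.30
  t_level: 0.35
  e1s_level: 0.35
  prl_level: 0.30

auc:
  variance: hanley
  n_boot: 200

cv:
  enabled: true
  k: 10

absolute_risk:
  at_age: 50
  horizon: 5
  threshold: 0.0227
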