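{
  "model_name": "gail_modified",
  "comment": "Modified Gail relative-risk score: published category coefficients with family history collapsed to yes/no and no atypical-hyperplasia term. Reference woman (menarche >= 14, no biopsies, first birth < 20, no family history) has linear predictor 0.",
  "terms": [
    {"covariate": "age_menarche", "transform": "gail_menarche_cat", "coef": 0.09401},
    {"covariate": "n_biopsies", "transform": "gail_biopsy_cat", "coef": 0.52926},
    {"covariate": "age_first_birth", "transform": "gail_ageflb_cat", "coef": 0.21863},
    {"covariate": "family_history", "transform": "binary", "coef": 0.95830}
  ],
  "interactions": [
    {"covariates": ["n_biopsies", "age_at_draw"],
     "transforms": ["gail_biopsy_cat", "age_ge_50"],
     "coef": -0.28804},
    {"covariates": ["age_first_birth", "family_history"],
     "transforms": ["gail_ageflb_cat", "binary"],
     "coef": -0.19081}
  ]
}
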