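{
  "model_name": "rosner_colditz_simplified",
  "comment": "Simplified log-incidence score with reproductive-timeline terms. Coefficients are illustrative defaults and are meant to be replaced with a fitted or published set; they are configuration data, not package constants. All factors at reference give linear predictor 0.",
  "terms": [
    {"covariate": "age_menarche", "transform": "center", "params": {"center": 13}, "coef": -0.04},
    {"covariate": "birth_ages", "transform": "birth_index", "coef": 0.003},
    {"covariate": "family_history", "transform": "binary", "coef": 0.45},
    {"covariate": "bbd_history", "transform": "binary", "coef": 0.30},
    {"covariate": "age_at_draw", "transform": "premeno_duration", "coef": 0.045},
    {"covariate": "age_at_draw", "transform": "postmeno_duration", "coef": 0.022},
    {"covariate": "ht_use", "transform": "binary", "coef": 0.25},
    {"covariate": "bmi", "transform": "center", "params": {"center": 25}, "coef": 0.02, "condition": "postmenopausal"},
    {"covariate": "height", "transform": "center", "params": {"center": 163}, "coef": 0.02},
    {"covariate": "alcohol", "transform": "identity", "coef": 0.01}
  ],
  "interactions": []
}
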