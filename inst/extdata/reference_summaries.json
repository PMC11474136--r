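{
  "description": "Published summary statistics of a crossed gage R&R evaluation of nine LLM triage prompts (appraisers) on 391 START patient vignettes (parts) with 10 replicates per combination.",
  "design": {"n_appraisers": 9, "n_parts": 391, "n_replicates": 10, "n_trials": 35190},
  "class_mix": {"red": 35, "yellow": 130, "green": 201, "black": 25},
  "rater_agreement": {"n_agreed": 345, "n_total": 391},
  "valid_responses": {"n_valid": 35102, "n_total": 35190},
  "cell_range_frequency": {"range": [0, 1, 2, 3], "n": [1735, 1459, 226, 99]},
  "part_range_frequency": {"range": [0, 1, 2, 3], "n": [27, 174, 150, 40]},
  "per_prompt_mean_range": [0.46, 0.49, 0.72, 1.27, 0.66, 0.53, 0.54, 0.36, 0.61],
  "per_prompt_accuracy": [71.8, 72.0, 63.1, 46.7, 68.7, 60.6, 66.8, 54.4, 71.3],
  "per_class_rates": {
    "red":    {"match": 80.9, "overtriage": 0.0,  "undertriage": 19.1},
    "yellow": {"match": 50.8, "overtriage": 45.0, "undertriage": 4.2},
    "green":  {"match": 69.4, "overtriage": 30.6, "undertriage": 0.04},
    "black":  {"match": 64.6, "overtriage": 35.4, "undertriage": 0.0}
  },
  "published_EV": 0.17,
  "published_AV": 0.091
}
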