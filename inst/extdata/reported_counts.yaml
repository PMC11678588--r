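# Published summary counts and printed evaluation metrics for the
# three-disease AAPP overlap study; inputs to reproduceReported().
venn:
  totals: {AD: 67213, ALS: 63179, FTD: 43643}
  pairwise: {AD_ALS: 62335, AD_FTD: 43418, ALS_FTD: 43368}
  triple: 43176
reported_percentages:
  AD: {all_three: 64.2, shared_ALS: 28.5, shared_FTD: 0.4, exclusive: 6.9}
  ALS: {all_three: 68.3, shared_AD: 30.3, shared_FTD: 0.3, exclusive: 1.1}
  FTD: {all_three: 98.9, shared_AD: 0.6, shared_ALS: 0.4, exclusive: 0.1}
evaluators:
  - {evaluator: SemNet 2.0, precision: 0.94, recall: 0.71, f_measure: 0.81, accuracy: 0.74}
  - {evaluator: GPT-4o LLM, precision: 0.80, recall: 0.83, f_measure: 0.82, accuracy: 0.71}
  - {evaluator: Humans, precision: 1.0, recall: 1.0, f_measure: 1.0, accuracy: 1.0}
composites:
  grn_protein: {AD: 0.888, ALS: 0.934, FTD: 0.988}
  single_disease_example: {disease: AD, score: 0.991}
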