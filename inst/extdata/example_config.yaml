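# Example run configuration for the radsel command-line pipeline:
#   radsel simulate --config example_config.yaml
#   radsel select   --config example_config.yaml
seed: 7
output_dir: radsel_out
marker: ER
simulate:
  table:
    n_samples: 80
    n_features: 200
    n_informative: 5
    effect_size: 1.5
    class_balance: 0.5
select:
  table: radsel_out/synthetic_table.csv
  step1:
    selectors: [fisher, chi_squared, gini_index, relieff]
    classifiers: [knn, nb, dt]
    thresholds: [5, 10, 15, 20, 25, 30, 35, 40, 45, 50]
    n_folds: 10
  step2:
    selectors: [lr_rfe, mutual_information, cfs]
    classifiers: [knn, nb, dt]
    thresholds: [1, 2, 3, 4, 5, 6, 7, 8, 9, 10]
    n_folds: 10
train:
  table: radsel_out/synthetic_table.csv
  features_file: radsel_out/final_features.txt
  classifiers: [knn, nb, svm, dt, mlp, rf]
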