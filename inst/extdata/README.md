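# extdata

`iseg2017_reported_metrics.csv` — published per-record precision, recall,
F1 score and accuracy of the (2+1)D U-Net on the ten iSeg-2017 training
records (one row per infant, sorted by increasing F1). Used by the
aggregation tests and the README example to check that the cohort summary
statistics (mean, sample SD, linear-interpolation quartiles) reproduce the
published distribution table from the published per-record values.

`reported_f1_per_tissue.csv` — published per-tissue F1 scores (CSF, GM,
WM) of the (2+1)D U-Net, whose arithmetic mean is the published
tissue-average benchmark.
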