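Reference evaluation tables for the wrist-IMU biceps concentration-curl
fatigue benchmark (25 volunteers, real recordings; the deposited dataset is
not bundled). Used by the test suite and the acceptance script purely as
inputs to arithmetic self-consistency checks: F1 from precision/recall
(reference_rq2_metrics.csv), accuracy-gain-ratio from delta-accuracy and
repetition counts (reference_budget_table.csv), and pairwise accuracy
deltas (reference_comparison.csv). All values are percentages as printed.
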