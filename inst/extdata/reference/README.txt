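Reference clinical evaluation values (per-fold metrics, diagnosis confusion
matrices, and the comparison against the prior state-of-the-art pipeline)
from the published evaluation of this detection protocol on a 1,870-image
ICU chest-radiograph dataset plus a 150-image external validation set.
These are inputs to the metric-arithmetic operations (fold aggregation,
confusion-matrix accuracy, relative change); the package recomputes the
published averages from them.
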