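dataset,lsnn_max_acc,lsnn_nhdn_max_acc,lsm_baseline_acc
ECG5000,98.49,97.73,NA
Wafer,99.51,99.38,98.85
FordA,93.56,89.62,80.37
FordB,82.72,77.78,64.32
Earthquakes,80.43,79.71,71.94
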