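# demo: simulate the three demographic archetypes and scan
# cultivated vs natural for selection
scenario = demography
window_size = 4000
summary_window_size = 2000
pairs = cultivated1:natural1
dcms_threshold = 0.025
seed = 1
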