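recruited,dropped_single_timepoint,no_chemo_rt
19,6,3
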