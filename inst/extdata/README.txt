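dlpfc_group_auc_means.csv: published group mean (and SD) rectified AUC values,
in uV*ms, for low- vs high-power trials under the stimulated and no-stimulus
control conditions, from a 64-dataset healthy-participant DLPFC TMS-EEG study.
Used to check the arithmetic identities of the corrected_effect measure.
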