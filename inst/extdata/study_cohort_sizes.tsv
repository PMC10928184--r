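cohort	role	n_samples
control_cortex	control	14
control_hippocampus	control	13
TLE-HS	epilepsy	64
FCD_IIa	epilepsy	17
FCD_IIb	epilepsy	33
TSC_tubers	epilepsy	21
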