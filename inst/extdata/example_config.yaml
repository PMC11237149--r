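# Headline synthetic experiment: two-class (healthy vs IBD) PCA-LDA / SVM
# classification of the strong-separation plasma cohort, on the full
# 1300-1600 nm window and on the 12 WAMAC water absorbance bands.
preset: plasma_ibd
label_field: label2
ranges: [full_1300_1600, wamac12]
pretreatments:
  - [snv]
models: [LDA, SVM]
validations: [loo]
pc_threshold: 99
seed: 17
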