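# display_label<TAB>token1,token2  -- auditable synonym groups; no stemmer
cell/cells	cell,cells
inflammatory/inflammation	inflammatory,inflammation
disease/diseases	disease,diseases
patient/patients	patient,patients
study/studies	study,studies
control/controls	control,controls
variant/variants	variant,variants
level/levels	level,levels
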