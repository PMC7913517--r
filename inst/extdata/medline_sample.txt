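PMID- 20000001
TI  - Proteome analysis of stratum corneum in atopic
      dermatitis patients.
AB  - Mass spectrometry of tape-stripped stratum corneum revealed
      altered filaggrin processing. FLG degradation products were
      reduced in lesional skin.
DP  - 2017 Mar 15
MH  - Dermatitis, Atopic
MH  - Proteomics

PMID- 20000002
TI  - Genome-wide association study of psoriasis in a European cohort.
AB  - GWAS identified risk variants near IL23R and HLA-C.
DP  - 2016
MH  - Psoriasis
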