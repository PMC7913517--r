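# class<TAB>keyword -- trigger rules for omics categorisation
# epigenome/methylome triggers fold into genome (five-class scheme)
genome	genome
genome	genomic
genome	GWAS
genome	exome
genome	genotype
genome	variant
genome	SNP
genome	methylome
genome	epigenome
genome	epigenomic
transcriptome	transcriptome
transcriptome	RNA-seq
transcriptome	expression profiling
transcriptome	microRNA
transcriptome	miRNA
proteome	proteome
proteome	proteomic
proteome	mass spectrometry
microbiome	microbiome
microbiome	microbiota
microbiome	metagenome
microbiome	metagenomic
microbiome	16S
metabolome	metabolome
metabolome	metabolomic
metabolome	metabolite profiling
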