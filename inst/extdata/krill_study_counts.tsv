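# Published stage counts and quality figures for the Antarctic krill
# reference transcriptome consolidation; used for arithmetic consistency
# checks of the pipeline's bookkeeping conventions.
metric	value
meta_assembly_transcripts	274840
meta_assembly_genes	173549
final_transcripts	151464
final_genes	85830
containment_removed	78731
busco_complete_meta_pct	95.3
busco_complete_final_pct	93.5
nr_matched_transcripts	63903
trembl_matched_transcripts	62518
nt_matched_transcripts	22024
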