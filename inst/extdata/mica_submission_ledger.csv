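batch_id,novel_proteins,synonymous_exon,intron_variations,confirmations_extensions
1,22,9,70,108
2,177,64,64,89
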