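so_id	name
SO:0001893	transcript_ablation
SO:0001574	splice_acceptor_variant
SO:0001575	splice_donor_variant
SO:0001587	stop_gained
SO:0001589	frameshift_variant
SO:0001578	stop_lost
SO:0002012	start_lost
SO:0001889	transcript_amplification
SO:0001821	inframe_insertion
SO:0001822	inframe_deletion
SO:0001583	missense_variant
SO:0001630	splice_region_variant
SO:0001626	incomplete_terminal_codon_variant
SO:0001567	stop_retained_variant
SO:0001819	synonymous_variant
SO:0001580	coding_sequence_variant
SO:0001620	mature_miRNA_variant
SO:0001623	5_prime_UTR_variant
SO:0001624	3_prime_UTR_variant
SO:0001792	non_coding_transcript_exon_variant
SO:0001627	intron_variant
SO:0001621	NMD_transcript_variant
SO:0001619	non_coding_transcript_variant
SO:0001631	upstream_gene_variant
SO:0001632	downstream_gene_variant
SO:0001895	TFBS_ablation
SO:0001892	TFBS_amplification
SO:0001782	TF_binding_site_variant
SO:0001894	regulatory_region_ablation
SO:0001891	regulatory_region_amplification
SO:0001566	regulatory_region_variant
SO:0001907	feature_elongation
SO:0001906	feature_truncation
SO:0001628	intergenic_variant
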