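term	category
missense_variant	missense
frameshift_variant	frameshift
inframe_insertion	in-frame indel
inframe_deletion	in-frame indel
stop_gained	stop gained
stop_lost	stop gained
start_lost	stop gained
splice_donor_variant	splice
splice_acceptor_variant	splice
splice_region_variant	splice
protein_altering_variant	other protein-altering
intron_variant	intronic
synonymous_variant	synonymous
3_prime_UTR_variant	UTR3
5_prime_UTR_variant	UTR5
upstream_gene_variant	other
downstream_gene_variant	other
non_coding_transcript_exon_variant	other
intergenic_variant	other
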