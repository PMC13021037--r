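# Sequence Ontology terms counted as protein-coding-region or
# canonical-splice-site consequences by the region/impact filter.
missense_variant
frameshift_variant
stop_gained
stop_lost
start_lost
inframe_insertion
inframe_deletion
splice_donor_variant
splice_acceptor_variant
protein_altering_variant
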