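#!min_covered_sites=2
#ref_pos	qnor_residue	nod_residues
# Template for a user-supplied signature-site table.
# One row per site: the 1-based residue position on your reference qNor
# protein, the conserved qNor residue, and the comma-separated set of
# Nod-characteristic substitutions observed at that position. Fill the
# positions and residues from the curated qNor/Nod alignment literature
# for your reference numbering; delete these comment lines. The shipped
# defaults in signature_table() are synthetic placeholders for testing,
# not curated biology.
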