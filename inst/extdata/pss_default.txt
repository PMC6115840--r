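# Default nine selected-codon positions (1-based codon indices) laid out
# for a 30-codon alignment, matching the synthetic generator's layout.
# Replace with the empirically determined positions for real alignments.
3
6
9
12
16
19
22
25
28
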