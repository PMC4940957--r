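# Transposable-element and NAT content of identified lncRNAs, counts
# transcribed from the source study: lncRNAs containing TEs split into
# retrotransposon / DNA-transposon carriers, and the trans-NAT count.
# lnc_total is the total number of identified lncRNAs.
quantity	count
lnc_total	25327
te_lnc	2326
te_retro	2117
te_dna	209
nat_lnc	388
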