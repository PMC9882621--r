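# Default non-coding-region coordinates for the 16,569 bp human mtDNA
# (rCRS-style annotations; 1-based inclusive; start > end wraps the
# linearization origin). All values are overridable.
control_region = chrM:16024-576
CSBII = chrM:299-315
CSBIII = chrM:346-363
LSP = chrM:407-445
origin_H_zone = chrM:110-191
seven_s_span = chrM:16106-191
locus_302 = chrM:300-318
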