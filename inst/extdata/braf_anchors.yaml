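# BRAF virtual-4C viewpoint anchors, GRCh38 chromosome 7.
# Coordinates are 0-based half-open and 10 kb aligned; the shared boundary
# (140,790,000) is the breakpoint anchor separating the kept C-terminal
# region from the lost N-terminal region.
gene: BRAF
chrom: chr7
c_terminal: [140710000, 140790000]
n_terminal: [140790000, 140930000]
background: [140710000, 140930000]
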