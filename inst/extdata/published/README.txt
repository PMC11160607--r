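# published reference tables (counts only; clock CpG lists are not redistributed)
clock_overlap_counts.tsv: reported overlap counts between the four top/bottom-1000 loading CpG sets (PC1/PC5) and four published clocks.
clock_pairwise_overlap.tsv: reported pairwise clock CpG overlaps; diagonal entries are the clock sizes.
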