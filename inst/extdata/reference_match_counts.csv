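category,total,level_1c,level_2a
all_observations,299851,252536,47315
matched,94199,84438,9761
in_vivo_chlorophyll,93376,84193,9183
in_vitro_chlorophyll,823,245,578
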