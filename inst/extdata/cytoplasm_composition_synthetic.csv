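# Synthetic coarse-grained cytoplasm composition (constructed stand-in, not a
# measured proteome): nine hard-sphere species spanning 1.7-13 nm, including a
# GFP-like 2.4 nm species and a ribosome-like 13 nm species contributing
# roughly a third of the macromolecular volume. Counts are relative; the box
# is scaled to the requested occupied volume fraction at build time.
label,radius_nm,count
protein_s1,1.7,106
protein_s2,2.1,75
gfp_like,2.4,63
protein_m1,2.8,50
protein_m2,3.4,34
protein_l1,4.2,21
complex_s,5.5,10
complex_l,8.0,5
ribosome_like,13.0,3
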