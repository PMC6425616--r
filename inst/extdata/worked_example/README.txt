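# Reconstructed worked example (synthetic transcription; see package docs).
# Species E = B|C and F = A|B|C are internal species-tree nodes.
# Under the LCA-mapping: d_hat = 6 (heights 1 at A, B, C, B|C; 2 at A|B|C).
# Under alt_mapping.tsv: d_hat = 4 (height 1 at A, 3 at A|B|C), more losses.
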