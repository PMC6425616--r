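((((B__1,C__1),(B__2,C__2)),((B__3,C__3),A__1)),(B__5,C__5));
((A__3,A__4),((B__6,B__7),(C__6,C__7)));
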