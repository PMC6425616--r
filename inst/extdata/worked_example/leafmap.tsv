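B__1	B
C__1	C
B__2	B
C__2	C
B__3	B
C__3	C
A__1	A
B__5	B
C__5	C
A__3	A
A__4	A
B__6	B
B__7	B
C__6	C
C__7	C
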