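node	species	event
B__1	B	C
C__1	C	C
B__2	B	C
C__2	C	C
B__3	B	C
C__3	C	C
A__1	A	C
B__5	B	C
C__5	C	C
A__1|B__1|B__2|B__3|B__5|C__1|C__2|C__3|C__5	A|B|C	D
A__1|B__1|B__2|B__3|C__1|C__2|C__3	A|B|C	D
B__1|B__2|C__1|C__2	A|B|C	D
B__1|C__1	B|C	S
B__2|C__2	B|C	S
A__1|B__3|C__3	A|B|C	S
B__3|C__3	B|C	S
B__5|C__5	B|C	S
A__3	A	C
A__4	A	C
B__6	B	C
B__7	B	C
C__6	C	C
C__7	C	C
A__3|A__4|B__6|B__7|C__6|C__7	A|B|C	D
A__3|A__4	A	D
B__6|B__7|C__6|C__7	A|B|C	D
B__6|B__7	A|B|C	D
C__6|C__7	A|B|C	D
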