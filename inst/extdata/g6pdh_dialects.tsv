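id	equation
r1	[c]: g6p + nadp < = = > 6pgl + h + nadph
r2	[c]: g6p + nadp -- > 6pgl + h + nadph
r3	[c]g6p + nadp < = = > 6pgl + h + nadph
r4	[c]: f420-2 + g6p -- > 6pgl + f420-2h2
r5	G6P + NADP < - > D6PGL + NADPH
r6	G6P + NADP - > D6PGL + NADPH
r7	G6P + NAD - > D6PGL + NADH
r8	C01172 + C00006 = C01236 + C00005 + C00080
r9	C00092 + C00006 < = > C01236 + C00005 + C00080
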