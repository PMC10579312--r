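name	formula	neutral_mass	ion_type
FA 8:0	C8H16O2	144.1150298	[M-H]-
FA 10:0	C10H20O2	172.1463299	[M-H]-
FA 12:0	C12H24O2	200.1776300	[M-H]-
FA 14:0	C14H28O2	228.2089301	[M-H]-
FA 16:0	C16H32O2	256.2402303	[M-H]-
FA 18:0	C18H36O2	284.2715304	[M-H]-
FA 20:0	C20H40O2	312.3028305	[M-H]-
FA 22:0	C22H44O2	340.3341306	[M-H]-
FA 24:0	C24H48O2	368.3654308	[M-H]-
FA 26:0	C26H52O2	396.3967309	[M-H]-
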