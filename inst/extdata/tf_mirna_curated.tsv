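tf	mirna	sign	feedback
E2F1	miR-19b-3p	Activation	FALSE
E2F1	miR-20b-5p	Activation	FALSE
EGR1	miR-30a-5p	Activation	FALSE
EGR1	miR-125a-5p	Activation	FALSE
ESR1	miR-19b-3p	Activation	FALSE
ESR1	miR-20b-5p	Activation	FALSE
ESR1	miR-221-3p	Repression	TRUE
LIN28A	let-7b-5p	Repression	TRUE
LIN28A	let-7g-5p	Repression	TRUE
LIN28B	let-7g-5p	Repression	FALSE
SRSF1	miR-221-3p	Activation	TRUE
TLR2	miR-125a-5p	Activation	FALSE
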