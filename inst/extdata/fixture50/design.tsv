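sample	condition
A_s01	A
A_s02	A
A_s03	A
A_s04	A
A_s05	A
A_s06	A
A_s07	A
A_s08	A
A_s09	A
A_s10	A
B_s01	B
B_s02	B
B_s03	B
B_s04	B
B_s05	B
B_s06	B
B_s07	B
B_s08	B
B_s09	B
B_s10	B
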