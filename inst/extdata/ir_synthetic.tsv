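name	start	end
IR1	20	34
IR2	75	88
IR3	140	151
IR4	230	239
IR5	300	309
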