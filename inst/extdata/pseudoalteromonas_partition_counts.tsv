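#group	core	accessory	unique
genus	1571	2901	18058
pigmented	2042	3906	6340
ph_group	2255	6371	8671
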