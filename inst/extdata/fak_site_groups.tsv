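group	subdomain	residue
Group I	F2	K191
Group I	F2	K216
Group I	F2	K218
Group I	F2	R221
Group I	F2	K222
Group I	F2	R229
Group I	C-lobe	R640
Group I	C-lobe	K657
Group I	C-lobe	R665
Group II	N-lobe & C-lobe	R508
Group II	N-lobe & C-lobe	R514
Group II	N-lobe & C-lobe	K515
Group II	N-lobe & C-lobe	K578
Group II	N-lobe & C-lobe	K621
Group II	N-lobe & C-lobe	K627
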