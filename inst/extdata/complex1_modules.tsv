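N	Ndufa1	Ndufa2	Ndufs1	Ndufv2	Ndufa6	Ndufs6	Ndufa7	Ndufs4	Ndufv3
Q	Ndufs2	Ndufs3	Ndufs7	Ndufs8	Ndufa5
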