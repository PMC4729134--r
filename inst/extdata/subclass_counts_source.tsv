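subclass	clade	n_genes	members
MIKC_C	NA	42	NA
MIKC_STAR	1	3	MADSD1a;MADSD1b;MADSD1c
MIKC_STAR	2	2	MADSD2a;MADSD2b
MIKC_STAR	3	1	MADSD3a
M_ALPHA	1	7	MADS1A1a;MADS1A1b;MADS1A1c;MADS1A1d;MADS1A1e;MADS1A1f;MADS1A1g
M_ALPHA	2	9	MADS1A2a;MADS1A2b;MADS1A2c;MADS1A2d;MADS1A2e;MADS1A2f;MADS1A2g;MADS1A2h;MADS1A2i
M_ALPHA	3	7	MADS1A3a;MADS1A3b;MADS1A3c;MADS1A3d;MADS1A3e;MADS1A3f;MADS1A3g
M_GAMMA	1	10	MADS1G1a;MADS1G1b;MADS1G1c;MADS1G1d;MADS1G1e;MADS1G1f;MADS1G1g;MADS1G1h;MADS1G1i;MADS1G1j
M_GAMMA	2	8	MADS1G2a;MADS1G2b;MADS1G2c;MADS1G2d;MADS1G2e;MADS1G2f;MADS1G2g;MADS1G2h
M_GAMMA	3	1	MADS1G3a
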