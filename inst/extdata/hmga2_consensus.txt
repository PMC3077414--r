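# HMGA2 SELEX-derived consensus binding patterns (IUPAC; W = A or T)
ATATTCGCGAWWATT
ATATTGCGCAWWATT
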