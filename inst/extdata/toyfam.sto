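# STOCKHOLM 1.0
#=GF ID toyfam
seq1 SANDICGPYIMK
seq2 EANDSVGPPNAK
seq3 TNILLCGSLEEK
seq4 SANDQCGSLEEK
seq5 PWNDLHAPFEEW
seq6 SAASGCGPYVNK
//
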