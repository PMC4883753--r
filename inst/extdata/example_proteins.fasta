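>cpA synthetic candidate, Ala-rich, Trp-free
AAAAAGAAASAAAPAAAVAAALAAAGAAASAAAPAAAVAAALAAAGAAAS
AAAPAAAVAAALAAAGAAASAAAPAAAVAAAL
>cpB synthetic candidate, uniform composition
ARNDCQEGHILKMFPSTWYVARNDCQEGHILKMFPSTWYV
ARNDCQEGHILKMFPSTWYVARNDCQEGHILKMFPSTWYV
>cpC synthetic candidate with one ambiguous residue
MKVLSTGHPQNDEFYRACWIMKVLSTGHPQNDEFYRACWIX
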