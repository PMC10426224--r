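# Nucleotide scoring: match +5 / mismatch -4; N scores -1 vs everything
   A  C  G  T  N
A  5 -4 -4 -4 -1
C -4  5 -4 -4 -1
G -4 -4  5 -4 -1
T -4 -4 -4  5 -1
N -1 -1 -1 -1 -1
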