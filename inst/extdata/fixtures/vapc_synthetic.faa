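>VAPC_SYN|Fusobacterium necrophorum subsp. funduliforme (synthetic)|Type II toxin-antitoxin system VapC family toxin, synthetic stand-in for accession H1D476
LIFRVDFDNEWHFALGYLSELDSALLIKEPEVKTRGHASIGSTQLDSNDLTKYDINDTCG
REHKSKKNVKRPVPRFRDDFQDEETKEVNNPGHATDCHNNPVVGARSFKEVPKLYSF
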