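>NEMAPORE_seed01
MRNL-FFVLFFFFASASNLYSCH--AKQVL-SCSYGVQYRNAVRRFKMV-MVFIKFKFSKCFGGEQL-EAT-SCYSPGGSKDIA-SELAPGYAWRDSLQGRCVHKS--LCPEPIQ
>NEMAPORE_seed02
MKV--FLFVVVLVANASNLYSCHK-AKQL--SCSYGVQ-RNAVRRFNMVEMAELKIKFSLCIGAEQL-E-T-SCYSPGGMKDIA-YELAPGYAW-DSLQGRCTKIKF-LCPYPLQ
>NEMAPORE_seed03
MK---DILVFIFVAQASNLMSCHK-AKQV--SCSYGVQYRNGRRRFKMVEMVENRIKFSKCFGGEQL-ETT-SCRSLGGMKDIA-LELAPGVAW-DSLQGRCTKKK--ACPEPMQ
>NEMAPORE_seed04
MR----LIFVVFLASASNLYHCHK-AKQVLVSCSYGTQYRNAVRRFKMVEMVEIKIKFSKCFG-EQL-EAT-TCYSPGGMKDVS-LELAPGYAW-DSLQGRCTKKKKFLCPEPMQ
>NEMAPORE_seed05
MKDDFLVFILLFVANASNLYACHKEAKQVL-SCSYGVQYRNAVRRFKMVEMLEIKIEFSKCFGGEQLSEAT-MCYSPGGMKDIAQLELAPGYAV-DSLQGRCGKKKFSLCPEPMQ
>NEMAPORE_seed06
MR---QFFVLVVVAQASNLYSCHK-ARKVL-SCSYG-GYRNHVRRFKMVEMIEIKIKFSKCFGGENL-EATESCYSPGGMADVA-LEM-PGHAF-DSLQGRCTAKKKFLCPEPMQ
>NEMAPORE_seed07
MK---LIVLIFVLAQASSLYSCHK-AKQVLSACSYGVQYRNAVRRFKSVEMVEIKIKFEKCFGGE-L-EMV-SCYSPAGSKDIA-LELAPGYAW-DSLNGRCTKKKFKLCPEPMQ
>NEMAPORE_seed08
MRE--LLIFIFLLANASNLYSCFK-AKQVL-SCSFGVQYRNAVRRFKMVEMVEIKIKFSKCFGGVEL-KAT-SCYSPGGMKDIA-LELAPGYAW-DSLQGRCTKKKF-LCPEPMQ
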