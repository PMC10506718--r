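>NEMAPORE_seed01
MRNLFFVLFFFFASASNLYSCHAKQVLSCSYGVQYRNAVRRFKMVMVFIKFKFSKCFGGEQLEATSCYSPGGSKDIASELAPGYAWRDSLQGRCVHKSLCPEPIQ
>NEMAPORE_seed02
MKVFLFVVVLVANASNLYSCHKAKQLSCSYGVQRNAVRRFNMVEMAELKIKFSLCIGAEQLETSCYSPGGMKDIAYELAPGYAWDSLQGRCTKIKFLCPYPLQ
>NEMAPORE_seed03
MKDILVFIFVAQASNLMSCHKAKQVSCSYGVQYRNGRRRFKMVEMVENRIKFSKCFGGEQLETTSCRSLGGMKDIALELAPGVAWDSLQGRCTKKKACPEPMQ
>NEMAPORE_seed04
MRLIFVVFLASASNLYHCHKAKQVLVSCSYGTQYRNAVRRFKMVEMVEIKIKFSKCFGEQLEATTCYSPGGMKDVSLELAPGYAWDSLQGRCTKKKKFLCPEPMQ
>NEMAPORE_seed05
MKDDFLVFILLFVANASNLYACHKEAKQVLSCSYGVQYRNAVRRFKMVEMLEIKIEFSKCFGGEQLSEATMCYSPGGMKDIAQLELAPGYAVDSLQGRCGKKKFSLCPEPMQ
>NEMAPORE_seed06
MRQFFVLVVVAQASNLYSCHKARKVLSCSYGGYRNHVRRFKMVEMIEIKIKFSKCFGGENLEATESCYSPGGMADVALEMPGHAFDSLQGRCTAKKKFLCPEPMQ
>NEMAPORE_seed07
MKLIVLIFVLAQASSLYSCHKAKQVLSACSYGVQYRNAVRRFKSVEMVEIKIKFEKCFGGELEMVSCYSPAGSKDIALELAPGYAWDSLNGRCTKKKFKLCPEPMQ
>NEMAPORE_seed08
MRELLIFIFLLANASNLYSCFKAKQVLSCSFGVQYRNAVRRFKMVEMVEIKIKFSKCFGGVELKATSCYSPGGMKDIALELAPGYAWDSLQGRCTKKKFLCPEPMQ
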