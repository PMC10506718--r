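>CSAB_MND_seed01
MKEFFIFFLVVIANAERTPYTCRWLETGCSDNGNCSEIGCVGSEIGVLKCSVTQPCGQCALPDDACIQAYVRYGG
>CSAB_MND_seed02
MRPPLLLLVIFIAQAERFPYRCSWSEKGCSNNNGCGTEIGCILWSPEIGVLECSFTQGCQGQCALPDACIPAQVGLDG
>CSAB_MND_seed03
MKNIFFLVFFANAERFPYRCRWLLQERGCSNNGCSEISGCLGSSEIGVLKCSFTQPCGQCAALPDACIAAQIRMDG
>CSAB_MND_seed04
MKNQFVLLLLLLAQAERFPYRCRWLQETGCSNNGCSIEIGCLGSPEIGIVLKCSYTQCGQCALPDACIPAQVRLDG
>CSAB_MND_seed05
MKVVLLLIIASAERFPYRCRWLQESKGCSNGCLEISCLGSPEIGVLKCTFQPCGRQCALPDACIPAQVRYDG
>CSAB_MND_seed06
MRDLLFILILIANAERFPLRCWRWLQEKGCSIRCDGEIGCLNPEIGVIKCSFTPCGQCALPDADCIPVEVRYDG
>CSAB_MND_seed07
MRNVVVVFLVAQAERYPYRCRWLQEKGCSNSNGCSEICLSPEIGVLKCFAQGCGGQCALNACILAQVRFDG
>CSAB_MND_seed08
MKENLVLLIIFFLAQAERFTYQCRWRQEKGCSNTSGCSEIEGCLSPEAGVLKCSFTQPCGQCAEPDPCIPAQFSYDG
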