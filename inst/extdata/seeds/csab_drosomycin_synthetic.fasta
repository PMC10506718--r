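>CSAB_DROSOMYCIN_seed01
MKVVLVILVFASAALHIKCVTDIVNCVRLILRVNEHSRAQCFLNATAFCVGEGYGADCSVSTLSPNVCQCGECKHEIGMVKG
>CSAB_DROSOMYCIN_seed02
MKNVIIFIVFLIANAALHLKCTDIVNCKLMLRVNEHNTQCLNTFFCGGEVGGEYCSISTISVLNVCQCGETCKHEIGMWEG
>CSAB_DROSOMYCIN_seed03
MKNIFFVLIFANAALHLKCDIVNCRLILRVNSHSTQCLNATFFCGGEVGYCSVSTLFLNCQCQGETCKHEIGMSEG
>CSAB_DROSOMYCIN_seed04
MRVFLVFVIFVAQAALGLKCTDIVNCRLILRVNLEHSNTQCLNLPTFFCGNEVTNYCSVSTTLLLNLCQCGETCKHEIGMVEG
>CSAB_DROSOMYCIN_seed05
MKEDLVFIIIILLAQAALHLKCADTMCRLILRVNWHSRTQCLNSTFFCGGAVGNYCSFSTLSLNVCQCGETCKHEIGMGRG
>CSAB_DROSOMYCIN_seed06
MKEEIVIFIVLASAALFLKCTDIVACRLDLNRVNEHSRTQCLNATFCGGDVVGNHCSVSPLSLNSVCQCGESTCKHEIGMVDG
>CSAB_DROSOMYCIN_seed07
MREPLIILIFFFASAALYLKCTDIVNCRLIIRVNHHSRQCLNATFFCGGEEIGNYCSVTTLSLVCQCGTCKHEIGMVEG
>CSAB_DROSOMYCIN_seed08
MRIFIIVLFIASAALHLKCNDIVNCRLILRDNEEHSRTQCLLATFCGGEVGGYCSVSVTLSLNVCQCGEGTCKHEIGMVEG
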