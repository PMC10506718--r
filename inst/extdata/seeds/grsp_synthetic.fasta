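>GRSP_seed01
MRVVILIVFIVAQAGGYGGNGGSQGGQGGQGGYGGNGKSQTGESGKGGYGGNGGSQGGEGGTGGYGGNGGSQKGEGGK
>GRSP_seed02
MKNPVFFLLIIANAHGYGGNGGSQGGKGGKGQYGGNGGSQGGEGGKGGYDGYGGSQGGEGGKGGYGGNGGSNGGEGGK
>GRSP_seed03
MRQLIVLLVIIAQAHGYGGQGGSQGGEGGKGGYSGNGESQGGEGDKGGYGGNGGEQGGEGGYGGYGGNGGSQGGEQGK
>GRSP_seed04
MRVLVFIILASAGGYGGNGGSGGGDGGKGGYGENGGSQGGEGGKGGYGGYGQSQGGEGGKGGYGGNGGQQGGEGGY
>GRSP_seed05
MKNDFIIILLILAQAGGYGGNGGSQGKEGGKGGYGGNGGSQGGEGGKGRDGGNGGSQGGEGSKGGYGGQGGRQGGYGGK
>GRSP_seed06
MRIFIFVFFASAGSYDGNGGSQGGEGQKGGYGTNGGEQGTEGRRGNYGGNGGSQGGENGKGGYGGNGGSQNGEGYK
>GRSP_seed07
MKFVLLVFFASAGDYQGNGGSQGGEGGKGGYGGNGGSQGGEGRKGGYGGDGGSQGGEGGKKGYGGNGGSQGGEGGK
>GRSP_seed08
MKLVFLLFLFIAQAGGYPGNGGSPGGEGGKGGYGGPGTSRGGEGGKGGYGGNGGTQGGEGGKGGYGGNGGSQGGEGGK
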