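>GRSP_seed01
MRV-VILIVFIVAQAGGYGGNGGSQGGQGGQGGYGGNGKSQTGESGKGGYGGNGGSQGGEGGTGGYGGNGGSQKGEGGK
>GRSP_seed02
MKN-PVFFLLIIANAHGYGGNGGSQGGKGGKGQYGGNGGSQGGEGGKGGYDGYGGSQGGEGGKGGYGGNGGSNGGEGGK
>GRSP_seed03
MRQ-LIVLLVIIAQAHGYGGQGGSQGGEGGKGGYSGNGESQGGEGDKGGYGGNGGEQGGEGGYGGYGGNGGSQGGEQGK
>GRSP_seed04
MR---VLVFIILASAGGYGGNGGSGGGDGGKGGYGENGGSQGGEGGKGGYGGYGQSQGGEGGKGGYGGNGGQQGGEGGY
>GRSP_seed05
MKNDFIIILLILAQAGGYGGNGGSQGKEGGKGGYGGNGGSQGGEGGKGRDGGNGGSQGGEGSKGGYGGQGGRQGGYGGK
>GRSP_seed06
MR---IFIFVFFASAGSYDGNGGSQGGEGQKGGYGTNGGEQGTEGRRGNYGGNGGSQGGENGKGGYGGNGGSQNGEGYK
>GRSP_seed07
MK---FVLLVFFASAGDYQGNGGSQGGEGGKGGYGGNGGSQGGEGRKGGYGGDGGSQGGEGGKKGYGGNGGSQGGEGGK
>GRSP_seed08
MKL-VFLLFLFIAQAGGYPGNGGSPGGEGGKGGYGGPGTSRGGEGGKGGYGGNGGTQGGEGGKGGYGGNGGSQGGEGGK
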