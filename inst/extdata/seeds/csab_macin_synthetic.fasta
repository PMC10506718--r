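>CSAB_MACIN_seed01
MRDIIIILVVVANAVQGLCYQQTCSSRETMCEDRCRDTKEFADAKDECPMVPCSYYVCRICKNPCRKEVGLNLCLRKLPKK
>CSAB_MACIN_seed02
MRQLLFVILIFIANAVQGLCYSTTCGSMRRETMCRRCHDVKKEFFDAKEECPVCYYEYYVCVICAKNPCRLNEVGANCGVKLPKY
>CSAB_MACIN_seed03
MRNQIFIFVFVASAVRGLCYTQTCSKRETMCDDDRCHTTKELFDAPDECLVCSSEYYVCIVICSAVNPCRVLEMGLNCLRKLPKK
>CSAB_MACIN_seed04
MRFLVILIIIFANAISGLCYQTCGSAQTMCDDDRCHDKKESFADAKDECLPLVCSEYVCVICVKNPCSLEVGVNCLRNLPKK
>CSAB_MACIN_seed05
MKQNIVVVFVVASAVQGLCYQQLCGSKRETMGCDDPCHDTKSFFDAKDECPIVCSEYGVCHICAKNCRLEVGLRCLRVLVKK
>CSAB_MACIN_seed06
MRQFFIILLLAQAVQGLCYQYTCGSKESMCDDCHDLKEFFDRKDECELVCSEYYVCVICAKNCRLEVGLNRCLRKLPKK
>CSAB_MACIN_seed07
MKPPFFFVLFVIVASAVQGLCYGTTCGPRETMCDDDRCHDTKQFDAKDECPVCEYYVCVICKNPCRLVGLNCLEKLPKK
>CSAB_MACIN_seed08
MKPDLVFFILIASAVQGLCYYQTCGQGREPMCTDRCHDNKEEFFDAKDECVPIVCSEYLVCVICAGPCRLEVVGLNCLRKLDKK
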