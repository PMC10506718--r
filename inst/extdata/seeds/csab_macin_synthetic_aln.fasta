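>CSAB_MACIN_seed01
MRD--IIIILVVVANAVQGLCYQQTCSSR--ETM-C-EDRCRDTK-EFADAKDEC-PMVPCSYYVC-RICK--NPCRKE-VGLNLCLRKLPKK
>CSAB_MACIN_seed02
MRQ-LLFVILIFIANAVQGLCYSTTCGSMRRETM-C--RRCHDVKKEFFDAKEEC-PVCYYEYYVC-VICA-KNPCRLNEVGAN-CGVKLPKY
>CSAB_MACIN_seed03
MRN--QIFIFVFVASAVRGLCYTQTCSKR--ETM-CDDDRCHTTK-ELFDAPDEC-LVCSSEYYVCIVICSAVNPCRVLEMGLN-CLRKLPKK
>CSAB_MACIN_seed04
MRF--LVILIIIFANAISGLCY-QTCGSA--QTM-CDDDRCHDKKESFADAKDECLPLVCSE-YVC-VICV-KNPCSLE-VGVN-CLRNLPKK
>CSAB_MACIN_seed05
MKQ--NIVVVFVVASAVQGLCYQQLCGSKR-ETMGC-DDPCHDTK-SFFDAKDEC-PIVCSEYGVC-HICA--KNCRLE-VGLR-CLRVLVKK
>CSAB_MACIN_seed06
MRQ---FFIILLLAQAVQGLCYQYTCGSK--ESM-C-DD-CHDLK-EFFDRKDEC-ELVCSEYYVC-VICA--KNCRLE-VGLNRCLRKLPKK
>CSAB_MACIN_seed07
MKPPFFFVLFVIVASAVQGLCYGTTCGPR--ETM-CDDDRCHDTK-Q-FDAKDEC-PVC--EYYVC-VICK--NPCRL--VGLN-CLEKLPKK
>CSAB_MACIN_seed08
MKP--DLVFFILIASAVQGLCYYQTCGQGR-EPM-C-TDRCHDNKEEFFDAKDECVPIVCSEYLVC-VICA--GPCRLEVVGLN-CLRKLDKK
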