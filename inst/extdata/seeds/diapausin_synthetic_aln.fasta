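>DIAPAUSIN_seed01
MRDQ--FIFFIVFAQANVTEECGEHATS-DHNSAAQCRDRFDDRCR-PCGDF-NMS-EDMC-VEF-CVPSRV
>DIAPAUSIN_seed02
MKNL-FVLIVILFANANLLERCGEHAQM-DHNS-AQCRD--DDRCA-PCGDA-NMSVEDCV-IELICVPSRV
>DIAPAUSIN_seed03
MREE--VVIIVFFASANITEECSEHATS-DHNT--QCRD--DDRCR-PECGF-NMS-EDCS-IEF-CVPSRV
>DIAPAUSIN_seed04
MRPP--VFFFIVVASANRNEECGEHATA-DHNS--QCRF--DDRCRPPCGDF-NMSEEDCV-IKFKCISSRV
>DIAPAUSIN_seed05
MK----VIVIFIFANANVGEECGEHVT--NHNK-AQCRD-FDDQCPRPCG-F-NME-ENCI-IEE-CVPSRV
>DIAPAUSIN_seed06
MRQD--VLIIIVIASANVTEECGEH-TS-DHNS-AFCDT--DDQCR-PCGD--NMH-EDCVEIEF-CVPRRV
>DIAPAUSIN_seed07
MKDNILLLIFIILASANVSEECGEHATSQDHVS-AQCLD--WDRCRRPCGDFENMS-DTCV-IEF-CPPSRV
>DIAPAUSIN_seed08
MRDE--LLFILLVANAGVTEECGSHATS-DHNS-AQCRD--DDRCR-RCVDF-NMS-EDCV-IDF-CFPSRV
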