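>DIAPAUSIN_seed01
MRDQFIFFIVFAQANVTEECGEHATSDHNSAAQCRDRFDDRCRPCGDFNMSEDMCVEFCVPSRV
>DIAPAUSIN_seed02
MKNLFVLIVILFANANLLERCGEHAQMDHNSAQCRDDDRCAPCGDANMSVEDCVIELICVPSRV
>DIAPAUSIN_seed03
MREEVVIIVFFASANITEECSEHATSDHNTQCRDDDRCRPECGFNMSEDCSIEFCVPSRV
>DIAPAUSIN_seed04
MRPPVFFFIVVASANRNEECGEHATADHNSQCRFDDRCRPPCGDFNMSEEDCVIKFKCISSRV
>DIAPAUSIN_seed05
MKVIVIFIFANANVGEECGEHVTNHNKAQCRDFDDQCPRPCGFNMEENCIIEECVPSRV
>DIAPAUSIN_seed06
MRQDVLIIIVIASANVTEECGEHTSDHNSAFCDTDDQCRPCGDNMHEDCVEIEFCVPRRV
>DIAPAUSIN_seed07
MKDNILLLIFIILASANVSEECGEHATSQDHVSAQCLDWDRCRRPCGDFENMSDTCVIEFCPPSRV
>DIAPAUSIN_seed08
MRDELLFILLVANAGVTEECGSHATSDHNSAQCRDDDRCRRCVDFNMSEDCVIDFCFPSRV
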