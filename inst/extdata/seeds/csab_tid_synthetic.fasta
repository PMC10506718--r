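>CSAB_TID_seed01
MKVILFLVVVIANAIIGELECIENKDCLSRCLDNLDPMGVSCRETDECTCKQLNGVRS
>CSAB_TID_seed02
MKNVFVFFFVFANAITGELECIEKNKKDCISRCVDNLDDPMSVSCRETDPCTCKALQGVNS
>CSAB_TID_seed03
MRNDLVIVIIIANAIRGELECIENKKKDCIVSRCVDNLDMGVSCREQDECTCPQLQGMRS
>CSAB_TID_seed04
MKPFFVFLVVASAITGEAECIENGKKGCISRCVSIDPMGVSCREPIDDCTCKQLQGVRS
>CSAB_TID_seed05
MKNNIIVLLLVASALTGELECIENKTDKCISRCMDNLDPMGVSCRETDPCTCRQLQGNRS
>CSAB_TID_seed06
MRVVIIILVVANAETGELECIENQDCLSRCTDALVDPMGVSCRETPCTCKQLQGVRS
>CSAB_TID_seed07
MRDEILVIVLVASAITGELECIENKKDCISRTCVNENLDPMGVSCEETPCTCKQLQGVRS
>CSAB_TID_seed08
MRQPIFILIILLASAIGDELECSENKKDICISRCVINLDPGVNCRTDPCTCKELQGVDS
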