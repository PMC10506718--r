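>CSAB_TID_seed01
MKV-ILFLVVVIANAIIGELECIENK--DCL-SR-CL-DNL-DPMGVSCRE-TDECTCKQLNGVRS
>CSAB_TID_seed02
MKN-VFVFFFVFANAITGELECIEKNKKDCI-SR-CV-DNLDDPMSVSCRE-TDPCTCKALQGVNS
>CSAB_TID_seed03
MRN-DLVIVIIIANAIRGELECIENKKKDCIVSR-CV-DNL-D-MGVSCRE-QDECTCPQLQGMRS
>CSAB_TID_seed04
MK--PFFVFLVVASAITGEAECIENGKKGCI-SR-CV--SI-DPMGVSCREPIDDCTCKQLQGVRS
>CSAB_TID_seed05
MKN-NIIVLLLVASALTGELECIENKTDKCI-SR-CM-DNL-DPMGVSCRE-TDPCTCRQLQGNRS
>CSAB_TID_seed06
MR--VVIIILVVANAETGELECIENQ--DCL-SR-CT-DALVDPMGVSCRE-T-PCTCKQLQGVRS
>CSAB_TID_seed07
MRD-EILVIVLVASAITGELECIENK-KDCI-SRTCVNENL-DPMGVSCEE-T-PCTCKQLQGVRS
>CSAB_TID_seed08
MRQPIFILIILLASAIGDELECSENKKDICI-SR-CV-INL-DP-GVNCR--TDPCTCKELQGVDS
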