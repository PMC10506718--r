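>CSAB_MND6CYS_seed01
MRLLFLVFVASALGKNECGACLSHTHRSSFPDCVAICTSNSAVATGGDTKSQLCNEACLGSTS
>CSAB_MND6CYS_seed02
MKLLLVFLLASATSKNECGPGGCLSHTHRSSFHCVGICTSGSDVAGADTISRLCANEACLGSTE
>CSAB_MND6CYS_seed03
MRQQFFIIIVFILAQATSKNECGPCLSHTHRASRFSDCVGCTSGSEVATGAEDTISQLCNEEACEGSTS
>CSAB_MND6CYS_seed04
MKQDIIVFVLIIFANATSKNECGGPGCLSHFTHRSSFPLCVGICTSGSEVAIGIDTISQLCNALACLGATS
>CSAB_MND6CYS_seed05
MKFFVLLFFLANATSNNECGFPGCLSFHTHRSSFPDCWICTSGSEVAAGADTISLCNTCLGSSS
>CSAB_MND6CYS_seed06
MRDPVIFVIVVFASATSKNECTSGCSLKHTDRSRFVDCVGICTSGSVATGADTISQSCNEACLGSTM
>CSAB_MND6CYS_seed07
MKELVIFFILIAQATSKNECGLCLSHTQRSSFPDCVIGICTKGSEVATGADYISQLCPEAECFGLTS
>CSAB_MND6CYS_seed08
MREIVFFLFLILASAVSKNECPGPGCLSHTARSSKMCVVGICTTGSEVATGANISQLCTEACLGSTS
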