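>CSAB_MND6CYS_seed01
MR----LLFLVFVASALGKNECG--ACLS-H-THRSS-FPDCV-AICTSNSAVATGG-DTKSQLCNE-ACLGSTS
>CSAB_MND6CYS_seed02
MK----LLLVFLLASATSKNECGPGGCLS-H-THRSS-FH-CV-GICTSGSDVA-GA-DTISRLCANEACLGSTE
>CSAB_MND6CYS_seed03
MRQQFFIIIVFILAQATSKNECG--PCLS-H-THRASRFSDCV-G-CTSGSEVATGAEDTISQLCNEEACEGSTS
>CSAB_MND6CYS_seed04
MKQDIIVFVLIIFANATSKNECGGPGCLS-HFTHRSS-FPLCV-GICTSGSEVAIGI-DTISQLCNALACLGATS
>CSAB_MND6CYS_seed05
MK---FFVLLFFLANATSNNECGFPGCLSFH-THRSS-FPDC--WICTSGSEVAAGA-DTIS-LCN--TCLGSSS
>CSAB_MND6CYS_seed06
MRD-PVIFVIVVFASATSKNECTSGCSLK-H-TDRSR-FVDCV-GICTSGS-VATGA-DTISQSCNE-ACLGSTM
>CSAB_MND6CYS_seed07
MKE--LVIFFILIAQATSKNECG--LCLS-H-TQRSS-FPDCVIGICTKGSEVATGA-DYISQLCPEAECFGLTS
>CSAB_MND6CYS_seed08
MRE-IVFFLFLILASAVSKNECPGPGCLS-H-TARSS-KMCVV-GICTTGSEVATGA-N-ISQLCTE-ACLGSTS
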