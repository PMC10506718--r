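>CEC_seed01
MRVIIVLVVASASWLSKTAKKLENSAKKHIHEGIAIAIQGGPR
>CEC_seed02
MKDQLLIVILFLAQASWLSKTAKMLENSAKKRISEGQAIAISGSPR
>CEC_seed03
MRNLILIVLLIAQASWLSKTASKLENSAKKRISEGIAIAVQDVPR
>CEC_seed04
MRNVIVVLFIAQASWLQKTAKSLENKAKKRISEGIRILIQGGPQ
>CEC_seed05
MRFVIIVIVANASWLSKTATKLENGAKKRVSEGIAIAIQGGPR
>CEC_seed06
MKVLVLILFIASASWLSKTEKKLENSADIRISEGIAIAIQGLPR
>CEC_seed07
MKENIFLVFVVVAQASWLSKTAKKADNSAKKLISEGIAIAIQGGKR
>CEC_seed08
MRVLLIVLVVAQASWLSKTDKKLENSAKKRISEGIAIAIQGGNR
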