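species,body_size,clutch,insular,activity
sp01,52.1,2,no,diurnal
sp02,48.7,2,no,diurnal
sp03,61.3,3,no,diurnal
sp04,58.9,3,no,nocturnal
sp05,60.2,3,yes,diurnal
sp06,105.4,6,no,nocturnal
sp07,98.1,5,no,nocturnal
sp08,NA,6,yes,diurnal
sp09,33.5,1,no,cathemeral
sp10,35.2,2,no,diurnal
sp11,31.8,NA,yes,diurnal
sp12,34.4,1,no,nocturnal
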