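>Trogon_melanurus Black-tailed Trogon offset=0
FIFCVFSVFTV
>Momotus_momota Blue-crowned Motmot offset=0
FIFCSFSVFTV
>Malacoptila_panamensis White-whiskered Puffbird offset=0
FISCIFSVFTV
>Galbula_ruficauda Rufous-tailed Jacamar offset=0
LMCCIFSVFTV
>Thamnophilus_atrinucha Slaty Antshrike offset=0
FMCCIFCIFTV
>Pitangus_sulphuratus Great Kiskadee offset=0
FMCCIFSVFTV
>Mionectes_oleagineus Ochre-bellied Flycatcher offset=0
FMCCIFSVFTV
>Myiarchus_panamensis Panama Flycatcher offset=0
FMCCIFSVFTV
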