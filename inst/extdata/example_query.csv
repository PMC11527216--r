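organism,barcode
Eleutherodactylus coqui,CO1
Lithobates catesbeianus,16S
Xenopus laevis,
Ctenopharyngodon idella,
Dreissena polymorpha,
Dreissena bugensis,
Eriocheir senensis,
Euwallacea kuroshio,
Euwallacea whitfordiodendrus,
Pomacea canaliculata,
Potamopyrgus antipodarum,
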