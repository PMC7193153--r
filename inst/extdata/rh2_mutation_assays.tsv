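ancestor	ancestor_lambda	mutations	mutant_lambda	descendant	descendant_lambda
AncAgnatha	503	E122Q	486	AncJawedFish	488
AncCyprini2	505	E122Q	489	zebrafish3	488
AncTeleost	491	Q122E	508	eel	506
AncCyprini1	489	Q122E	504	AncCyprini2	505
AncEuteleost1	488	Q122E	503	scabbardfishC	506
AncAgnatha	503	M207L	493	lamprey	492
AncTetrapod	488	M207L	481	coelacanth	478
AncEuteleost2	489	A292S	478	AncEuteleost3	474
AncEuteleost1	488	M207L	480	loosejaw	468
AncEuteleost4	524	E122Q	504	medakaC	492
AncSquamata	497	D83N	496	gecko	467
AncEuteleost2	489	Q122E	504	AncEuteleost4	524
AncEuteleost2	489	Y96T/Q122E/C213F	509	AncEuteleost4	524
AncEuteleost2	489	V60F/F74Y/Y96T/Q122E/T209V/C213F/I255V/L259M/A273G	510	AncEuteleost4	524
AncTetrapod	488	M44I	491	AncSauropsid	499
AncTetrapod	488	L40V/A42C/M44I/I50T/V87A/A166S/I205L/L214I/L309M	491	AncSauropsid	499
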