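node_label	lambda_max_nm	aa122	aa207	aa292	thick_branch	duplication	provenance
AncAgnatha	503	E	M	A	FALSE	FALSE	text
AncJawedFish	488	Q	M	A	TRUE	FALSE	text
AncTeleost	491	Q	M	A	FALSE	FALSE	text
AncClupeo	488	Q	M	A	FALSE	FALSE	text
AncCyprini1	489	Q	M	A	FALSE	TRUE	text
AncCyprini2	505	E	M	A	TRUE	TRUE	text
Ancestor2	474	Q	M	A	TRUE	TRUE	text
AncEuteleost1	488	Q	M	A	FALSE	FALSE	text
AncEuteleost2	489	Q	M	A	FALSE	TRUE	text
AncEuteleost3	474	Q	M	S	TRUE	TRUE	text
AncEuteleost4	524	E	M	A	TRUE	TRUE	text
AncTetrapod	488	Q	M	A	FALSE	FALSE	text
AncSauropsid	499	Q	M	A	TRUE	FALSE	text
AncSquamata	497	Q	M	A	FALSE	FALSE	text
lamprey	492	E	L	A	TRUE	FALSE	text
eel	506	E	M	A	TRUE	FALSE	text
goldfish	511	Q	M	A	TRUE	FALSE	reconstructed
zebrafish1	467	Q	M	A	FALSE	FALSE	reconstructed
zebrafish2	476	Q	M	A	FALSE	FALSE	reconstructed
zebrafish3	488	Q	M	A	TRUE	FALSE	text
zebrafish4	505	E	M	A	FALSE	FALSE	text
scabbardfishC	506	E	M	A	TRUE	FALSE	text
loosejaw	468	Q	M	A	TRUE	FALSE	reconstructed
medakaA	452	Q	M	S	TRUE	FALSE	text
tilapiaB	472	Q	M	S	FALSE	FALSE	text
medakaC	492	Q	M	A	TRUE	FALSE	text
medakaB	516	E	M	A	FALSE	FALSE	text
tilapiaAalpha	528	E	M	A	FALSE	FALSE	text
tilapiaAbeta	518	E	M	A	FALSE	FALSE	text
bfinKillifish	530	E	M	A	FALSE	FALSE	text
coelacanth	478	Q	L	A	TRUE	FALSE	text
pigeon	503	Q	M	A	FALSE	FALSE	text
chicken	505	Q	M	A	FALSE	FALSE	text
zebrafinch	508	Q	M	A	FALSE	FALSE	text
chameleon	495	Q	M	A	FALSE	FALSE	text
gecko	467	Q	M	A	TRUE	FALSE	text
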