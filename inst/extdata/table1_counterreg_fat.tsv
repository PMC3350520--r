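symbol	gene_name	fc_diabetes	fc_aat	fc_powermix
Ppbp	pro-platelet basic protein	-13.4	4.1	6.5
Net1	neuroepithelial cell transforming gene 1	-11.1	7.7	14.7
Pck1	phosphoenolpyruvate carboxykinase 1, cytosolic	-9.3	12.6	13.6
Cd24a	CD24a antigen	-5.8	5.4	3.5
Egr1	early growth response 1	-5.4	6.8	9.5
Rsad2	radical S-adenosyl methionine domain containing 2	-4.3	3.8	2.5
Txnip	thioredoxin interacting protein	-3.9	3.6	4.0
Ptp4a1	protein tyrosine phosphatase 4a1	-3.6	2.7	4.3
Crls1	cardiolipin synthase 1	-3.6	2.2	4.1
Mycl1	v-myc myelocytomatosis viral oncogene homolog 1	-3.0	2.3	2.6
Bnip3l	BCL2/adenovirus E1B interacting protein 3-like	-3.0	2.2	2.0
Ube2d3	ubiquitin-conjugating enzyme E2D 3	-2.9	2.2	3.2
Isg20	interferon-stimulated protein	-2.7	2.3	2.2
Ikbkg	inhibitor of kappaB kinase gamma	-2.6	2.6	2.9
Ccng2	cyclin G2	-2.5	2.5	2.4
Psmd7	proteasome 26S subunit	-2.5	2.0	2.0
Pdk4	pyruvate dehydrogenase kinase, isoenzyme 4	-2.3	4.4	4.2
Bcap31	B-cell receptor-associated protein 31	2.3	-2.4	-2.5
Ccnd2	cyclin D2	2.5	-2.7	-2.4
Chst1	carbohydrate (keratan sulfate Gal-6) sulfotransferase 1	2.6	-2.1	-2.3
Acaca	acetyl-Coenzyme A carboxylase alpha	3.0	-4.5	-3.0
Ccnl2	cyclin L2	3.1	-2.2	-3.1
Mrc2	mannose receptor, C type 2	3.1	-2.1	-3.1
Igfbp5	insulin-like growth factor binding protein 5	3.7	-2.6	-3.7
Rpn1	ribophorin I	3.7	-2.1	-3.6
Rhof	ras homolog gene family, member f	3.9	-3.2	-3.9
Camkk2	calcium/calmodulin-dependent protein kinase kinase 2	4.0	-3.0	-3.7
Pgd	phosphogluconate dehydrogenase	5.2	-4.1	-5.3
Insig1	insulin induced gene 1	7.8	-7.2	-4.3
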