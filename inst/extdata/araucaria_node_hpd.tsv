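# Published per-scenario node-age summaries (Ma) for the dated Araucariaceae
# analysis: posterior median and 95% HPD under the two prior-median scenarios
# (plus10: prior median 10% above the fossil age; plus50: 50% above).
clade	scenario	median	hpd_low	hpd_high
node4_agathis_crown	plus10	26	12	47
node4_agathis_crown	plus50	31	13	55
node5_agathis_wollemia	plus10	61	55	77
node5_agathis_wollemia	plus50	72	60	91
node6_eutacta_crown	plus10	21	9	43
node6_eutacta_crown	plus50	25	11	51
node7_araucaria_crown	plus10	55	29	87
node7_araucaria_crown	plus50	64	34	103
node8_araucariaceae_crown	plus10	81	60	122
node8_araucariaceae_crown	plus50	94	68	138
node9_araucariaceae_stem	plus10	225	202	233
node9_araucariaceae_stem	plus50	250	224	284
pacific_eutacta	plus10	14	5	28
pacific_eutacta	plus50	16	7	33
new_caledonian_eutacta	plus10	7	3	15
new_caledonian_eutacta	plus50	9	3	19
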