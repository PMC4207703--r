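# Candidate fossil calibrations for the Araucariaceae dating study:
# published empirical scaling-factor summaries (implied root age, Ma).
# mean_si with 95% interval (lo95-hi95); min_age_ma is the fossil minimum age
# (NA where the candidate is an alternative placement of the same fossil age,
# 190 Ma, or of the 55 Ma Agathis fossil; the placements node4 and node6-node9
# share those ages).
fossil_id	fossil_name	min_age_ma	taxa	mean_si	lo95	hi95
node1	Acmopyle florinii	55	Podocarpus,Retrophyllum,Dacrycarpus,Falcatifolium,Acmopyle	186	133	250
node2	Prumnopitys Mt. Somers	60	Prumnopitys,Sundacarpus	175	170	247
node3	Austrohamia minuta	160	Cupressaceae,Taxaceae	284	210	413
node4	Agathis vittata (crown placement)	55	Agathis	784	415	1186
node5	Agathis vittata	55	Agathis,Wollemia	368	198	565
node6	araucarian bract scale (Eutacta crown)	190	Eutacta	3083	1305	5426
node7	araucarian bract scale (Araucaria crown)	190	Araucaria	1260	698	1928
node8	araucarian bract scale (Araucariaceae crown)	190	Araucariaceae	842	488	1191
node9	araucarian bract scale (Araucariaceae stem)	190	Araucariaceae,Podocarpaceae	221	196	264
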