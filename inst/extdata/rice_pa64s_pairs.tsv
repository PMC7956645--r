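# Published miRNA-target interaction pairs for rice PA64S, sterile (S)
# compared with fertile (F) anthers; log2 fold changes are S over F.
# Columns: duplex alignment range (1-based, inclusive), degradome-validated
# cleavage site and its category.
mirna_id	target_id	mirna_log2fc	mirna_direction	target_log2fc	target_direction	align_start	align_end	cleavage_site	category
osa-miR156a	OS08G0531600	-1.81	down	2.04	up	1053	1073	1064	2
osa-miR164a	OS06G0675600	0.32	up	-2.58	down	954	974	965	0
osa-miR528-5p	OS09G0365900	1.05	up	-2.41	down	164	183	174	2
osa-miR528-5p	OS12G0552300	1.05	up	1.83	up	2790	2809	2800	4
osa-miR5488	OS02G0177600	1.22	up	-2.14	down	1516	1535	1526	2
osa-miR171b	OS10G0551200	-0.83	down	-1.16	down	549	569	560	2
osa-miR171b	OS05G0417100	-0.83	down	0.87	up	1957	1977	1968	2
osa-miR319a-3p.2-3p	OS01G0755500	-0.97	down	-1.09	down	1236	1254	1245	0
osa-miR319a-3p.2-3p	OS03G0785800	-0.97	down	-1.14	down	1182	1201	1192	0
osa-miR396c-5p	OS04G0600900	0.52	up	-1.78	down	404	425	415	0
osa-miR396c-5p	OS02G0776900	0.52	up	-1.26	down	570	590	581	0
osa-miR156l-5p	OS01G0922600	-1.81	down	-0.70	down	615	635	626	0
osa-miR172d-5p	OS02G0582400	1.21	up	-0.75	down	671	689	681	2
osa-miR399a	OS04G0415000	-1.36	down	0.90	up	489	510	500	2
osa-miR399d	OS04G0415000	-1.14	down	0.90	up	489	510	500	2
osa-miR399j	OS04G0415000	-1.10	down	0.90	up	489	510	500	2
osa-miR419	OS01G0606000	-1.86	down	2.44	up	108	127	119	4
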