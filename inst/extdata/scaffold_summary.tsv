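scaffold	scaffold_size_bp	n_total_snps	n_sex_specific	region_start	region_end	region_size_bp	n_ld_blocks	max_block_span_bp	ld_start	ld_end
scaffold_002	19343486	634171	2	1411525	1411537	13	NA	NA	NA	NA
scaffold_004	15333484	729773	58	13755422	13757959	2538	21	406	13757866	13758271
scaffold_008	13582522	414429	18	13181867	13182926	1060	6	71	13182469	13182539
scaffold_012	11623986	535318	4	6658078	6658121	44	NA	NA	NA	NA
scaffold_016	10992500	349783	4	5851008	5851271	264	NA	NA	NA	NA
scaffold_024	9474074	378040	2	4640584	4641391	808	NA	NA	NA	NA
scaffold_040	6874678	235900	1	6336490	6336490	1	NA	NA	NA	NA
scaffold_047	5831790	228235	32	2802518	2810509	7992	23	208	2810382	2810589
scaffold_061	4681469	154850	29	1942591	2033284	90694	206	307	2026362	2026668
scaffold_064	4535926	89006	44	3723782	3730295	6514	4	3174	3723703	3726876
scaffold_081	3464053	53509	2	3407626	3407890	265	NA	NA	NA	NA
scaffold_082	3452009	163342	11	620729	620873	145	1	185	620689	620873
scaffold_150	749403	5889	41	54606	58731	4126	19	1204	56072	57275
scaffold_187	294664	3161	1	6	1626	1621	NA	NA	NA	NA
scaffold_208	153918	1173	1	139056	139056	1	NA	NA	NA	NA
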