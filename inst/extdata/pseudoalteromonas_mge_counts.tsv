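#strain	plasmid	virus	prophage	total
Pseudoalteromonas sp. AC163	464	1	107	572
P. arctica A 37 1 2 uid168325	493	1	116	610
P. atlantica T6c uid58283	534	2	140	676
Pseudoalteromonas sp. BSi20311 uid78647	450	3	105	558
Pseudoalteromonas sp. BSi20429 uid78649	442	2	102	546
Pseudoalteromonas sp. BSi20439 uid78651	425	1	97	523
Pseudoalteromonas sp. BSi20480 uid78653	422	1	91	514
Pseudoalteromonas sp. BSi20495 uid78655	470	4	102	576
Pseudoalteromonas sp. BSi20652 uid78645	394	3	99	496
Pseudoalteromonas sp. Bsw20308 uid179221	463	3	108	574
P. citrea NCIMB 1889 uid168326	409	3	97	509
P. flavipulchra JG1 uid177806	486	8	106	600
P. haloplanktis ANT 505 uid66747	454	10	115	579
P. haloplanktis ATCC 14393 uid198981	521	4	129	654
P. haloplanktis TAC125 uid58431	427	2	148	577
P. luteoviolacea B ATCC 29581 uid186644	363	5	92	460
P. marina mano4 uid168327	424	1	97	522
Pseudoalteromonas sp. NJ631 uid199000	464	8	98	570
Pseudoalteromonas sp. PAMC 22718 uid179404	463	2	109	574
P. piscicida JCM 20779 uid168328	444	4	100	548
P. rubra ATCC 29570 uid168329	434	5	93	532
P. ruthenica CP76 uid199935	389	5	96	490
Pseudoalteromonas sp. S8-38	528	5	119	652
Pseudoalteromonas sp. S8-8	518	7	120	645
Pseudoalteromonas sp. SM9913 uid61247	424	1	96	521
P. spongiae UST010723 006 uid168330	424	2	94	520
Pseudoalteromonas sp. TAB23	561	2	133	696
P. haloplanktis TAC125	397	2	149	548
Pseudoalteromonas sp. TAE56	445	2	95	542
Pseudoalteromonas sp. TAE79	605	3	121	729
Pseudoalteromonas sp. TAE80	585	4	113	702
Pseudoalteromonas sp. TB13	413	2	143	558
Pseudoalteromonas sp. TB25	456	1	106	563
Pseudoalteromonas sp. TB41	580	4	164	748
Pseudoalteromonas sp. TB51	465	2	148	615
Pseudoalteromonas sp. TB64	463	2	93	558
P. tunicata D2 uid54181	398	4	109	511
P. undina NCIMB 2128 uid168331	400	1	91	492
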