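#strain	contigs	length	orfs	gc	pigmented
Pseudoalteromonas sp. AC163	565	4779003	4765	39.10	NO
P. arctica A 37 1 2 uid168325	68	4628018	4094	39.04	NO
P. atlantica T6c uid58283	1	5187005	4281	44.62	YES
Pseudoalteromonas sp. BSi20311 uid78647	195	3979836	3676	40.33	NO
Pseudoalteromonas sp. BSi20429 uid78649	121	4495777	4030	39.04	NO
Pseudoalteromonas sp. BSi20439 uid78651	243	3882800	3612	40.22	NO
Pseudoalteromonas sp. BSi20480 uid78653	201	4149214	3967	39.60	NO
Pseudoalteromonas sp. BSi20495 uid78655	222	4826524	4365	38.92	NO
Pseudoalteromonas sp. BSi20652 uid78645	298	4253936	4085	38.86	NO
Pseudoalteromonas sp. Bsw20308 uid179221	146	4757001	4172	38.90	NO
P. citrea NCIMB 1889 uid168326	114	5337619	4438	41.13	YES
P. flavipulchra JG1 uid177806	61	5503991	4758	43.19	YES
P. haloplanktis ANT 505 uid66747	142	4494717	4127	39.32	NO
P. haloplanktis ATCC 14393 uid198981	56	6513609	4329	40.84	NO
P. haloplanktis TAC125 uid58431	2	3850272	3484	40.09	NO
P. luteoviolacea B ATCC 29581 uid186644	61	4046270	3681	41.95	YES
P. marina mano4 uid168327	31	4177200	3711	39.65	NO
Pseudoalteromonas sp. NJ631 uid199000	55	6943067	4591	43.36	NA
Pseudoalteromonas sp. PAMC 22718 uid179404	56	5425171	3821	40.17	NO
P. piscicida JCM 20779 uid168328	73	5281621	4524	43.24	YES
P. rubra ATCC 29570 uid168329	64	5969931	4893	47.80	YES
P. ruthenica CP76 uid199935	120	5225945	3714	47.59	YES
Pseudoalteromonas sp. S8-38	87	4990009	4427	39.19	NO
Pseudoalteromonas sp. S8-8	79	4911233	4371	39.21	NO
Pseudoalteromonas sp. SM9913 uid61247	2	4037671	3712	40.28	NO
P. spongiae UST010723 006 uid168330	14	4724746	4185	40.81	YES
Pseudoalteromonas sp. TAB23	367	5139089	5012	39.11	NO
P. haloplanktis TAC125	216	3888065	3740	39.98	NO
Pseudoalteromonas sp. TAE56	163	4600700	4258	39.03	NO
Pseudoalteromonas sp. TAE79	298	5045088	4940	39.29	NO
Pseudoalteromonas sp. TAE80	360	4971170	4941	39.29	NO
Pseudoalteromonas sp. TB13	254	4734094	4489	39.05	NO
Pseudoalteromonas sp. TB25	458	4648658	4546	39.18	NO
Pseudoalteromonas sp. TB41	122	4632606	4217	40.34	NO
Pseudoalteromonas sp. TB51	369	4633324	4625	40.91	NO
Pseudoalteromonas sp. TB64	275	4843680	4649	37.92	NO
P. tunicata D2 uid54181	37	4994813	4504	39.75	YES
P. undina NCIMB 2128 uid168331	20	4001234	3581	39.95	NO
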