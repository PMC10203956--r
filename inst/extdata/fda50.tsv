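no	name	ic50_um	label_1	pred_1	label_1_10	pred_1_10	label_1_20	pred_1_20	label_1_30	pred_1_30	label_1_40	pred_1_40	external
1	Desmethylastemizole	0.001	Blocker	Blocker	Blocker	Blocker	Blocker	Blocker	Blocker	Blocker	Blocker	Blocker	FALSE
2	Cisapride	0.0094	Blocker	Non-blocker	Blocker	Blocker	Blocker	Blocker	Blocker	Blocker	Blocker	Blocker	FALSE
3	Astemizole	0.01	Blocker	Blocker	Blocker	Blocker	Blocker	Blocker	Blocker	Blocker	Blocker	Blocker	FALSE
4	Dofetilide	0.01	Blocker	Blocker	Blocker	Blocker	Blocker	Blocker	Blocker	Blocker	Blocker	Blocker	FALSE
5	Sertindole	0.01	Blocker	Non-blocker	Blocker	Blocker	Blocker	Blocker	Blocker	Blocker	Blocker	Blocker	FALSE
6	Haloperidol	0.0302	Blocker	Blocker	Blocker	Blocker	Blocker	Blocker	Blocker	Blocker	Blocker	Blocker	FALSE
7	Droperidol	0.0324	Blocker	Blocker	Blocker	Blocker	Blocker	Blocker	Blocker	Blocker	Blocker	Blocker	FALSE
8	Verapamil	0.141	Blocker	Blocker	Blocker	Blocker	Blocker	Blocker	Blocker	Blocker	Blocker	Blocker	FALSE
9	Risperidone	0.151	Blocker	Non-blocker	Blocker	Blocker	Blocker	Blocker	Blocker	Blocker	Blocker	Blocker	FALSE
10	Halofantrine	0.2	Blocker	Non-blocker	Blocker	Blocker	Blocker	Blocker	Blocker	Blocker	Blocker	Blocker	TRUE
11	Terfenadine	0.2	Blocker	Blocker	Blocker	Blocker	Blocker	Blocker	Blocker	Blocker	Blocker	Blocker	FALSE
12	Clozapine	0.324	Blocker	Non-blocker	Blocker	Blocker	Blocker	Blocker	Blocker	Blocker	Blocker	Blocker	FALSE
13	Quinidine	0.324	Blocker	Non-blocker	Blocker	Non-blocker	Blocker	Non-blocker	Blocker	Blocker	Blocker	Non-blocker	TRUE
14	Thioridazine	0.363	Blocker	Non-blocker	Blocker	Blocker	Blocker	Blocker	Blocker	Blocker	Blocker	Blocker	FALSE
15	Bepridil	0.55	Blocker	Non-blocker	Blocker	Blocker	Blocker	Blocker	Blocker	Blocker	Blocker	Blocker	FALSE
16	Vesnarinone	1.1	Non-blocker	Non-blocker	-	Non-blocker	-	Non-blocker	-	Non-blocker	-	Non-blocker	FALSE
17	Azimilide	1.41	Non-blocker	Non-blocker	-	Non-blocker	-	Blocker	-	Blocker	-	Blocker	FALSE
18	Mibefradil	1.45	Non-blocker	Non-blocker	-	Non-blocker	-	Blocker	-	Blocker	-	Blocker	FALSE
19	Fluoxetine	1.51	Non-blocker	Non-blocker	-	Non-blocker	-	Blocker	-	Blocker	-	Non-blocker	FALSE
20	Ketoconazole	1.91	Non-blocker	Non-blocker	-	Non-blocker	-	Non-blocker	-	Non-blocker	-	Blocker	FALSE
21	Alosetron	3.24	Non-blocker	Non-blocker	-	Non-blocker	-	Non-blocker	-	Non-blocker	-	Non-blocker	FALSE
22	Sildenafil	3.31	Non-blocker	Non-blocker	-	Non-blocker	-	Non-blocker	-	Non-blocker	-	Blocker	FALSE
23	Imipramine	3.39	Non-blocker	Non-blocker	-	Blocker	-	Non-blocker	-	Non-blocker	-	Non-blocker	FALSE
24	Flecainide	3.89	Non-blocker	Non-blocker	-	Non-blocker	-	Non-blocker	-	Non-blocker	-	Blocker	FALSE
25	Citalopram	3.98	Non-blocker	Non-blocker	-	Blocker	-	Blocker	-	Non-blocker	-	Blocker	FALSE
26	Norclozapine	4.47	Non-blocker	Non-blocker	-	Non-blocker	-	Non-blocker	-	Blocker	-	Non-blocker	FALSE
27	Mosapride	4.8	Non-blocker	Non-blocker	-	Non-blocker	-	Non-blocker	-	Blocker	-	Blocker	FALSE
28	Mefloquine	5.62	Non-blocker	Non-blocker	-	Non-blocker	-	Non-blocker	-	Blocker	-	Blocker	FALSE
29	Cocaine	7.24	Non-blocker	Non-blocker	-	Non-blocker	-	Non-blocker	-	Blocker	-	Blocker	FALSE
30	Perhexiline	7.76	Non-blocker	Non-blocker	-	Non-blocker	-	Non-blocker	-	Non-blocker	-	Non-blocker	FALSE
31	Ranolazine	8.03	Non-blocker	Non-blocker	-	Non-blocker	-	Non-blocker	-	Non-blocker	-	Blocker	FALSE
32	Amitriptyline	10	Non-blocker	Non-blocker	-	Non-blocker	-	Non-blocker	-	Non-blocker	-	Non-blocker	FALSE
33	Nitrendipine	10	Non-blocker	Non-blocker	-	Blocker	-	Non-blocker	-	Non-blocker	-	Non-blocker	FALSE
34	Carvedilol	10.5	Non-blocker	Non-blocker	Non-blocker	Non-blocker	-	Blocker	-	Blocker	-	Blocker	FALSE
35	Dolasetron	12	Non-blocker	Non-blocker	Non-blocker	Non-blocker	-	Non-blocker	-	Non-blocker	-	Non-blocker	FALSE
36	Diltiazem	17.4	Non-blocker	Non-blocker	Non-blocker	Non-blocker	-	Non-blocker	-	Non-blocker	-	Blocker	FALSE
37	Sparfloxacin	18.2	Non-blocker	Non-blocker	Non-blocker	Non-blocker	-	Non-blocker	-	Non-blocker	-	Non-blocker	FALSE
38	Pilsicainide	20.4	Non-blocker	Non-blocker	Non-blocker	Non-blocker	Non-blocker	Non-blocker	-	Non-blocker	-	Non-blocker	FALSE
39	Chlorpheniramine	20.9	Non-blocker	Non-blocker	Non-blocker	Blocker	Non-blocker	Blocker	-	Non-blocker	-	Non-blocker	FALSE
40	Diphenhydramine	26.9	Non-blocker	Non-blocker	Non-blocker	Non-blocker	Non-blocker	Blocker	-	Non-blocker	-	Blocker	FALSE
41	Cetirizine	30.2	Non-blocker	Non-blocker	Non-blocker	Non-blocker	Non-blocker	Non-blocker	Non-blocker	Non-blocker	-	Blocker	FALSE
42	Nifedipine	51	Non-blocker	Non-blocker	Non-blocker	Non-blocker	Non-blocker	Non-blocker	Non-blocker	Non-blocker	Non-blocker	Non-blocker	FALSE
43	Disopyramide	91.2	Non-blocker	Non-blocker	Non-blocker	Non-blocker	Non-blocker	Non-blocker	Non-blocker	Non-blocker	Non-blocker	Non-blocker	TRUE
44	Epinastine	100	Non-blocker	Non-blocker	Non-blocker	Non-blocker	Non-blocker	Non-blocker	Non-blocker	Non-blocker	Non-blocker	Blocker	TRUE
45	Moxifloxacin	129	Non-blocker	Non-blocker	Non-blocker	Non-blocker	Non-blocker	Non-blocker	Non-blocker	Non-blocker	Non-blocker	Non-blocker	FALSE
46	Lidocaine	142	Non-blocker	Non-blocker	Non-blocker	Non-blocker	Non-blocker	Non-blocker	Non-blocker	Non-blocker	Non-blocker	Non-blocker	TRUE
47	Mepivacaine	156	Non-blocker	Non-blocker	Non-blocker	Non-blocker	Non-blocker	Non-blocker	Non-blocker	Non-blocker	Non-blocker	Non-blocker	TRUE
48	Trimethoprim	240	Non-blocker	Non-blocker	Non-blocker	Non-blocker	Non-blocker	Non-blocker	Non-blocker	Non-blocker	Non-blocker	Blocker	TRUE
49	Nicotine	245	Non-blocker	Non-blocker	Non-blocker	Non-blocker	Non-blocker	Non-blocker	Non-blocker	Non-blocker	Non-blocker	Non-blocker	TRUE
50	Ofloxacin	1410	Non-blocker	Non-blocker	Non-blocker	Non-blocker	Non-blocker	Non-blocker	Non-blocker	Non-blocker	Non-blocker	Non-blocker	TRUE
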