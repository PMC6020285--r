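# source: published top-30 concordant gene tables (positively and negatively regulated), transcribed from print
# fc_vitro is SHH/Veh; fc_vivo is oriented Veh/Cyc; FDR columns are Benjamini-Hochberg adjusted p-values
# note: the printed Ptch1 row's fold-change and FDR cells are typeset merged ("218.20E-07");
# transcribed here as fc_vitro=21, fdr_vitro=8.20e-07, the only split consistent with neighboring rows
# printed_rank is the rank printed in each table (positives and negatives ranked separately)
gene	regulation	printed_rank	fc_vitro	fdr_vitro	fc_vivo	fdr_vivo
Gli1	positive	1	25.62	0.000009	1.61	0.104969
Hhip	positive	2	114.91	0.000001	1.56	0.119514
Ptch2	positive	3	8.68	0.000009	1.55	0.006306
Ptch1	positive	4	21	8.20e-07	1.47	0.007005
Gm5127	positive	5	7.49	0.000117	1.48	0.538991
Foxd1	positive	6	6.37	0.000056	1.44	0.380027
Foxf2	positive	7	2.43	0.000041	1.83	0.175736
Id4	positive	8	2.13	0.000259	1.55	0.723333
Epha3	positive	9	3.7	0.00002	1.31	0.668124
Frem1	positive	10	4.18	0.000039	1.21	0.442643
1700018A04Rik	positive	11	5.58	0.000086	1.19	0.698151
Adamts15	positive	12	6.61	0.000038	1.17	0.704734
Lama2	positive	13	3.76	0.00002	1.19	0.571271
Lypd6	positive	14	11.4	0.000125	1.12	0.737329
Trp53i11	positive	15	2.57	0.000119	1.22	0.516635
St8sia2	positive	16	6.19	0.000014	1.15	0.488058
Arhgap20	positive	17	2	0.004416	1.24	0.529114
Gm13476	positive	18	3.2	0.000017	1.18	0.641684
Ntn1	positive	19	3.23	0.000133	1.11	0.618111
Ckb	positive	20	1.19	0.000728	1.5	0.447282
Fez1	positive	21	1.66	0.00097	1.19	0.704734
Gpr30	positive	22	1.76	0.000049	1.15	0.704734
Foxc2	positive	23	1.28	0.004471	1.34	0.442166
H2-Ke6	positive	24	1.69	0.001836	1.12	0.516635
Ephb2	positive	25	2.79	0.000911	1.08	0.73884
Adam5	positive	26	1.53	0.009818	1.13	0.704734
Efnb1	positive	27	1.67	0.000085	1.11	0.618111
Rfc3	positive	28	1.51	0.000725	1.14	0.41917
Fgfr2	positive	29	1.67	0.000309	1.11	0.689333
Nek7	positive	30	1.17	0.003294	1.18	0.618111
Edn1	negative	1	0.262467192	0.000042	0.680272109	0.195648
Gprc5a	negative	2	0.408163265	0.000156	0.81300813	0.730671
Aoc3	negative	3	0.259067358	0.00002	0.847457627	0.725263
Stambpl1	negative	4	0.409836066	0.000181	0.833333333	0.654448
Slc38a4	negative	5	0.408163265	0.004794	0.833333333	0.737329
St6galnac2	negative	6	0.487804878	0.00094	0.81300813	0.714645
Gas1	negative	7	0.261096606	0.000085	0.854700855	0.749637
Grem1	negative	8	0.423728814	0.000056	0.833333333	0.641684
Bnc1	negative	9	0.502512563	0.000752	0.833333333	0.226873
Adamts9	negative	10	0.462962963	0.000004	0.854700855	0.448794
Lhfp	negative	11	0.558659218	0.000247	0.840336134	0.723333
Mylk	negative	12	0.529100529	0.000042	0.847457627	0.32826
Cacnb2	negative	13	0.414937759	0.000106	0.869565217	0.618111
H2-Q9	negative	14	0.564971751	0.00101	0.847457627	0.170192
Prkg1	negative	15	0.595238095	0.00159	0.840336134	0.488058
Cadm1	negative	16	0.411522634	0.000029	0.877192982	0.749129
Nrp2	negative	17	0.666666667	0.000395	0.769230769	0.685182
B4galnt1	negative	18	0.694444444	0.000643	0.763358779	0.560523
Pamr1	negative	19	0.531914894	0.004349	0.862068966	0.723333
Npnt	negative	20	0.344827586	0.000037	0.909090909	0.448794
Ak4	negative	21	0.41322314	0.000639	0.909090909	0.158579
Pard6b	negative	22	0.406504065	0.000074	0.917431193	0.707119
Aldoc	negative	23	0.751879699	0.001536	0.819672131	0.618111
Slc1a4	negative	24	0.584795322	0.002363	0.892857143	0.730671
Nfkbiz	negative	25	0.636942675	0.000028	0.884955752	0.661155
Mast4	negative	26	0.558659218	0.000588	0.900900901	0.618111
Maml2	negative	27	0.454545455	0.000009	0.917431193	0.618111
Syde2	negative	28	0.78125	0.007317	0.826446281	0.704734
Lpar4	negative	29	0.689655172	0.000181	0.877192982	0.317827
Lamb1	negative	30	0.694444444	0.000362	0.877192982	0.155497
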