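uniprot	gene_name	neg_log10_p	log2_ratio	exclusive	compartment
Q7JJ13	Brd2	3.44	-1.27	no
Q8R149	Bud13	3.20	-1.61	no
O35658	C1qbp	3.66	-2.06	no
Q9JJ89	Ccdc86	4.79	-1.55	no
Q99LM2	Cdk5rap3	2.73	-1.51	no
Q8K327	Champ1	4.35	-1.52	no
Q921N6	Ddx27	5.15	-2.14	no	nucleolus
O08749	Dld	6.00	-2.13	no
Q9D2G2	Dlst	3.57	-2.49	no
O08579	Emd	4.27	-2.69	no	nuclear lamin
O35130	Emg1	5.19	-1.08	no	nucleolus
P62806	Hist1h4a	3.63	-1.98	no
Q9DC33	Hmg20a	4.31	-2.16	no
P38647	Hspa9	6.57	-1.99	no
Q3U9G9	Lbr	2.92	-2.71	no	nuclear lamin
P48678	Lmna	5.43	-1.18	no	nuclear lamin
P14733	Lmnb1	5.63	-3.73	no	nuclear lamin
P21619	Lmnb2	4.90	-3.00	no	nuclear lamin
Q6PB66	Lrpprc	3.00	-2.05	no
Q810V0	Mphosph10	3.71	-2.72	no	nucleolus
Q91VE6	Nifk	4.00	-1.67	no	nucleolus
Q9WV70	Noc2l	2.99	-1.26	no	nucleolus
Q8BH74	Nup107	3.23	-1.14	no	nuclear pore
Q8R0G9	Nup133	3.34	-1.70	no	nuclear pore
Q9CWU9	Nup37	4.06	-2.31	no	nuclear pore
P59235	Nup43	6.28	-2.93	no	nuclear pore
Q9JIH2	Nup50	5.74	-1.13	no	nuclear pore
Q8BTS4	Nup54	4.34	-3.37	no	nuclear pore
Q8R480	Nup85	3.47	-1.98	no	nuclear pore
Q8BJ71	Nup93	4.32	-3.14	no	nuclear pore
Q6PFD9	Nup98	5.50	-2.68	no	nuclear pore
Q8R332	Nupl1	4.88	-3.66	no	nuclear pore
P67778	Phb	4.68	-2.54	yes
O35129	Phb2	5.75	-2.48	yes
Q9WTU0	Phf2	3.19	-1.48	no
Q8R3C6	Rbm19	4.06	-1.51	no
Q9JJT0	Rcl1	3.08	-1.63	no	nucleolus
Q91WM3	Rrp9	5.44	-1.36	no	nucleolus
Q9CYH6	Rrs1	3.75	-1.45	no	nucleolus
Q8R2U0	Seh1l	3.23	-1.82	no	nuclear pore
Q91ZW3	Smarca5	3.74	-1.30	no
Q8C4J7	Tbl3	3.78	-1.41	no	nucleolus
Q9CR67	Tmem33	4.45	-3.17	no
Q921T2	Tor1aip1	4.20	-1.88	yes	nuclear lamin
Q9JI13	Utp3	4.54	-2.11	yes	nucleolus
Q9JJA4	Wdr12	3.75	-1.37	no	nucleolus
Q8BHB4	Wdr3	3.22	-1.55	no	nucleolus
Q6ZQL4	Wdr43	2.95	-1.40	no	nucleolus
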