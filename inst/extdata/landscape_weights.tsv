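base	p1	p2	p3	p4	p5	p6	p7	p8	p9	p10	p11	p12	p13	p14	p15	p16	p17	p18	p19	p20	p21	p22	p23	p24	p25	p26	p27	p28	p29	p30
A	0.4113	0.1213	0.6055	-0.4167	-0.0853	-0.092	0.5686	0.138	0.3105	-0.2353	0.0618	-0.4105	-0.1294	0.4727	0.2038	-0.1102	-0.2182	0.2762	0.1871	0.2305	0.4538	-0.3583	0.28	0.1951	-0.3395	0.3603	-0.2	0.0565	-0.1456	-0.1538
C	-0.1694	-0.0318	-0.0188	-0.0836	-0.7969	-0.5344	-0.1291	-0.192	-0.1827	-0.2553	-0.1083	0.1298	0.1967	0.1929	0.0269	0.0556	0.3908	0.2163	-0.2861	0.1391	0.0774	0.1836	0.2465	0.4173	-0.4378	0.3134	0.0317	0.0357	-0.1513	0.8106
G	0.1089	0.4535	0.3915	-0.04	-0.7321	-0.0516	-0.0772	0.1366	0.1515	-0.7243	0.2274	-0.2434	0.0966	0.0269	-0.8979	0.1745	0.1008	-0.3129	-0.1628	-0.2657	0.0265	-0.0651	0.4176	-0.3332	0.024	-0.301	-0.1267	-0.0075	-0.4983	-0.4086
T	0.1899	-0.0284	0.686	0.1908	0.396	0.3644	-0.5289	0.2115	-0.5151	0.0108	-0.218	0.4332	-0.2352	0.083	0.0855	0.4199	0.3116	-0.0271	0.1743	-0.3299	-0.0363	-0.0548	-0.1429	-0.2582	0.196	0.5545	-0.0367	0.0324	-0.1147	0.0412
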