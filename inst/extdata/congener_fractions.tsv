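composition	mz	congener	novel	pPA2	pFLU	pDAD	pANA	pHAL	pAMB	pBUG
14:0	273	C4-C10	1	NA	NA	NA	0.1	NA	NA	NA
16:0	301	C6-C10	0	NA	NA	NA	0.1	NA	NA	NA
18:0	329	C8-C10	0	4.1	0.1	1.9	5.5	NA	NA	NA
19:0	343	C9-C10	0	NA	NA	NA	0.1	NA	NA	NA
20:0	357	C8-C12	0	0.3	NA	0.3	0.3	NA	NA	NA
20:0	357	C10-C10	0	49.5	3.0	4.5	31.3	NA	NA	NA
20:1	355	C8-C12:1	0	NA	NA	0.1	0.3	NA	NA	NA
20:1	355	C10-C10:1	0	0.3	NA	NA	0.2	NA	NA	NA
21:0	371	C10-C11	0	NA	NA	NA	0.1	NA	NA	NA
22:0	385	C8-C14	1	0.3	NA	NA	NA	0.3	NA	0.2
22:0	385	C10-C12	0	32.5	17.1	7.1	16.4	0.1	0.3	0.2
22:1	383	C8-C14:1	1	NA	0.4	NA	NA	0.1	NA	0.1
22:1	383	C10-C12:1	0	4.2	21.3	5.6	10.7	NA	NA	NA
23:0	399	C10-C13	1	NA	0.3	0.3	0.2	NA	0.1	NA
24:0	413	C10-C14	0	4.1	23.8	25.8	10.0	2.0	2.3	4.5
24:0	413	C12-C12	0	0.4	1.0	NA	1.5	0.5	0.2	0.1
24:1	411	C10-C14:1	0	2.9	25.2	47.4	10.8	2.0	0.6	3.0
24:1	411	C12-C12:1	0	NA	NA	NA	1.5	NA	NA	NA
24:2	409	C10:1-C14:1	0	NA	NA	0.2	NA	NA	NA	NA
25:0	427	C11-C14	1	NA	NA	NA	NA	NA	0.3	0.1
25:0	427	C12-C13	1	NA	NA	NA	NA	0.1	0.6	NA
25:1	425	C10-C15:1	1	NA	NA	0.1	NA	NA	NA	NA
25:1	425	C11-C14:1	1	NA	NA	NA	NA	NA	0.1	NA
26:0	441	C10-C16	0	NA	0.2	NA	0.1	NA	NA	NA
26:0	441	C12-C14	0	NA	1.2	1.2	1.5	10.1	12.1	5.1
26:0	441	C13-C13	1	NA	NA	NA	NA	0.2	1.2	NA
26:1	439	C10-C16:1	0	NA	4.1	2.6	3.3	0.1	0.1	0.4
26:1	439	C12-C14:1	0	NA	1.2	1.6	2.2	8.8	4.9	3.9
26:2	437	C12:1-C14:1	0	NA	0.3	0.6	0.7	0.1	NA	0.1
27:0	455	C12-C15	1	NA	NA	NA	NA	NA	0.1	NA
27:0	455	C13-C14	0	NA	NA	NA	NA	0.4	6.3	0.6
27:1	453	C13-C14:1	1	NA	NA	NA	NA	0.3	4.0	0.4
28:0	469	C14-C14	0	NA	NA	NA	0.1	22.1	12.2	24.4
28:1	467	C10-C18:1	1	NA	0.4	NA	0.7	NA	NA	NA
28:1	467	C12-C16:1	1	NA	0.2	0.1	0.3	0.3	NA	0.3
28:1	467	C14-C14:1	0	NA	NA	0.1	0.4	30.8	36.5	28.3
28:2	465	C12:1-C16:1	1	NA	NA	NA	0.2	NA	NA	NA
28:2	465	C14:1-C14:1	0	NA	NA	0.2	0.2	14.9	10.3	11.7
29:0	483	C13-C16	1	NA	NA	NA	NA	0.1	NA	NA
29:0	483	C14-C15	0	NA	NA	NA	NA	NA	NA	0.3
29:1	481	C13-C16:1	1	NA	NA	NA	NA	NA	0.2	NA
29:1	481	C14-C15:1	1	NA	NA	NA	NA	0.1	0.5	0.2
29:1	481	C14:1-C15	1	NA	NA	NA	NA	NA	0.5	NA
29:2	479	C14:1-C15:1	1	NA	NA	NA	NA	NA	0.4	NA
30:0	497	C14-C16	0	NA	NA	NA	NA	0.5	NA	1.2
30:1	495	C12-C18:1	1	NA	NA	NA	0.1	NA	NA	NA
30:1	495	C14-C16:1	0	NA	NA	NA	0.2	3.5	1.7	8.9
30:2	493	C12:1-C18:1	1	NA	NA	NA	0.1	NA	NA	NA
30:2	493	C14:1-C16:1	1	NA	NA	NA	0.2	2.1	4.2	4.4
32:1	523	C14-C18:1	0	NA	NA	NA	NA	NA	NA	0.5
32:1	523	C16-C16:1	0	NA	NA	NA	NA	0.1	NA	0.1
32:2	521	C14:1-C18:1	1	NA	NA	NA	0.1	0.1	NA	0.4
32:2	521	C16:1-C16:1	0	NA	NA	NA	NA	0.1	NA	0.2
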