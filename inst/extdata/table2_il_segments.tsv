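il_name	n_introgressions	segments	multiplicity
Tim1	3	2At.A5,6At.A9,7G.B4	1
Tim2	3	1At.A9,3G.B2,7G.B3	1
Tim3	3	2At.A10,5At.A17,7At.A8	1
Tim4	4	5At.A1,5At.A8,6G.B4,7At.A1	1
Tim5	3	1At.A12,2G.D2,3G.B4	1
Tim6	3	2G.D4,3G.B5,6G.B5	1
Tim7	2	2At.A10,7G.D2	1
Tim8	2	2At.A10,5G.B3	1
Tim9	4	2At.A10,5G.B3,7At.A9,7G.B4	1
Tim10	5	2At.A10,2G.B15,3At.A1,5At.A13,5G.B14	1
Tim11	2	2G.D4,6At.A3	1
Tim12	3	2G.D5,6At.A3,7G.D2	1
Tim13	3	7At.A1,7At.A12,7G.D2	1
Tim14/29	3	1At.A5,2At.A1,4G.B1	2
Tim15	2	1At.A7,1G.B1	1
Tim16	2	2At.A10,3G.D5	1
Tim17	2	4G.B2,5At.A24	1
Tim18	3	5G.B15,6At.A4,6G.B3	1
Tim19	3	1G.D1,4G.B1,6At.A1	1
Tim20	1	2G.B7	1
Tim21	2	2At.A1,4G.B3	1
Tim22	1	6At.A7	1
Tim23	1	5At.A10	1
Tim24	2	3G.B1,7G.B1	1
Tim25	2	2G.D1,5At.A10	1
Tim26	1	2G.B12	1
Tim27	4	2G.B9,3G.B7,5At.A20,6G.B5	1
Tim28	3	1At.A1,5G.B8,6At.A3	1
Tim30	1	2At.A5	1
Tim31	3	5At.A3,5At.A8,6G.B4	1
Tim32	5	2At.A6,3At.A10,5At.A18,6At.A4,7At.A1	1
Tim33	2	2G.B14,7At.A5	1
Tim34	3	2At.A3,2At.A10,3G.D5	1
Tim35	3	1At.A9,3G.B2,7G.B3	1
Tim36	2	2G.B5,4G.B1	1
Tim37	4	1At.A4,4G.B2,5At.A4,7At.A6	1
Tim38	3	1At.A6,5At.A17,7At.A8	1
Tim39	3	2At.A10,2G.B4,5At.A19	1
Tim40	3	2At.A10,2G.B4,3At.A4	1
Tim41	2	2At.A10,7At.A1	1
Tim42	6	1At.A8,5At.A1,5At.A9,6At.A8,6At.A12,7G.D1	1
Tim43	4	1G.B4,2G.B8,5At.A1,5At.A7	1
Tim44	2	5At.A6,6At.A7	1
Tim45	4	1G.B2,5At.A5,5At.A15,6At.A3	1
Tim46	6	1G.B2,2G.D2,5At.A5,5At.A15,6At.A3,6At.A12	1
Tim47	3	3G.D7,5G.B2,7At.A7	1
Tim48	2	3G.D7,5G.B4	1
Tim49	2	2At.A2,2At.A9	1
Tim50	1	5At.A21	1
Tim51	4	2G.B5,3At.A3,5At.A23,7At.A10	1
Tim52	2	3At.A3,7At.A10	1
Tim53	2	1At.A2,2G.B14	1
Tim54	1	2G.B14	1
Tim55	7	1At.A1,2G.B10,3At.A10,3G.D1,5At.A12,6At.A12,6G.B5	1
Tim56	5	1At.A4,2G.B14,3G.D2,5At.A24,7At.A5	1
Tim57	5	1At.A1,2At.A10,3At.A10,7At.A1,7At.A12	1
Tim58	2	1At.A10,5At.A16	1
Tim59	2	3G.D7,4G.B3	1
Tim60	1	4G.B3	1
Tim61	2	1G.D2,6At.A2	1
Tim62	1	2G.B11	1
Tim63	1	2G.D3	1
Tim64	1	5At.A11	1
Tim65	1	3G.D6	1
Tim66	1	5G.B10	1
Tim67	1	7At.A3	1
Tim68	2	4G.B3,7At.A3	1
Tim69	2	4G.B4,6At.A4	1
Tim70	2	2G.B2,6At.A9	1
Tim71	2	2G.B2,6At.A7	1
Tim72	1	2G.B2	1
Tim73	6	2At.A3,2G.B3,2G.B15,3G.D3,5At.A19,6G.B5	1
Tim74	4	1At.A1,1At.A12,2G.B13,7At.A6	1
Tim75	4	2G.B2,6At.A7,7G.B4,7G.D3	1
Tim76	3	2G.B2,4At.A1,6G.B2	1
Tim77	5	1At.A1,2At.A2,3At.A8,5At.A2,5At.A25	1
Tim78	3	1G.D3,2At.A4,6G.B2	1
Tim79	7	1G.B5,2At.A2,2At.A7,5At.A1,6G.B1,7At.A4,7At.A13	1
Tim80	4	1G.B5,2At.A2,6At.A5,7At.A4	1
Tim81	3	5At.A19,5G.B11,6At.A10	1
Tim82	5	3At.A2,3G.B6,5At.A24,6At.A13,6G.B5	1
Tim83	2	2G.B1,5G.B7	1
Tim84	4	3G.B7,4At.D1,6G.B5,7G.B2	1
Tim85	3	5G.B5,6G.B5,7G.B2	1
Tim86	4	1At.A6,2At.D1,5At.A17,7At.A8	1
Tim87	2	3G.B3,4At	1
Tim88	6	2At.A4,3At.A9,5At.A14,5G.B1,5G.B12,6At.A10	1
Tim89	6	2At.A2,3At.A6,3At.A9,5At.A14,5G.B1,6At.A11	1
Tim90	7	2At.A2,3At.A5,3At.A7,5At.A14,5G.B1,5G.B13,6At.A11	1
Tim91	6	1G.B3,5At.A3,5At.A8,6At.A2,6G.B5,7At.A15	1
Tim92	1	7At.A9	1
Tim93	7	2At.A2,2G.B6,3G.D4,5At.A19,6G.B5,7At.A16,7G.B4	1
Tim94	8	2At.A1,2At.A10,4G.D1,5G.B6,5G.B12,6At.A4,7At.A2,7At.A14	1
Tim95	5	5At.A22,5G.B6,5G.B12,7At.A2,7At.A14	1
Tim96	2	1At.A3,5At.A21	1
Tim97	7	1At.A11,2G.B8,3At.A4,5G.B9,6At.A6,6G.B4,7At.A11	1
Tim98	5	1At.A11,3At.A4,5At.A1,5G.B9,6At.A6	1
Tim99	3	2At.A8,3G.B7,5At.A19	1
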