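0	0.75	1.5	2	2.5	3	3.5	4	5	6	7	8	9	10	12	14	16	20	25	30	40	500
0	0.10000000000000001	0.20000000000000001	0.30000000000000004	0.40000000000000002	0.5	0.60000000000000009	0.70000000000000007	0.80000000000000004	0.90000000000000002	1
3	3.444	3.8889999999999998	4.3330000000000002	4.7779999999999996	5.2220000000000004	5.6669999999999998	6.1109999999999998	6.556	7
2.2999999999999998	2.7440000000000002	3.1890000000000001	3.633	4.0780000000000003	4.5220000000000002	4.9669999999999996	5.4109999999999996	5.8559999999999999	6.2999999999999998
1.6000000000000001	2.044	2.4889999999999999	2.9329999999999998	3.3780000000000001	3.8220000000000001	4.2670000000000003	4.7110000000000003	5.1559999999999997	5.5999999999999996
0.90000000000000002	1.3440000000000001	1.7889999999999999	2.2330000000000001	2.6779999999999999	3.1219999999999999	3.5670000000000002	4.0110000000000001	4.4560000000000004	4.9000000000000004
0.20000000000000001	0.64400000000000002	1.089	1.5329999999999999	1.978	2.4220000000000002	2.867	3.3109999999999999	3.7559999999999998	4.2000000000000002
-0.5	-0.056000000000000001	0.38900000000000001	0.83299999999999996	1.278	1.722	2.1669999999999998	2.6110000000000002	3.056	3.5
-1.2	-0.75600000000000001	-0.311	0.13300000000000001	0.57799999999999996	1.022	1.4670000000000001	1.911	2.3559999999999999	2.7999999999999998
-1.8999999999999999	-1.456	-1.0109999999999999	-0.56699999999999995	-0.122	0.32200000000000001	0.76700000000000002	1.2110000000000001	1.6559999999999999	2.1000000000000001
-2.6000000000000001	-2.1560000000000001	-1.7110000000000001	-1.2669999999999999	-0.82199999999999995	-0.378	0.067000000000000004	0.51100000000000001	0.95599999999999996	1.3999999999999999
-3.2999999999999998	-2.8559999999999999	-2.411	-1.9670000000000001	-1.522	-1.0780000000000001	-0.63300000000000001	-0.189	0.25600000000000001	0.69999999999999996
-4	-3.556	-3.1110000000000002	-2.6669999999999998	-2.222	-1.778	-1.333	-0.88900000000000001	-0.44400000000000001	0
-4.7000000000000002	-4.2560000000000002	-3.8109999999999999	-3.367	-2.9220000000000002	-2.4780000000000002	-2.0329999999999999	-1.589	-1.1439999999999999	-0.69999999999999996
-5.4000000000000004	-4.9560000000000004	-4.5110000000000001	-4.0670000000000002	-3.6219999999999999	-3.1779999999999999	-2.7330000000000001	-2.2890000000000001	-1.8440000000000001	-1.3999999999999999
-6.0999999999999996	-5.6559999999999997	-5.2110000000000003	-4.7670000000000003	-4.3220000000000001	-3.8780000000000001	-3.4329999999999998	-2.9889999999999999	-2.544	-2.1000000000000001
-6.7999999999999998	-6.3559999999999999	-5.9109999999999996	-5.4669999999999996	-5.0220000000000002	-4.5780000000000003	-4.133	-3.6890000000000001	-3.2440000000000002	-2.7999999999999998
-7.5	-7.056	-6.6109999999999998	-6.1669999999999998	-5.7220000000000004	-5.2779999999999996	-4.8330000000000002	-4.3890000000000002	-3.944	-3.5
-8.1999999999999993	-7.7560000000000002	-7.3109999999999999	-6.867	-6.4219999999999997	-5.9779999999999998	-5.5330000000000004	-5.0890000000000004	-4.6440000000000001	-4.2000000000000002
-8.9000000000000004	-8.4559999999999995	-8.0109999999999992	-7.5670000000000002	-7.1219999999999999	-6.6779999999999999	-6.2329999999999997	-5.7889999999999997	-5.3440000000000003	-4.9000000000000004
-9.5999999999999996	-9.1560000000000006	-8.7110000000000003	-8.2669999999999995	-7.8220000000000001	-7.3780000000000001	-6.9329999999999998	-6.4889999999999999	-6.0439999999999996	-5.5999999999999996
-10.300000000000001	-9.8559999999999999	-9.4109999999999996	-8.9670000000000005	-8.5220000000000002	-8.0779999999999994	-7.633	-7.1890000000000001	-6.7439999999999998	-6.2999999999999998
-11	-10.555999999999999	-10.111000000000001	-9.6669999999999998	-9.2219999999999995	-8.7780000000000005	-8.3330000000000002	-7.8890000000000002	-7.444	-7
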