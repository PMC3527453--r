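id	status	smoking	age	gender	site	rs1014971	rs11892031	rs1495741	rs710521	rs8102137	rs9642880	GSTM1
S00001	1	non	77.3	male	B	1	0	1	0	0	0	1
S00002	1	non	53.9	female	A	0	0	1	0	0	1	0
S00003	1	non	69	male	C	1	0	1	0	1	0	1
S00004	1	non	66.8	male	A	1	1	0	1	0	1	0
S00005	1	non	68	male	B	1	0	1	0	1	0	1
S00006	1	non	62.9	female	A	1	0	0	1	1	2	0
S00007	1	non	80.2	male	D	1	0	0	1	2	0	1
S00008	1	non	72.8	male	D	0	0	0	1	0	0	1
S00009	0	non	51.6	male	A	2	0	1	0	0	0	1
S00010	0	non	63.2	male	C	0	0	1	0	1	2	1
S00011	0	non	49.3	male	D	2	0	0	1	1	0	0
S00012	0	non	73.9	male	B	2	0	1	0	2	1	0
S00013	0	non	72.5	male	D	1	0	0	1	1	2	0
S00014	0	non	43.7	male	D	1	1	0	0	0	0	0
S00015	0	non	64.6	male	B	1	0	1	0	1	1	1
S00016	0	non	75.2	male	D	1	0	1	1	0	2	1
S00017	0	non	61	male	A	0	0	0	0	1	2	1
S00018	0	non	60.2	male	C	1	1	0	0	1	0	0
S00019	0	non	60.2	female	A	0	0	0	1	2	1	0
S00020	0	non	72	female	A	0	0	0	0	1	0	1
S00021	1	former	73.3	male	B	0	0	0	0	0	0	1
S00022	1	former	83.4	male	D	1	0	0	0	0	0	1
S00023	1	former	67.4	male	D	2	1	0	0	1	0	0
S00024	1	former	74.7	male	B	1	0	0	0	1	0	1
S00025	1	former	76.5	male	D	0	0	0	0	0	1	0
S00026	1	former	54.6	male	D	1	1	0	0	1	1	0
S00027	0	former	62.5	male	B	1	0	0	0	1	1	1
S00028	0	former	89.3	female	B	2	0	1	0	0	0	1
S00029	0	former	76.7	male	D	0	0	0	1	2	1	1
S00030	0	former	54.6	male	A	1	1	1	0	2	2	0
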