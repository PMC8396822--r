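isolate_id,group_id,opa02,opa03,opa09
1,GG1,A2,A3,A9
14,GG1,A2,A3,A9
25,GG1,A2,A3,A9
26,GG1,A2,A3,A9
27,GG1,A2,A3,A9
30,GG1,A2,A3,A9
49,GG1,A2,A3,A9
61,GG1,A2,A3,A9
62,GG1,A2,A3,A9
LO2E2,GG1,A2,A3,A9
CDR3,GG1,A2,A3,A9
CDR12,GG1,A2,A3,A9
2,GG2,B2,B3,B9
4,GG2,B2,B3,B9
6,GG2,B2,B3,B9
11,GG2,B2,B3,B9
17,GG2,B2,B3,B9
19,GG2,B2,B3,B9
20,GG2,B2,B3,B9
3,GG3,C2,B3,C9
5,GG3,C2,B3,C9
7,GG3,C2,B3,C9
8,GG3,C2,B3,C9
9,GG3,C2,B3,C9
10,GG3,C2,B3,C9
12,GG3,C2,B3,C9
13,GG3,C2,B3,C9
15,GG3,C2,B3,C9
16,GG3,C2,B3,C9
18,GG3,C2,B3,C9
21,GG3,C2,B3,C9
22,GG3,C2,B3,C9
23,GG3,C2,B3,C9
24,GG3,C2,B3,C9
28,GG3,C2,B3,C9
29,GG3,C2,B3,C9
31,GG3,C2,B3,C9
32,GG3,C2,B3,C9
33,GG3,C2,B3,C9
34,GG3,C2,B3,C9
35,GG3,C2,B3,C9
36,GG3,C2,B3,C9
37,GG3,C2,B3,C9
38,GG3,C2,B3,C9
39,GG3,C2,B3,C9
40,GG3,C2,B3,C9
41,GG3,C2,B3,C9
42,GG3,C2,B3,C9
43,GG3,C2,B3,C9
44,GG3,D2,D3,E9
45,GG3,D2,D3,E9
46,GG3,D2,D3,E9
47,GG3,D2,D3,E9
48,GG3,D2,D3,E9
50,GG3,D2,D3,E9
51,GG3,D2,D3,E9
52,GG3,D2,D3,E9
53,GG3,D2,D3,E9
54,GG3,D2,D3,E9
55,GG3,D2,D3,E9
56,GG3,D2,D3,E9
57,GG3,D2,D3,E9
58,GG3,D2,D3,E9
59,GG3,D2,D3,E9
60,GG3,D2,D3,E9
64,GG3,D2,D3,E9
LO6/036,GG3,D2,D3,E9
CDR9,GG3,D2,D3,E9
CDR11,GG3,D2,D3,E9
63,GG4,C2,C3,D9
CDR217,GG4,C2,C3,D9
CDR219,GG4,C2,C3,D9
LO417,GG4,C2,C3,D9
AWRI1499,GG4,C2,C3,D9
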