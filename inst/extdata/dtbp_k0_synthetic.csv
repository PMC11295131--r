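"EN_td","K0_cm2_Vs"
0,1.519
10,1.51868
20,1.51773
30,1.51615
40,1.51394
50,1.51109
60,1.50761
70,1.50349
80,1.49875
90,1.49337
100,1.48735
110,1.48071
120,1.47343
130,1.46552
140,1.45697
150,1.4478
160,1.43799
170,1.42754
180,1.41647
190,1.40476
200,1.39242
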