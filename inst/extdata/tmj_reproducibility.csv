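tmj,structure,rmsd_mm,md_mm,dsi
1,condyle,0.18,2.92,0.97
2,condyle,0.28,0.87,0.94
3,condyle,0.1,2.60,0.99
4,condyle,0.08,2.36,0.99
5,condyle,0.05,1.45,1
6,condyle,0.09,2.79,1
7,condyle,0.05,1.45,0.93
8,condyle,0.09,2.79,1
9,condyle,0.09,2.02,0.98
10,condyle,0.02,0.15,1
1,fossa,0.24,1.42,0.97
2,fossa,0.28,1.86,0.93
3,fossa,0.19,2.1,0.99
4,fossa,0.17,1.9,0.96
5,fossa,0.20,1.81,0.99
6,fossa,0.21,2.27,0.99
7,fossa,0.20,1.81,0.97
8,fossa,0.20,2.27,0.99
9,fossa,0.28,1.43,0.90
10,fossa,0.27,3.26,0.99
1,disc,0.26,3.92,0.88
2,disc,0.27,2.97,0.89
3,disc,0.36,3.95,0.78
4,disc,0.33,3.84,0.75
5,disc,0.41,3.81,0.86
6,disc,0.29,3.5,0.76
7,disc,0.41,3.81,0.80
8,disc,0.29,3.5,0.73
9,disc,0.23,3.2,0.71
10,disc,0.29,3.7,0.90
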