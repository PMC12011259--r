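sample_group,species,volume,count
1,Robinia pseudoacacia,3.51,92
2,Robinia pseudoacacia,2.61,72
3,Robinia pseudoacacia,2.45,95
4,Robinia pseudoacacia,2.89,83
5,Robinia pseudoacacia,3.22,81
6,Robinia pseudoacacia,2.52,74
7,Robinia pseudoacacia,2.94,86
8,Robinia pseudoacacia,2.82,77
9,Robinia pseudoacacia,2.92,91
10,Robinia pseudoacacia,2.16,71
1,Pinus tabulaeformis,0.24,20
2,Pinus tabulaeformis,0.19,14
3,Pinus tabulaeformis,0.36,18
4,Pinus tabulaeformis,0.17,15
5,Pinus tabulaeformis,0.10,11
6,Pinus tabulaeformis,0.23,16
7,Pinus tabulaeformis,0.25,20
8,Pinus tabulaeformis,0.18,16
9,Pinus tabulaeformis,0.29,16
10,Pinus tabulaeformis,0.23,15
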