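sample_group,species,volume,count
1,Robinia pseudoacacia,4.91,71
2,Robinia pseudoacacia,3.08,71
3,Robinia pseudoacacia,3.25,70
4,Robinia pseudoacacia,3.61,74
5,Robinia pseudoacacia,3.69,85
6,Robinia pseudoacacia,3.31,74
7,Robinia pseudoacacia,3.58,73
8,Robinia pseudoacacia,2.87,69
9,Robinia pseudoacacia,3.38,72
10,Robinia pseudoacacia,2.43,53
1,Pinus tabulaeformis,0.46,34
2,Pinus tabulaeformis,0.38,32
3,Pinus tabulaeformis,0.41,34
4,Pinus tabulaeformis,0.32,28
5,Pinus tabulaeformis,0.28,32
6,Pinus tabulaeformis,0.35,31
7,Pinus tabulaeformis,0.33,29
8,Pinus tabulaeformis,0.37,32
9,Pinus tabulaeformis,0.38,30
10,Pinus tabulaeformis,0.34,30
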