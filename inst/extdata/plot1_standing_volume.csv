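sample_group,species,volume,count
1,Robinia pseudoacacia,3.82,156
2,Robinia pseudoacacia,1.82,121
3,Robinia pseudoacacia,2.41,122
4,Robinia pseudoacacia,2.43,96
5,Robinia pseudoacacia,2.31,86
6,Robinia pseudoacacia,2.51,95
7,Robinia pseudoacacia,2.46,103
8,Robinia pseudoacacia,1.82,90
9,Robinia pseudoacacia,2.21,105
10,Robinia pseudoacacia,1.35,62
1,Pinus tabulaeformis,0.31,38
2,Pinus tabulaeformis,0.23,36
3,Pinus tabulaeformis,0.26,38
4,Pinus tabulaeformis,0.19,32
5,Pinus tabulaeformis,0.13,36
6,Pinus tabulaeformis,0.2,35
7,Pinus tabulaeformis,0.18,33
8,Pinus tabulaeformis,0.22,37
9,Pinus tabulaeformis,0.23,34
10,Pinus tabulaeformis,0.19,34
1,Ulmus spp.,5.54,19
2,Ulmus spp.,5.72,19
3,Ulmus spp.,8.29,21
4,Ulmus spp.,2.78,19
5,Ulmus spp.,19.98,24
6,Ulmus spp.,6.46,19
7,Ulmus spp.,24.94,23
8,Ulmus spp.,17.09,26
9,Ulmus spp.,7.94,22
10,Ulmus spp.,12.92,17
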