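sample_group,species,volume,count
1,Robinia pseudoacacia,3.63,128
2,Robinia pseudoacacia,3.45,111
3,Robinia pseudoacacia,2.45,95
4,Robinia pseudoacacia,3.06,120
5,Robinia pseudoacacia,3.38,136
6,Robinia pseudoacacia,3.04,129
7,Robinia pseudoacacia,3.10,121
8,Robinia pseudoacacia,2.99,121
9,Robinia pseudoacacia,3.10,130
10,Robinia pseudoacacia,2.50,124
1,Pinus tabulaeformis,0.25,23
2,Pinus tabulaeformis,0.22,15
3,Pinus tabulaeformis,0.36,19
4,Pinus tabulaeformis,0.18,16
5,Pinus tabulaeformis,0.11,13
6,Pinus tabulaeformis,0.23,16
7,Pinus tabulaeformis,0.25,21
8,Pinus tabulaeformis,0.18,16
9,Pinus tabulaeformis,0.30,16
10,Pinus tabulaeformis,0.24,15
1,Ulmus spp.,0.59,51
2,Ulmus spp.,0.86,43
3,Ulmus spp.,0.61,29
4,Ulmus spp.,0.33,39
5,Ulmus spp.,0.11,37
6,Ulmus spp.,0.40,49
7,Ulmus spp.,0.34,47
8,Ulmus spp.,0.24,34
9,Ulmus spp.,0.14,49
10,Ulmus spp.,0.56,45
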