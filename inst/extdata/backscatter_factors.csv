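hvl_mm_al,field_side_cm,bsf
1,2,1.10
1,5,1.15
1,10,1.20
1,15,1.22
1,20,1.23
1,25,1.24
2,2,1.13
2,5,1.20
2,10,1.26
2,15,1.29
2,20,1.30
2,25,1.31
4,2,1.17
4,5,1.26
4,10,1.34
4,15,1.38
4,20,1.40
4,25,1.41
6,2,1.20
6,5,1.30
6,10,1.40
6,15,1.45
6,20,1.47
6,25,1.48
8,2,1.22
8,5,1.32
8,10,1.44
8,15,1.49
8,20,1.52
8,25,1.53
10,2,1.23
10,5,1.33
10,10,1.46
10,15,1.52
10,20,1.55
10,25,1.56
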